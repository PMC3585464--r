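# py-substitution: partition the quantities of a mass action model into a
# coefficient set P and a linear set Y, linearize the velocities (with
# pseudospecies where needed), solve C ybar = 0 over the fraction field of
# polynomials in the P symbols, and compose the steady-state map.

quantities <- function(model) c(model$species, model$rates)

#' Construct a P/Y partition of a model's quantities
#'
#' Every species concentration and rate constant is assigned to either the
#' coefficient set `P` or the linear set `Y`. The order of `Y` matters: row
#' reduction pivots greedily on low-indexed Y columns, so quantities placed
#' early in `Y` are favoured to become dependent and quantities placed late
#' are favoured to stay independent.
#'
#' @param model a `mass_action_model`.
#' @param Y ordered character vector of quantity names mapped to Y.
#' @param P character vector of quantity names mapped to P; defaults to the
#'   complement of `Y` in declaration order.
#' @param frozen character vector of species treated as time-invariant
#'   (their concentrations stay P symbols but their mass-balance rows are
#'   dropped from the steady-state system, as for King-Altman substrates).
#' @return a `partition_map`.
#' @export
partition_map <- function(model, Y, P = NULL, frozen = character(0)) {
  q <- quantities(model)
  if (is.null(P)) P <- setdiff(q, Y)
  if (!all(frozen %in% model$species))
    stop("frozen names must be species: ",
         paste(setdiff(frozen, model$species), collapse = ", "))
  if (any(frozen %in% Y))
    stop("frozen species must be P quantities: ",
         paste(intersect(frozen, Y), collapse = ", "))
  if (anyDuplicated(c(Y, P)))
    stop("partition is not a bijection: duplicated assignment for ",
         paste(unique(c(Y, P)[duplicated(c(Y, P))]), collapse = ", "))
  missing <- setdiff(q, c(Y, P))
  if (length(missing))
    stop("partition is not total: unassigned quantities ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(c(Y, P), q)
  if (length(unknown))
    stop("partition names unknown quantities: ", paste(unknown, collapse = ", "))
  structure(list(Y = Y, P = P, frozen = frozen, pseudospecies = list(),
                 velocity_override = list(), constraints = list()),
            class = "partition_map")
}

#' Read a partition configuration from a YAML file
#'
#' The file holds an ordered `Y:` list, an optional `P:` list and an optional
#' `independent_targets:` list (see [select_independent()]).
#'
#' @param model a `mass_action_model`.
#' @param path YAML file path.
#' @return a `partition_map`, with any `independent_targets` attached as an
#'   attribute.
#' @export
read_partition <- function(model, path) {
  cfg <- yaml::read_yaml(path)
  phi <- partition_map(model, Y = as.character(cfg$Y),
                       P = if (!is.null(cfg$P)) as.character(cfg$P),
                       frozen = if (!is.null(cfg$frozen))
                         as.character(cfg$frozen) else character(0))
  if (!is.null(cfg$independent_targets))
    attr(phi, "independent_targets") <- as.character(cfg$independent_targets)
  phi
}

# effective velocity exponent vector of reaction j under phi (with overrides)
effective_velocity <- function(model, phi, j) {
  ov <- phi$velocity_override[[as.character(j)]]
  if (!is.null(ov)) return(ov)
  r <- model$reactions[[j]]
  c(stats::setNames(1L, r$rate), r$orders)
}

y_degree <- function(expo, Y) {
  sum(expo[intersect(names(expo), Y)])
}

#' Check that a partition linearizes every velocity
#'
#' Under the change of variables, each mass-action velocity must be
#' homogeneous of degree exactly 1 in the Y symbols. Velocities of degree 0
#' (zero-order reactions whose rate constant sits in P) or degree 2 and more
#' (several Y factors) are flagged, with a pseudospecies suggestion.
#'
#' @param model a `mass_action_model`.
#' @param phi a `partition_map`.
#' @return tibble with one row per velocity: `reaction`, `rate`, `degree`,
#'   `ok`, `offending` (Y symbols involved), `suggestion`. Attribute `"ok"`
#'   is `TRUE` when all degrees are exactly 1.
#' @export
validate_partition <- function(model, phi, quiet = TRUE) {
  stopifnot(inherits(model, "mass_action_model"), inherits(phi, "partition_map"))
  rows <- lapply(seq_along(model$reactions), function(j) {
    expo <- effective_velocity(model, phi, j)
    ysyms <- intersect(names(expo), phi$Y)
    deg <- sum(expo[ysyms])
    suggestion <- ""
    if (deg == 0)
      suggestion <- "introduce a pseudospecies multiplying this velocity (constraint: = 1)"
    if (deg >= 2) {
      sq <- ysyms[expo[ysyms] >= 2L]
      suggestion <- if (length(sq))
        paste0("introduce a pseudospecies for the squared factor ", sq[1], "^2")
      else
        paste0("reassign one of {", paste(ysyms, collapse = ", "), "} to P")
    }
    tibble::tibble(reaction = j, rate = model$reactions[[j]]$rate,
                   degree = as.integer(deg), ok = deg == 1L,
                   offending = paste(ysyms[order(match(ysyms, phi$Y))],
                                     collapse = ","),
                   suggestion = suggestion)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ok") <- all(out$ok)
  out
}

#' Introduce a pseudospecies to linearize one velocity
#'
#' A sublinear velocity (degree 0 in Y) is multiplied by a fresh Y variable
#' whose steady value is constrained to 1, so the original rate constant stays
#' an independent P symbol. A superlinear velocity carrying a squared Y
#' concentration \eqn{x^2} has the square replaced by a fresh Y variable `s`
#' constrained to satisfy \eqn{\bar s = \bar x^2} after the null-space
#' combination is taken; that constraint is resolved by
#' [resolve_constraints()], linearly when possible and otherwise through the
#' two roots of a quadratic (one branch per real root).
#'
#' @param model a `mass_action_model`.
#' @param phi a `partition_map`.
#' @param velocity_id index of the flagged reaction.
#' @return list with the (unchanged) `model`, the augmented `phi` and the
#'   recorded `constraint`.
#' @export
introduce_pseudospecies <- function(model, phi, velocity_id) {
  expo <- effective_velocity(model, phi, velocity_id)
  deg <- y_degree(expo, phi$Y)
  if (deg == 1L)
    stop("velocity ", velocity_id, " is already linear in Y")
  ps <- paste0("ps_", model$reactions[[velocity_id]]$rate)
  while (ps %in% c(quantities(model), phi$Y)) ps <- paste0(ps, "_")
  if (deg == 0L) {
    phi$velocity_override[[as.character(velocity_id)]] <-
      mono_mul(expo, stats::setNames(1L, ps))
    constraint <- list(ps = ps, type = "one", target = NULL,
                       reaction = velocity_id)
  } else {
    ysyms <- intersect(names(expo), phi$Y)
    sq <- ysyms[expo[ysyms] >= 2L]
    if (length(sq) == 0L)
      stop("velocity ", velocity_id, " is bilinear in distinct Y quantities (",
           paste(ysyms, collapse = ", "),
           "); reassign one of them to P instead of using a pseudospecies")
    target <- sq[1]
    new_expo <- mono_mul(expo, stats::setNames(-2L, target))
    phi$velocity_override[[as.character(velocity_id)]] <-
      mono_mul(new_expo, stats::setNames(1L, ps))
    constraint <- list(ps = ps, type = "square", target = target,
                       reaction = velocity_id)
  }
  phi$Y <- c(phi$Y, ps)
  phi$pseudospecies[[length(phi$pseudospecies) + 1L]] <- constraint
  phi$constraints[[length(phi$constraints) + 1L]] <- constraint
  list(model = model, phi = phi, constraint = constraint)
}

# repeatedly introduce pseudospecies until every velocity has degree 1
linearize_partition <- function(model, phi) {
  for (pass in seq_len(length(model$reactions) + 1L)) {
    rep <- validate_partition(model, phi)
    if (attr(rep, "ok")) return(phi)
    bad <- rep$reaction[!rep$ok][1]
    phi <- introduce_pseudospecies(model, phi, bad)$phi
  }
  stop("failed to linearize the velocity vector")
}

#' Coefficient matrix and null-space basis of a partitioned model
#'
#' Substituting the partition into the steady state equation `N v = 0` turns
#' it into the linear system `C ybar = 0`, where `C = N (dv/dy)` has entries
#' in the fraction field of polynomials in the P symbols. The matrix is row
#' reduced (greedy lowest-index pivoting), and the null space basis `B` is
#' built from the reduced form with the special-solution normalization
#' (identity on the free rows).
#'
#' @param model a `mass_action_model`.
#' @param phi a `partition_map`; all velocities must have Y-degree 1
#'   (introduce pseudospecies first, or use [solve_steady_state()] which does
#'   so automatically).
#' @return a `coefficient_system` with fields `C`, `rref`, `pivots`, `free`,
#'   `B`, `rank` and nullity `q`.
#' @export
coefficient_matrix <- function(model, phi) {
  rep <- validate_partition(model, phi)
  if (!attr(rep, "ok"))
    stop("partition does not linearize the velocity vector; reactions ",
         paste(rep$reaction[!rep$ok], collapse = ", "),
         " have Y-degree != 1 (see validate_partition)")
  rows_x <- setdiff(model$species, phi$frozen %||% character(0))
  nx <- length(rows_x)
  ny <- length(phi$Y)
  Cp <- matrix(vector("list", nx * ny), nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) Cp[[i, j]] <- poly_zero()
  dimnames(Cp) <- list(rows_x, phi$Y)
  for (j in seq_along(model$reactions)) {
    expo <- effective_velocity(model, phi, j)
    ysym <- intersect(names(expo), phi$Y)
    coefmono <- mono_mul(expo, stats::setNames(-1L, ysym))
    col <- match(ysym, phi$Y)
    for (i in seq_len(nx)) {
      nij <- model$N[rows_x[i], j]
      if (nij != 0)
        Cp[[i, col]] <- p_add(Cp[[i, col]], poly_monomial(nij, coefmono))
    }
  }
  C <- Cp
  for (i in seq_len(nx)) for (j in seq_len(ny)) C[[i, j]] <- as_rf(Cp[[i, j]])
  ff <- poly_ff_jordan(Cp)
  nb <- ff_null_basis(ff, ny)
  q <- ny - ff$rank
  if (q == 0L)
    stop("only trivial steady state for this partition (coefficient matrix has full column rank)")
  dimnames(nb$B) <- list(phi$Y, paste0("u", seq_len(q)))
  # common-denominator form of B: B == B_num / B_den entry-wise, with the
  # free rows of B_num holding the common pivot value
  B_num <- matrix(vector("list", ny * q), ny, q)
  dimnames(B_num) <- dimnames(nb$B)
  for (k in seq_along(nb$free)) {
    for (i in seq_len(ny)) B_num[[i, k]] <- poly_zero()
    B_num[[nb$free[k], k]] <- ff$pivot_value
    for (r in seq_along(ff$pivots)) {
      B_num[[ff$pivots[r], k]] <- p_neg(ff$M[[r, nb$free[k]]])
    }
  }
  structure(list(model = model, phi = phi, C = C, rref = ff_rref(ff, ny),
                 pivots = ff$pivots, free = nb$free, B = nb$B,
                 B_num = B_num, B_den = ff$pivot_value,
                 rank = ff$rank, q = q, Y = phi$Y, P = phi$P),
            class = "coefficient_system")
}

#' @export
print.coefficient_system <- function(x, ...) {
  cat("coefficient_system: ", nrow(x$C), " x ", ncol(x$C),
      ", rank ", x$rank, ", nullity ", x$q, "\n", sep = "")
  cat("pivot columns: ", paste(x$pivots, collapse = ", "),
      " | free columns: ", paste(x$free, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dependency map from the null-space basis
#'
#' Taking `ybar = B u` for fresh independent parameters `u` expresses every
#' pivot (dependent) Y quantity as a rational function of the `u`'s and the P
#' symbols, while each free Y quantity maps to its own `u`.
#'
#' @param system a `coefficient_system`.
#' @param u_symbols names for the independent parameters (default
#'   `u1 ... uq`).
#' @return a `dependency_map`: list `psi` of rational expressions indexed by Y
#'   quantity, plus the free-column/u correspondence.
#' @export
dependency_map <- function(system, u_symbols = NULL) {
  stopifnot(inherits(system, "coefficient_system"))
  q <- system$q
  if (is.null(u_symbols)) u_symbols <- paste0("u", seq_len(q))
  stopifnot(length(u_symbols) == q)
  psi <- vector("list", length(system$Y))
  names(psi) <- system$Y
  for (i in seq_along(system$Y)) {
    acc <- rf_zero()
    for (k in seq_len(q)) {
      b <- system$B[[i, k]]
      if (!rf_is_zero(b)) acc <- rf_add(acc, rf_mul(b, rf_sym(u_symbols[k])))
    }
    psi[[i]] <- acc
  }
  structure(list(psi = psi,
                 u_symbols = u_symbols,
                 owner = stats::setNames(system$Y[system$free], u_symbols),
                 free = system$free, pivots = system$pivots),
            class = "dependency_map")
}

#' Select a specific independent set of Y quantities
#'
#' A set of `q` Y quantities can serve as the independent parameters iff the
#' corresponding rows of the null-space basis `B` form an invertible square
#' matrix `G`; then `u = G^{-1} w` (with `w` the targets' own symbols)
#' re-expresses the whole solution with exactly those quantities independent.
#'
#' @param system a `coefficient_system`.
#' @param targets character vector (length `q`) of Y quantity names, or
#'   integer row indices into `B`.
#' @return list with `accepted`; when accepted, `u` (expressions for the
#'   basis coefficients) and `ybar` (expression for every Y quantity in terms
#'   of the targets and P symbols); when rejected, the symbolic determinant.
#' @export
select_independent <- function(system, targets) {
  stopifnot(inherits(system, "coefficient_system"))
  if (is.numeric(targets)) targets <- system$Y[targets]
  stopifnot(all(targets %in% system$Y))
  if (length(targets) != system$q)
    stop("need exactly q = ", system$q, " targets")
  idx <- match(targets, system$Y)
  q <- system$q
  # work fraction-free: B = B_num / B_den with a global denominator, so a row
  # subset of B is invertible iff the same subset of B_num is
  Gn <- system$B_num[idx, , drop = FALSE]
  detG <- poly_det_bareiss(Gn)
  if (p_is_zero(detG)) {
    return(list(accepted = FALSE, det = rf_zero(), targets = targets))
  }
  # solve (B_num/B_den) u = w  <=>  B_num u = B_den * w on the target rows
  aug <- matrix(vector("list", q * (q + 1L)), q, q + 1L)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) aug[[i, j]] <- Gn[[i, j]]
    aug[[i, q + 1L]] <- p_mul(system$B_den, poly_sym(targets[i]))
  }
  ffs <- poly_ff_jordan(aug)
  u <- vector("list", q)
  for (r in seq_along(ffs$pivots)) {
    u[[ffs$pivots[r]]] <- rf(ffs$M[[r, q + 1L]], ffs$pivot_value)
  }
  ybar <- vector("list", length(system$Y))
  names(ybar) <- system$Y
  for (i in seq_along(system$Y)) {
    acc <- rf_zero()
    for (k in seq_len(q)) {
      b <- system$B[[i, k]]
      if (!rf_is_zero(b)) acc <- rf_add(acc, rf_mul(b, u[[k]]))
    }
    ybar[[i]] <- acc
  }
  list(accepted = TRUE, det = rf(detG), targets = targets, u = u, ybar = ybar)
}

# deterministic pseudo-random residues for the modular screen
mod_points <- function(syms, salt) {
  state <- 48271 * salt + 11
  vals <- stats::setNames(numeric(length(syms)), sort(syms))
  for (i in seq_along(vals)) {
    state <- (48271 * state + 3399) %% 2147483647
    vals[i] <- 2 + state %% (MOD_P - 4)
  }
  vals
}

#' Count admissible independent-variable selections
#'
#' Counts the `q`-row subsets of the null-space basis `B` whose square
#' submatrix is symbolically invertible, i.e. how many distinct sets of Y
#' quantities could serve as independent parameters. The count is a property
#' of the row matroid of `B` and does not depend on the basis choice.
#' Candidate submatrices are screened by exact modular evaluation at generic
#' points (a nonzero modular determinant certifies invertibility) and the
#' remaining candidates are confirmed by exact symbolic determinants.
#'
#' @param system a `coefficient_system`.
#' @return integer count.
#' @export
count_admissible_partitions <- function(system) {
  stopifnot(inherits(system, "coefficient_system"))
  Bp <- system$B_num
  ny <- nrow(Bp); q <- ncol(Bp)
  syms <- sort(unique(unlist(lapply(Bp, p_vars))))
  screens <- lapply(1:2, function(s) {
    vals <- mod_points(syms, s)
    M <- matrix(0, ny, q)
    for (i in seq_len(ny)) for (j in seq_len(q))
      M[i, j] <- p_eval_mod(Bp[[i, j]], vals)
    M
  })
  subsets <- utils::combn(ny, q)
  count <- 0L
  for (s in seq_len(ncol(subsets))) {
    rows <- subsets[, s]
    nonzero <- FALSE
    for (M in screens) {
      if (det_mod(M[rows, , drop = FALSE]) != 0) { nonzero <- TRUE; break }
    }
    if (!nonzero) {
      nonzero <- !p_is_zero(poly_det_bareiss(Bp[rows, , drop = FALSE]))
    }
    if (nonzero) count <- count + 1L
  }
  count
}

# ---------------------------------------------------------------------------
# constraint resolution

# constraint expression in u-space: ybar_ps - 1  or  ybar_ps - ybar_target^2
constraint_rf <- function(constraint, psi) {
  lhs <- psi[[constraint$ps]]
  if (constraint$type == "one") {
    rf_sub(lhs, rf_one())
  } else {
    rf_sub(lhs, rf_pow(psi[[constraint$target]], 2L))
  }
}

#' Resolve pseudospecies constraints into solution branches
#'
#' Each pseudospecies carries a constraint on the null-space coefficients `u`
#' (its steady value must be 1 for a sublinear pseudospecies, or the square of
#' the designated concentration for a superlinear one). Substituting
#' `ybar = B u` turns each constraint into a polynomial equation in the `u`'s:
#' equations linear in some `u` are eliminated directly; a quadratic in one
#' `u` yields one branch per root, kept in exact form through the quadratic
#' relation. Anything beyond one terminal quadratic is returned unsolved.
#'
#' @param dep a `dependency_map`.
#' @param constraints list of constraints (normally taken from the partition
#'   after pseudospecies introduction).
#' @return list of branches; each branch has the updated `psi`, the
#'   eliminated `u`'s, an optional `quad` record `(u, a, b, c, sign)` and a
#'   `branch_id`.
#' @export
resolve_constraints <- function(dep, constraints) {
  stopifnot(inherits(dep, "dependency_map"))
  psi <- dep$psi
  alive <- dep$u_symbols
  eliminated <- list()
  quad <- NULL
  for (ci in seq_along(constraints)) {
    con <- constraints[[ci]]
    expr <- constraint_rf(con, psi)
    if (rf_is_zero(expr)) next
    num <- expr$num
    present <- intersect(alive, p_vars(num))
    if (length(present) == 0L)
      stop("constraint on ", con$ps, " has no free coefficient left to solve for")
    if (!is.null(quad))
      stop("constraint system goes beyond a single terminal quadratic; ",
           "returning unsolved is not supported past this point -- ",
           "reorder Y or choose another partition")
    degs <- vapply(present, function(s) p_deg(num, s), numeric(1))
    # prefer eliminating the u owned by a pseudospecies column, then the
    # highest-indexed linear u
    lin <- present[degs == 1]
    pick_pref <- function(cands) {
      owners <- dep$owner[cands]
      ps_owned <- cands[owners %in% vapply(constraints, `[[`, character(1), "ps")]
      if (length(ps_owned)) ps_owned[length(ps_owned)] else cands[length(cands)]
    }
    if (length(lin)) {
      usym <- pick_pref(lin)
      cf <- p_univariate(num, usym)
      sol <- rf_div(new_rf(p_neg(cf[[1]]), poly_one()), new_rf(cf[[2]], poly_one()))
      env <- stats::setNames(list(sol), usym)
      psi <- lapply(psi, rf_subst, env = env)
      eliminated[[usym]] <- sol
      alive <- setdiff(alive, usym)
    } else {
      qu <- present[degs == 2]
      if (length(qu) == 0L)
        stop("constraint on ", con$ps,
             " is neither linear nor quadratic in any free coefficient")
      usym <- pick_pref(qu)
      cf <- p_univariate(num, usym)
      quad <- list(u = usym, a = new_rf(cf[[3]], poly_one()),
                   b = new_rf(cf[[2]], poly_one()),
                   c = new_rf(cf[[1]], poly_one()))
      alive <- setdiff(alive, usym)
    }
  }
  if (is.null(quad)) {
    list(list(psi = psi, eliminated = eliminated, alive = alive,
              quad = NULL, branch_id = 1L, owner = dep$owner))
  } else {
    lapply(c(1L, 2L), function(b) {
      q2 <- quad
      q2$sign <- if (b == 1L) 1 else -1
      list(psi = psi, eliminated = eliminated, alive = alive,
           quad = q2, branch_id = b, owner = dep$owner)
    })
  }
}

# reduce polynomial `num` modulo the quadratic relation a u^2 + b u + c = 0
# (all polynomials); returns TRUE iff num == 0 modulo the relation
poly_zero_mod_quad <- function(num, usym, a, b, c) {
  rel_deg2 <- a
  for (guard in seq_len(64L)) {
    d <- p_deg(num, usym)
    if (!is.finite(d) || d < 2) break
    cf <- p_univariate(num, usym)
    lead <- cf[[d + 1L]]
    # num <- a*num - lead * u^(d-2) * (a u^2 + b u + c)
    shift <- poly_monomial(1, stats::setNames(as.integer(d - 2L), usym))
    rel <- p_add(p_mul(a, poly_monomial(1, stats::setNames(2L, usym))),
                 p_add(p_mul(b, poly_sym(usym)), c))
    num <- p_sub(p_mul(a, num), p_mul(p_mul(lead, shift), rel))
  }
  p_is_zero(num)
}

rf_zero_mod_quad <- function(x, quad_named) {
  if (rf_is_zero(x)) return(TRUE)
  if (is.null(quad_named)) return(FALSE)
  poly_zero_mod_quad(x$num, quad_named$u,
                     p_mul(quad_named$a$num, poly_one()),
                     quad_named$b$num, quad_named$c$num)
}

# ---------------------------------------------------------------------------
# composition

#' Compose and verify the steady-state map
#'
#' Builds the full map sending every original species concentration and rate
#' constant either to itself (independent quantities) or to a rational
#' expression in the independent quantities (dependent ones), by composing
#' the partition, the dependency map and the chosen constraint branch, and
#' renaming the abstract `u` coefficients back to the original names of the
#' free quantities. The composed map is then verified by substituting into
#' `N v` and simplifying: the residual must vanish identically.
#'
#' @param model a `mass_action_model`.
#' @param phi the (pseudospecies-augmented) `partition_map`.
#' @param dep a `dependency_map` for the coefficient system of `(model, phi)`.
#' @param branch one element of the list returned by [resolve_constraints()],
#'   or `NULL` when there are no pseudospecies constraints.
#' @return a `steady_state_solution`.
#' @export
compose_and_verify <- function(model, phi, dep, branch = NULL) {
  if (is.null(branch)) {
    branch <- list(psi = dep$psi, eliminated = list(),
                   alive = dep$u_symbols, quad = NULL, branch_id = 1L,
                   owner = dep$owner)
  }
  qs <- quantities(model)
  # rho: rename alive u symbols to the original quantity that owns the column
  env_rho <- list()
  for (usym in branch$alive) {
    owner <- branch$owner[[usym]]
    if (owner %in% qs) env_rho[[usym]] <- rf_sym(owner)
  }
  sigma <- vector("list", length(qs))
  names(sigma) <- qs
  for (q_ in qs) {
    if (q_ %in% phi$P) {
      sigma[[q_]] <- rf_sym(q_)
    } else {
      sigma[[q_]] <- rf_subst(branch$psi[[q_]], env_rho)
    }
  }
  quad <- branch$quad
  if (!is.null(quad)) {
    quad$a <- rf_subst(quad$a, env_rho)
    quad$b <- rf_subst(quad$b, env_rho)
    quad$c <- rf_subst(quad$c, env_rho)
  }
  # verification: N v(sigma) must vanish identically on time-varying rows
  rows_x <- setdiff(model$species, phi$frozen %||% character(0))
  residual_exprs <- character(0)
  for (i in rows_x) {
    acc <- rf_zero()
    for (j in seq_along(model$reactions)) {
      nij <- model$N[i, j]
      if (nij == 0) next
      vj <- p_subst(velocity_poly(model, j), sigma)
      acc <- rf_add(acc, rf_mul(rf_const(nij), vj))
    }
    ok <- if (is.null(quad)) rf_is_zero(acc) else
      rf_zero_mod_quad(acc, list(u = quad$u, a = as_rf(quad$a$num),
                                 b = quad$b, c = quad$c))
    if (!ok) {
      stop("internal inconsistency: nonzero steady-state residual for species ",
           i, ": ", rf_deparse(acc))
    }
    residual_exprs <- c(residual_exprs, "0")
  }
  is_self <- vapply(qs, function(q_) {
    s <- sigma[[q_]]
    p_nterms(s$num) == 1L && s$num$coefs[1] == 1 &&
      identical(s$num$keys[1], q_) &&
      p_nterms(s$den) == 1L && s$den$keys[1] == "1"
  }, logical(1))
  independents <- qs[is_self]
  if (!is.null(quad)) independents <- c(independents, quad$u)
  structure(list(model = model, phi = phi,
                 sigma = sigma,
                 independents = independents,
                 dependents = qs[!is_self],
                 quad = quad,
                 branch_id = branch$branch_id,
                 verified = TRUE,
                 feasible = NA),
            class = "steady_state_solution")
}

#' Derive an analytical steady-state expression for a mass action model
#'
#' End-to-end driver: validates the partition, introduces pseudospecies where
#' a velocity is not degree 1 in Y, forms the coefficient system, takes the
#' null-space dependency map, resolves pseudospecies constraints into
#' branches, and composes and verifies the steady-state map for each branch.
#'
#' @param model a `mass_action_model`.
#' @param phi a `partition_map`.
#' @return a `steady_state_result`: list with the augmented partition, the
#'   `coefficient_system`, the `dependency_map` and one verified
#'   `steady_state_solution` per branch.
#' @examples
#' m <- parse_model("
#'   E + S -> ES ; k1
#'   ES -> E + S ; k2
#'   ES -> E + P ; k3
#'   Ø -> S ; k4
#'   P -> Ø ; k5")
#' phi <- partition_map(m, Y = c("k1", "k2", "k3", "k4", "k5"))
#' sol <- solve_steady_state(m, phi)
#' tidy(sol$branches[[1]])
#' @export
solve_steady_state <- function(model, phi) {
  phi <- linearize_partition(model, phi)
  system <- coefficient_matrix(model, phi)
  dep <- dependency_map(system)
  branches <- if (length(phi$constraints)) {
    resolve_constraints(dep, phi$constraints)
  } else {
    list(NULL)
  }
  sols <- lapply(branches, function(b) compose_and_verify(model, phi, dep, b))
  structure(list(model = model, phi = phi, system = system, dep = dep,
                 branches = sols),
            class = "steady_state_result")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat("steady_state_solution (branch ", x$branch_id, ", residual verified)\n",
      sep = "")
  cat("independent: ", paste(x$independents, collapse = ", "), "\n", sep = "")
  for (q_ in x$dependents) {
    cat("  ", q_, " = ", rf_deparse(x$sigma[[q_]]), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("steady_state_result: rank ", x$system$rank, ", nullity ", x$system$q,
      ", ", length(x$branches), " branch(es)\n", sep = "")
  print(x$branches[[1]])
  invisible(x)
}
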