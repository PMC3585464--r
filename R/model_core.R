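# Mass action models: plain-text reaction format, stoichiometric matrix,
# symbolic velocity vector, linear-model classification.

SINK_TOKENS <- c("Ø", "0", "O/")

parse_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "")
    stop("parse error on line ", line_no,
         ": empty reaction side (use \u00d8 or 0 for a source/sink)",
         call. = FALSE)
  if (txt %in% SINK_TOKENS) return(stats::setNames(integer(0), character(0)))
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (p in parts) {
    if (p %in% SINK_TOKENS)

      stop("parse error on line ", line_no,
           ": source/sink token cannot be combined with species", call. = FALSE)
    m <- regmatches(p, regexec("^([0-9]+)[[:space:]*]*([A-Za-z_.][A-Za-z0-9_.]*)$", p))[[1]]
    if (length(m) == 3L) {
      sp <- m[3]; coef <- as.integer(m[2])
    } else if (grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", p)) {
      sp <- p; coef <- 1L
    } else {
      stop("parse error on line ", line_no, ": unknown token '", p, "'", call. = FALSE)
    }
    out[sp] <- if (sp %in% names(out)) out[[sp]] + coef else coef
  }
  out
}

parse_orders <- function(fields, line_no) {
  out <- integer(0)
  for (f in fields) {
    m <- regmatches(f, regexec("^order\\(([A-Za-z_.][A-Za-z0-9_.]*)\\)[[:space:]]*=[[:space:]]*([0-9]+)$",
                               trimws(f)))[[1]]
    if (length(m) != 3L)
      stop("parse error on line ", line_no, ": unknown annotation '", trimws(f), "'",
           call. = FALSE)
    out[m[2]] <- as.integer(m[3])
  }
  out
}

#' Parse a mass action model from its plain-text reaction format
#'
#' One reaction per line: `"A + 2 B -> C ; k"`. The source/sink token
#' `"Ø"` (or `"0"`) may stand on either side of the arrow; it is not a
#' species. Reversible reactions use `"<->"` and either two rate symbols
#' (`"; kf, kr"`) or one symbol, which is expanded to `<symbol>_f` and
#' `<symbol>_r`. Kinetic orders default to reactant stoichiometry and can be
#' overridden with trailing annotations, e.g. `"; order(B) = 2"`. Lines
#' starting with `#` are comments. An optional directive `species: A B C`
#' fixes the species ordering (and rejects duplicates); otherwise species are
#' ordered by first appearance.
#'
#' @param text character scalar (or vector of lines) holding the document.
#' @return A `mass_action_model` with species, reactions, the stoichiometric
#'   matrix `N` (entries \eqn{s^P - s^R}) and the mass-action velocity
#'   structure \eqn{v_j = k_j \prod_i x_i^{c_{ij}}}.
#' @examples
#' m <- parse_model("
#'   E + S -> ES ; k1
#'   ES -> E + S ; k2
#'   ES -> E + P ; k3
#'   Ø -> S   ; k4
#'   P -> Ø   ; k5")
#' m$species
#' stoichiometric_matrix(m)
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  declared <- NULL
  species <- character(0)
  reactions <- list()
  note_species <- function(sp, line_no) {
    for (s in sp) {
      if (!is.null(declared) && !(s %in% declared))
        stop("parse error on line ", line_no, ": species '", s,
             "' not in the species: declaration", call. = FALSE)
      if (!(s %in% species)) species <<- c(species, s)
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^species[[:space:]]*:", ln)) {
      decl <- strsplit(trimws(sub("^species[[:space:]]*:", "", ln)), "[[:space:],]+")[[1]]
      decl <- decl[decl != ""]
      if (anyDuplicated(decl))
        stop("parse error on line ", i, ": duplicate species '",
             decl[duplicated(decl)][1], "'", call. = FALSE)
      declared <- decl
      species <- decl
      next
    }
    fields <- trimws(strsplit(ln, ";", fixed = TRUE)[[1]])
    if (length(fields) < 2L)
      stop("parse error on line ", i, ": expected '<reaction> ; <rate>' in '",
           trimws(lines_raw[i]), "'", call. = FALSE)
    eq <- fields[1]
    reversible <- grepl("<->", eq, fixed = TRUE)
    arrow <- if (reversible) "<->" else "->"
    if (!grepl(arrow, eq, fixed = TRUE))
      stop("parse error on line ", i, ": no reaction arrow", call. = FALSE)
    sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
    if (length(sides) == 1L && endsWith(trimws(eq), arrow))
      stop("parse error on line ", i,
           ": empty reaction side (use \u00d8 or 0 for a source/sink)",
           call. = FALSE)
    if (length(sides) != 2L)
      stop("parse error on line ", i, ": malformed reaction", call. = FALSE)
    lhs <- parse_side(sides[1], i)
    rhs <- parse_side(sides[2], i)
    if (length(lhs) == 0L && length(rhs) == 0L)
      stop("parse error on line ", i,
           ": reaction with empty reactant and product sides", call. = FALSE)
    rates <- trimws(strsplit(fields[2], ",", fixed = TRUE)[[1]])
    rates <- rates[rates != ""]
    bad <- rates[!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", rates)]
    if (length(bad))
      stop("parse error on line ", i, ": invalid rate symbol '", bad[1], "'",
           call. = FALSE)
    orders <- if (length(fields) > 2L) parse_orders(fields[-(1:2)], i) else integer(0)
    note_species(names(lhs), i)
    note_species(names(rhs), i)
    if (length(orders)) note_species(names(orders), i)
    if (reversible) {
      if (!(length(rates) %in% c(1L, 2L)))
        stop("parse error on line ", i,
             ": reversible reaction needs one or two rate symbols", call. = FALSE)
      if (length(rates) == 1L) rates <- paste0(rates, c("_f", "_r"))
      if (length(orders))
        stop("parse error on line ", i,
             ": kinetic-order annotations are not supported on reversible lines; ",
             "write the two irreversible reactions explicitly", call. = FALSE)
      reactions[[length(reactions) + 1L]] <-
        list(reactants = lhs, products = rhs, orders = lhs, rate = rates[1],
             line = i, reversible_pair = length(reactions) + 2L)
      reactions[[length(reactions) + 1L]] <-
        list(reactants = rhs, products = lhs, orders = rhs, rate = rates[2],
             line = i, reversible_pair = length(reactions))
    } else {
      if (length(rates) != 1L)
        stop("parse error on line ", i, ": expected exactly one rate symbol",
             call. = FALSE)
      ord <- lhs
      if (length(orders)) ord[names(orders)] <- orders
      ord <- ord[ord > 0L]
      reactions[[length(reactions) + 1L]] <-
        list(reactants = lhs, products = rhs, orders = ord, rate = rates[1],
             line = i, reversible_pair = NA_integer_)
    }
  }
  if (length(reactions) == 0L) stop("no reactions", call. = FALSE)
  rates <- vapply(reactions, `[[`, character(1), "rate")
  if (anyDuplicated(rates))
    stop("duplicate rate symbol '", rates[duplicated(rates)][1], "'", call. = FALSE)
  clash <- intersect(rates, species)
  if (length(clash))
    stop("name '", clash[1], "' used as both species and rate symbol", call. = FALSE)
  model <- structure(
    list(species = species, reactions = reactions, rates = rates),
    class = "mass_action_model")
  model$N <- build_stoichiometric_matrix(model)
  zero_cols <- which(colSums(abs(model$N)) == 0)
  if (length(zero_cols))
    stop("reaction ", zero_cols[1], " ('", rates[zero_cols[1]],
         "') is a pure pass-through: its stoichiometric column is zero",
         call. = FALSE)
  model
}

#' Read a mass action model from a reaction-format file
#' @param path file path.
#' @return a `mass_action_model`; see [parse_model()].
#' @export
read_model <- function(path) parse_model(readLines(path, warn = FALSE))

build_stoichiometric_matrix <- function(model) {
  N <- matrix(0L, length(model$species), length(model$reactions),
              dimnames = list(model$species, model$rates))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in names(r$reactants)) N[s, j] <- N[s, j] - r$reactants[[s]]
    for (s in names(r$products)) N[s, j] <- N[s, j] + r$products[[s]]
  }
  N
}

#' Stoichiometric matrix of a model
#'
#' Entry `(i, j)` is the net production \eqn{s^P_{ij} - s^R_{ij}} of species
#' `i` by reaction `j`, so that the mass balance reads `dx/dt = N v(x)`.
#'
#' @param model a `mass_action_model`.
#' @return integer matrix, species by reactions.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "mass_action_model"))
  model$N
}

# internal: velocity j as a polynomial in species and rate symbols
velocity_poly <- function(model, j) {
  r <- model$reactions[[j]]
  expo <- c(stats::setNames(1L, r$rate), r$orders)
  poly_monomial(1, expo)
}

#' Mass-action velocity vector
#'
#' @param model a `mass_action_model`.
#' @return named character vector of the symbolic velocities
#'   \eqn{v_j = k_j \prod_i x_i^{c_{ij}}}; a zero-order reaction has velocity
#'   equal to its bare rate constant.
#' @export
velocity_vector <- function(model) {
  stopifnot(inherits(model, "mass_action_model"))
  out <- vapply(seq_along(model$reactions), function(j)
    p_deparse(velocity_poly(model, j)), character(1))
  stats::setNames(out, model$rates)
}

# internal: time-derivative of species i assembled reaction-by-reaction
species_derivative_poly <- function(model, i) {
  acc <- poly_zero()
  for (j in seq_along(model$reactions)) {
    nij <- model$N[i, j]
    if (nij != 0) acc <- p_add(acc, p_scal(velocity_poly(model, j), nij))
  }
  acc
}

#' Test whether a model is linear in its time-varying species
#'
#' A model is linear (after freezing the species in `frozen`) when every
#' reaction converts exactly one time-varying species into exactly one other
#' (its stoichiometric column, restricted to non-frozen rows, has a single
#' `-1` and a single `+1`) and every velocity is degree 1 in the non-frozen
#' concentrations. Linear models can be handed to [transition_system()] and
#' the King-Altman solver.
#'
#' @param model a `mass_action_model`.
#' @param frozen character vector of species treated as time-invariant.
#' @return list with `linear` (flag) and `witness`, a tibble of violating
#'   reactions and reasons.
#' @export
is_linear_model <- function(model, frozen = character(0)) {
  stopifnot(inherits(model, "mass_action_model"))
  if (!all(frozen %in% model$species)) {
    stop("frozen species not in model: ",
         paste(setdiff(frozen, model$species), collapse = ", "))
  }
  varying <- setdiff(model$species, frozen)
  bad <- list()
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    col <- model$N[varying, j]
    reason <- NULL
    if (!(sum(col == -1L) == 1L && sum(col == 1L) == 1L &&
          sum(col != 0L) == 2L)) {
      reason <- "column is not a (+1, -1) transition between time-varying species"
    } else {
      deg <- sum(r$orders[intersect(names(r$orders), varying)])
      if (deg != 1L)
        reason <- paste0("velocity has degree ", deg, " in time-varying species")
      else {
        consumed <- varying[col == -1L]
        if (!identical(r$orders[intersect(names(r$orders), varying)],
                       stats::setNames(1L, consumed)))
          reason <- "velocity does not depend linearly on the consumed species"
      }
    }
    if (!is.null(reason))
      bad[[length(bad) + 1L]] <- tibble::tibble(
        reaction = j, rate = r$rate, reason = reason)
  }
  witness <- if (length(bad)) dplyr::bind_rows(bad) else
    tibble::tibble(reaction = integer(0), rate = character(0), reason = character(0))
  list(linear = nrow(witness) == 0L, witness = witness)
}

#' Transition system of a linear model
#'
#' For a linear model, every reaction is a transition between two time-varying
#' species at a pseudo-first-order rate \eqn{\kappa} (the rate constant times
#' any frozen concentrations in the velocity). The matrix `K` holds
#' \eqn{\kappa_{ij}} off the diagonal and minus the column sums on it, so that
#' the steady state equation is `K x = 0`; each transition is also an edge of
#' a directed graph.
#'
#' @inheritParams is_linear_model
#' @return a `transition_system`: species, symbolic `K`, an edge tibble and an
#'   igraph graph, plus a `disjoint` flag for weakly disconnected networks.
#' @export
transition_system <- function(model, frozen = character(0)) {
  lin <- is_linear_model(model, frozen)
  if (!lin$linear) {
    stop("model is not linear under the given frozen set; ",
         "use the py-substitution engine (solve_steady_state) instead. First violation: ",
         lin$witness$reason[1])
  }
  varying <- setdiff(model$species, frozen)
  n <- length(varying)
  K <- rf_matrix(n, n)
  dimnames(K) <- list(varying, varying)
  edges <- list()
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    col <- model$N[varying, j]
    from <- varying[col == -1L]
    to <- varying[col == 1L]
    kap_expo <- c(stats::setNames(1L, r$rate), r$orders[setdiff(names(r$orders), from)])
    kappa <- rf(poly_monomial(1, kap_expo))
    K[[to, from]] <- rf_add(K[[to, from]], kappa)
    K[[from, from]] <- rf_sub(K[[from, from]], kappa)
    edges[[length(edges) + 1L]] <- tibble::tibble(
      from = from, to = to, reaction = j, rate = r$rate,
      kappa = rf_deparse(kappa))
  }
  edges <- dplyr::bind_rows(edges)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = varying, directed = TRUE)
  out <- structure(
    list(species = varying, K = K, edges = edges, graph = g,
         kappas = lapply(seq_len(nrow(edges)), function(i) {
           r <- model$reactions[[edges$reaction[i]]]
           from <- edges$from[i]
           rf(poly_monomial(1, c(stats::setNames(1L, r$rate),
                                 r$orders[setdiff(names(r$orders), from)])))
         }),
         disjoint = !igraph::is_connected(g, mode = "weak")),
    class = "transition_system")
  out
}

#' @export
print.mass_action_model <- function(x, ...) {
  cat("mass_action_model: ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("species:  ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("rates:    ", paste(x$rates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.transition_system <- function(x, ...) {
  cat("transition_system on ", length(x$species), " species (",
      nrow(x$edges), " transitions", if (x$disjoint) ", DISJOINT", ")\n", sep = "")
  print(rf_mat_deparse(x$K))
  invisible(x)
}

#' Re-pair expanded reversible reactions
#'
#' [parse_model()] expands `"<->"` into two irreversible reactions. This
#' helper recovers the pairing, for round-trip checks and reporting.
#'
#' @param model a `mass_action_model`.
#' @return tibble with one row per reversible pair (columns `forward`,
#'   `reverse`).
#' @export
reversible_pairs <- function(model) {
  stopifnot(inherits(model, "mass_action_model"))
  idx <- which(vapply(model$reactions,
                      function(r) !is.na(r$reversible_pair), logical(1)))
  done <- logical(length(model$reactions))
  out <- list()
  for (j in idx) {
    if (done[j]) next
    k <- model$reactions[[j]]$reversible_pair
    done[c(j, k)] <- TRUE
    out[[length(out) + 1L]] <- tibble::tibble(forward = min(j, k),
                                              reverse = max(j, k))
  }
  dplyr::bind_rows(c(out, list(tibble::tibble(forward = integer(0),
                                              reverse = integer(0)))))
}
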