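# King-Altman solution of linear models: enumeration of rooted spanning-tree
# patterns, principal minors, normalized steady-state concentrations, and the
# equivalence check against py-substitution solutions.

#' Enumerate King-Altman patterns (arborescences into a root)
#'
#' A King-Altman pattern for root species `r` is a directed spanning tree of
#' the transition graph with every edge oriented towards `r`: each non-root
#' vertex has out-degree 1, the root out-degree 0, and there are no cycles.
#' The sum over patterns of the edge rate products gives the principal minor
#' proportional to the root's steady-state concentration.
#'
#' @param ts a `transition_system`.
#' @param root species name.
#' @return list of patterns, each an integer vector of edge indices into
#'   `ts$edges`.
#' @export
enumerate_patterns <- function(ts, root) {
  stopifnot(inherits(ts, "transition_system"))
  if (ts$disjoint)
    stop("transition graph is disconnected (disjoint network); ",
         "no spanning patterns exist")
  stopifnot(root %in% ts$species)
  n <- length(ts$species)
  verts <- ts$species
  out_edges <- lapply(verts, function(v) which(ts$edges$from == v))
  names(out_edges) <- verts
  nonroot <- setdiff(verts, root)
  patterns <- list()
  succ_edge <- stats::setNames(rep(NA_integer_, length(nonroot)), nonroot)
  recurse <- function(i) {
    if (i > length(nonroot)) {
      patterns[[length(patterns) + 1L]] <<- unname(succ_edge)
      return(invisible(NULL))
    }
    v <- nonroot[i]
    for (e in out_edges[[v]]) {
      # acyclicity: follow already-chosen successors from the edge head; if
      # the walk returns to v the choice closes a cycle
      cur <- ts$edges$to[e]
      ok <- TRUE
      while (cur != root && cur != v) {
        nxt <- succ_edge[cur]
        if (is.na(nxt)) break
        cur <- ts$edges$to[nxt]
      }
      if (cur == v) ok <- FALSE
      if (!ok) next
      succ_edge[v] <<- e
      recurse(i + 1L)
      succ_edge[v] <<- NA_integer_
    }
  }
  recurse(1L)
  # deduplicate by edge set
  keys <- vapply(patterns, function(p) paste(sort(p), collapse = ","), character(1))
  patterns[!duplicated(keys)]
}

# sum over patterns of the product of edge transition rates
pattern_sum <- function(ts, root) {
  pats <- enumerate_patterns(ts, root)
  acc <- rf_zero()
  for (p in pats) {
    term <- rf_one()
    for (e in p) term <- rf_mul(term, ts$kappas[[e]])
    acc <- rf_add(acc, term)
  }
  list(sum = acc, n_patterns = length(pats))
}

# principal minor of K by determinant (delete row and column i); by the
# matrix-tree theorem det(K[-i,-i]) = (-1)^(n-1) * pattern_sum(i)
principal_minor_det <- function(ts, i) {
  K <- ts$K
  rf_det(K[-i, -i, drop = FALSE])
}

#' Steady state of a linear model by the King-Altman method
#'
#' Each species' steady-state concentration is proportional to its principal
#' minor, computed as the pattern sum over its King-Altman patterns, and the
#' concentrations are normalized so they sum to the total-concentration
#' symbol.
#'
#' @param ts a `transition_system`.
#' @param total_symbol name of the conserved total (default `"x_total"`).
#' @return a `king_altman_result` with `patterns`, `minors` (pattern-sum
#'   form), `concentrations` (normalized expressions) and the normalization
#'   symbol.
#' @export
ka_steady_state <- function(ts, total_symbol = "x_total") {
  stopifnot(inherits(ts, "transition_system"))
  n <- length(ts$species)
  minors <- vector("list", n)
  pats <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- pattern_sum(ts, ts$species[i])
    minors[[i]] <- ps$sum
    pats[[i]] <- enumerate_patterns(ts, ts$species[i])
  }
  names(minors) <- names(pats) <- ts$species
  denom <- Reduce(rf_add, minors)
  if (rf_is_zero(denom))
    stop("degenerate network: all King-Altman minors are zero")
  conc <- lapply(minors, function(m)
    rf_mul(rf_sym(total_symbol), rf_div(m, denom)))
  structure(list(species = ts$species, patterns = pats, minors = minors,
                 concentrations = conc, normalization = total_symbol,
                 ts = ts),
            class = "king_altman_result")
}

#' @export
print.king_altman_result <- function(x, ...) {
  cat("king_altman_result on ", length(x$species), " species (",
      paste(vapply(x$patterns, length, integer(1)), collapse = "/"),
      " patterns per root)\n", sep = "")
  for (s in x$species) {
    cat("  ", s, " = ", rf_deparse(x$concentrations[[s]]), "\n", sep = "")
  }
  invisible(x)
}

#' Check equivalence of King-Altman and py-substitution solutions
#'
#' The two methods normalize differently: King-Altman fixes the total
#' concentration, py-substitution expresses every enzyme form in terms of the
#' one left independent. Imposing the same total on the py solution must make
#' every concentration identical; the certificate is the simplified
#' difference, which has to vanish symbolically for every species.
#'
#' @param ka a `king_altman_result`.
#' @param py a `steady_state_solution` for the same linear model (the frozen
#'   species and rate constants must be P symbols of the py solution).
#' @return list with `equivalent` flag and a per-species tibble of
#'   certificates.
#' @export
equivalence_check <- function(ka, py) {
  stopifnot(inherits(ka, "king_altman_result"),
            inherits(py, "steady_state_solution"))
  sp <- ka$species
  if (!all(sp %in% names(py$sigma)))
    stop("structural mismatch: species ", paste(setdiff(sp, names(py$sigma)),
                                                collapse = ", "),
         " missing from the py-substitution solution")
  # impose sum(x) = total on the py solution: scale by total / sum(sigma(x))
  tot <- Reduce(rf_add, lapply(sp, function(s) py$sigma[[s]]))
  if (rf_is_zero(tot)) stop("degenerate py solution: concentrations sum to zero")
  scale <- rf_div(rf_sym(ka$normalization), tot)
  rows <- lapply(sp, function(s) {
    diff <- rf_sub(rf_mul(scale, py$sigma[[s]]), ka$concentrations[[s]])
    tibble::tibble(species = s, certificate = rf_deparse(diff),
                   zero = rf_is_zero(diff))
  })
  cert <- dplyr::bind_rows(rows)
  list(equivalent = all(cert$zero), certificate = cert)
}
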