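# Independent oracles used across the suite. These deliberately avoid the
# package's own symbolic path: numeric linear algebra, brute-force
# enumeration, and closed forms.

# numeric check that C %*% B == 0 at random positive values of the P symbols
expect_null_space_numeric <- function(system, seed = 1) {
  set.seed(seed)
  syms <- unique(unlist(lapply(system$C, pysub:::rf_vars)))
  q <- system$q
  for (rep in 1:3) {
    vals <- stats::setNames(runif(length(syms), 0.5, 2), syms)
    Cn <- pysub:::rf_mat_eval(system$C, vals)
    for (k in seq_len(q)) {
      ucol <- vapply(seq_len(nrow(system$B)), function(i)
        pysub:::rf_eval(system$B[[i, k]], vals), numeric(1))
      expect_lt(max(abs(Cn %*% ucol)), 1e-8)
    }
  }
}

# brute-force arborescence enumeration: all (n-1)-subsets of edges such that
# each non-root vertex has out-degree exactly 1 and the subgraph is acyclic
brute_force_patterns <- function(edges, vertices, root) {
  n <- length(vertices)
  idx <- utils::combn(nrow(edges), n - 1L, simplify = FALSE)
  keep <- Filter(function(sel) {
    sub <- edges[sel, , drop = FALSE]
    outdeg <- table(factor(sub$from, levels = vertices))
    if (outdeg[[root]] != 0) return(FALSE)
    if (any(outdeg[setdiff(vertices, root)] != 1)) return(FALSE)
    g <- igraph::graph_from_data_frame(sub[, c("from", "to")],
                                       vertices = vertices)
    igraph::is_dag(g)
  }, idx)
  keep
}

# closed-form steady state of the open Michaelis-Menten model given all five
# rate constants and the conserved total enzyme
omm_closed_form <- function(k, e_total) {
  ES <- k[["k4"]] / k[["k3"]]
  E <- e_total - ES
  S <- (k[["k2"]] + k[["k3"]]) * ES / (k[["k1"]] * E)
  P <- k[["k3"]] * ES / k[["k5"]]
  c(E = E, S = S, ES = ES, P = P)
}

# grid-scan threshold oracle for the toy switch
toy_grid_threshold <- function(model, real, event, lo = 1.2, hi = 2.6,
                               n = 200) {
  grid <- exp(seq(log(lo), log(hi), length.out = n))
  for (f in grid) {
    tr <- simulate_perturbation(model, real,
                                list(quantity = "S", fold = f))
    if (event(tr)) return(f)
  }
  NA_real_
}

toy_event <- function(traj) any(traj$A > 5)
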