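# py-substitution engine: partition validation, pseudospecies, coefficient
# systems, dependency maps, independent-target selection, constraint
# resolution, composition and verification

test_that("partition validation measures Y-degree per velocity", {
  omm <- fixture("omm1")
  rep1 <- validate_partition(omm$model, omm$phi)
  expect_true(attr(rep1, "ok"))
  expect_true(all(rep1$degree == 1L))
  # two bound Y concentrations give a degree-2 violation on the binding step
  fum <- fixture("fum1")$model
  phi_bad <- partition_map(fum, Y = c("E", "F"))
  rep2 <- validate_partition(fum, phi_bad)
  expect_false(attr(rep2, "ok"))
  expect_true(any(rep2$degree == 2L & grepl("E", rep2$offending)))
  # synthesis rate constant in P leaves a degree-0 velocity, with suggestion
  omm3 <- fixture("omm3")
  rep3 <- validate_partition(omm3$model, omm3$phi)
  expect_identical(rep3$degree[rep3$rate == "k4"], 0L)
  expect_match(rep3$suggestion[rep3$rate == "k4"], "pseudospecies")
  # non-bijective partitions are errors
  expect_error(partition_map(omm$model, Y = c("k1", "k1")), "bijection")
  expect_error(partition_map(omm$model, Y = "k1", P = "k2"), "total")
})

test_that("pseudospecies restore degree-1 homogeneity", {
  omm3 <- fixture("omm3")
  aug <- introduce_pseudospecies(omm3$model, omm3$phi, 4L)
  expect_identical(aug$constraint$type, "one")
  expect_true(attr(validate_partition(aug$model, aug$phi), "ok"))
  omm4 <- fixture("omm4")
  aug4 <- introduce_pseudospecies(omm4$model, omm4$phi, 3L)
  expect_identical(aug4$constraint$type, "square")
  expect_identical(aug4$constraint$target, "ES")
  expect_true(attr(validate_partition(aug4$model, aug4$phi), "ok"))
  # bilinear violations require reassignment, not a pseudospecies
  fum <- fixture("fum1")$model
  phi_bad <- partition_map(fum, Y = c("E", "F"))
  expect_error(introduce_pseudospecies(fum, phi_bad, 1L), "bilinear")
})

test_that("the homogeneous OMM coefficient system has rank 3, free columns 2 and 5", {
  omm <- fixture("omm1")
  sys <- coefficient_matrix(omm$model, omm$phi)
  expect_identical(dim(sys$C), c(4L, 5L))
  expect_identical(sys$rank, 3L)
  expect_identical(sys$q, 2L)
  expect_identical(sys$free, c(2L, 5L))
  expect_null_space_numeric(sys)
})

test_that("a full-column-rank (acyclic) system admits only the trivial steady state", {
  chain <- parse_model("A -> B ; k1\nB -> C ; k2\nC -> D ; k3")
  phi <- partition_map(chain, Y = c("k1", "k2", "k3"))
  expect_error(coefficient_matrix(chain, phi), "trivial steady state")
  # whereas a single reversible pair already creates a cycle and nullity > 0
  omm <- fixture("omm1")
  expect_gt(coefficient_matrix(omm$model, omm$phi)$q, 0L)
})

test_that("dependency map agrees with an independent numeric solve", {
  for (s in 1:5) {
    m <- random_linear_model(5, 6 + (s %% 4), seed = s)
    phi <- partition_map(m, Y = m$rates)
    sys <- coefficient_matrix(m, phi)
    expect_identical(sys$q, length(m$rates) - sys$rank)
    expect_null_space_numeric(sys, seed = s)
    dep <- dependency_map(sys)
    # psi at u = e_k reproduces column k of B
    set.seed(s)
    syms <- unique(unlist(lapply(sys$C, pysub:::rf_vars)))
    vals <- stats::setNames(runif(length(syms), 0.5, 2), syms)
    for (k in seq_len(sys$q)) {
      uv <- stats::setNames(as.numeric(seq_len(sys$q) == k), dep$u_symbols)
      for (i in seq_along(sys$Y)) {
        got <- pysub:::rf_eval(dep$psi[[i]], c(vals, uv))
        want <- pysub:::rf_eval(sys$B[[i, k]], vals)
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("independent-target selection accepts invertible rows and rejects others", {
  f2 <- fixture("fum2")
  res <- solve_steady_state(f2$model, f2$phi)
  sys <- res$system
  sel <- select_independent(sys, c(3L, 5L, 6L, 7L, 10L))
  expect_true(sel$accepted)
  # the selected targets become their own symbols in ybar
  for (tg in sel$targets) {
    expect_identical(pysub:::rf_deparse(sel$ybar[[tg]]), tg)
  }
  # and C ybar = 0 still holds numerically
  set.seed(1)
  syms <- unique(unlist(c(lapply(sys$C, pysub:::rf_vars), sys$Y)))
  vals <- stats::setNames(runif(length(syms), 0.5, 2), syms)
  Cn <- pysub:::rf_mat_eval(sys$C, vals)
  yv <- vapply(sys$Y, function(q_) pysub:::rf_eval(sel$ybar[[q_]], vals),
               numeric(1))
  expect_lt(max(abs(Cn %*% yv)), 1e-7)
  # a dependent row set is rejected, carrying the zero determinant
  dup <- select_independent(sys, c(1L, 2L, 3L, 4L, 5L))
  if (!dup$accepted) expect_true(pysub:::rf_is_zero(dup$det))
  expect_error(select_independent(sys, c(1L, 2L)), "exactly q")
})

test_that("q = 1 selection reduces to scalar inversion", {
  f1 <- fixture("fum1")
  sys <- solve_steady_state(f1$model, f1$phi)$system
  expect_identical(sys$q, 1L)
  for (i in seq_along(sys$Y)) {
    sel <- select_independent(sys, i)
    nonzero <- !pysub:::rf_is_zero(sys$B[[i, 1L]])
    expect_identical(sel$accepted, nonzero)
  }
})

test_that("admissible-partition counts match brute-force determinant enumeration", {
  # all-ones column: every 1x1 submatrix is invertible
  m <- parse_model("A -> B ; k1\nB -> A ; k2")
  phi <- partition_map(m, Y = c("A", "B"))
  sys <- coefficient_matrix(m, phi)
  expect_identical(sys$q, 1L)
  expect_identical(count_admissible_partitions(sys),
                   sum(vapply(seq_len(nrow(sys$B)), function(i)
                     !pysub:::rf_is_zero(sys$B[[i, 1]]), logical(1))))
  # random systems: compare against exhaustive symbolic determinants
  for (s in 1:3) {
    mm <- random_linear_model(4, 6, seed = s)
    sys2 <- coefficient_matrix(mm, partition_map(mm, Y = mm$rates))
    brute <- 0L
    for (rows in utils::combn(length(sys2$Y), sys2$q, simplify = FALSE)) {
      d <- pysub:::rf_det(sys2$B[rows, , drop = FALSE])
      if (!pysub:::rf_is_zero(d)) brute <- brute + 1L
    }
    expect_identical(count_admissible_partitions(sys2), brute)
  }
})

test_that("sublinear constraint resolves to a single branch pinning one coefficient", {
  omm3 <- fixture("omm3")
  res <- solve_steady_state(omm3$model, omm3$phi)
  expect_identical(res$system$q, 2L)          # two-dimensional null space
  expect_identical(length(res$branches), 1L)  # one linear branch
  sol <- res$branches[[1]]
  # the synthesis rate constant stays independent
  expect_true("k4" %in% sol$independents)
  expect_identical(length(sol$dependents), 3L)
})

test_that("superlinear constraint is a product relation; elimination choice immaterial", {
  omm4 <- fixture("omm4")
  phi <- pysub:::linearize_partition(omm4$model, omm4$phi)
  sys <- coefficient_matrix(omm4$model, phi)
  dep <- dependency_map(sys)
  con <- phi$constraints[[1]]
  expr <- pysub:::constraint_rf(con, dep$psi)
  # the constraint couples one bare u to the square of another
  us <- intersect(dep$u_symbols, pysub:::p_vars(expr$num))
  expect_identical(length(us), 2L)
  degs <- vapply(us, function(u) pysub:::p_deg(expr$num, u), numeric(1))
  expect_setequal(degs, c(1, 2))
  branches <- resolve_constraints(dep, phi$constraints)
  expect_identical(length(branches), 1L)
  sol <- compose_and_verify(omm4$model, phi, dep, branches[[1]])
  expect_identical(length(sol$dependents), 3L)
  # the squared concentration stays an independent quantity
  expect_true("ES" %in% sol$independents)
})

test_that("composition verifies a zero residual and detects corruption", {
  omm <- fixture("omm1")
  phi <- omm$phi
  sys <- coefficient_matrix(omm$model, phi)
  dep <- dependency_map(sys)
  sol <- compose_and_verify(omm$model, phi, dep)
  expect_true(sol$verified)
  # deliberate sign flip in one dependent expression is caught
  bad <- dep
  bad$psi[["k1"]] <- pysub:::rf_neg(bad$psi[["k1"]])
  expect_error(compose_and_verify(omm$model, phi, bad),
               "nonzero steady-state residual")
})

test_that("independent count is |X| + |R| - rank(N) for every strategy", {
  for (nm in c("omm1", "omm2", "omm3", "omm4", "fum2", "toy_switch")) {
    f <- fixture(nm)
    res <- solve_steady_state(f$model, f$phi)
    nx <- length(f$model$species)
    nr <- length(f$model$reactions)
    rk <- qr(stoichiometric_matrix(f$model))$rank
    for (b in res$branches) {
      expect_identical(length(b$independents), nx + nr - rk,
                       info = nm)
    }
  }
})

test_that("all four OMM strategies yield exactly three dependent quantities", {
  deps <- vapply(c("omm1", "omm2", "omm3", "omm4"), function(nm) {
    f <- fixture(nm)
    length(solve_steady_state(f$model, f$phi)$branches[[1]]$dependents)
  }, integer(1))
  expect_identical(unname(deps), rep(3L, 4L))
})

test_that("the homogeneous strategy recovers the rate-cone construction", {
  # with P = concentrations and Y = rate constants, the solution space is the
  # null space of N diag(monomials); check numerically against base R
  omm <- fixture("omm1")
  sys <- coefficient_matrix(omm$model, omm$phi)
  set.seed(4)
  x <- stats::setNames(runif(4, 0.5, 2), omm$model$species)
  N <- stoichiometric_matrix(omm$model)
  mono <- vapply(seq_len(5), function(j) {
    r <- omm$model$reactions[[j]]
    if (length(r$orders)) prod(x[names(r$orders)]^r$orders) else 1
  }, numeric(1))
  Cn <- N %*% diag(mono)
  for (k in seq_len(sys$q)) {
    v <- vapply(seq_len(5), function(i) pysub:::rf_eval(sys$B[[i, k]], x),
                numeric(1))
    expect_lt(max(abs(Cn %*% v)), 1e-9)
  }
})

test_that("solution tables and exports are deterministic", {
  f <- fixture("omm1")
  t1 <- tidy(solve_steady_state(f$model, f$phi)$branches[[1]])
  t2 <- tidy(solve_steady_state(f$model, f$phi)$branches[[1]])
  expect_identical(t1, t2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  export_solution(solve_steady_state(f$model, f$phi)$branches[[1]], tsv, js)
  expect_identical(readLines(tsv)[1], "quantity\tkind\tclass\texpression")
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
})
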