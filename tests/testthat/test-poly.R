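# internal symbolic kernel: exact arithmetic, exact division, fraction-free
# elimination, modular screening

P <- function(s) pysub:::poly_sym(s)
PC <- function(c) pysub:::poly_const(c)

random_poly <- function(syms, nterms, maxdeg = 2) {
  monos <- lapply(seq_len(nterms), function(i) {
    k <- sample(0:length(syms), 1)
    if (k == 0) return(stats::setNames(integer(0), character(0)))
    picked <- sample(syms, k)
    stats::setNames(sample.int(maxdeg, k, replace = TRUE), picked)
  })
  pysub:::new_poly(sample(-5:5, nterms, replace = TRUE), monos)
}

test_that("polynomial ring identities hold on random operands", {
  set.seed(42)
  syms <- c("a", "b", "c")
  for (i in 1:25) {
    x <- random_poly(syms, sample(1:5, 1))
    y <- random_poly(syms, sample(1:5, 1))
    z <- random_poly(syms, sample(1:5, 1))
    # commutativity / distributivity / subtraction inverse
    expect_identical(pysub:::p_deparse(pysub:::p_mul(x, y)),
                     pysub:::p_deparse(pysub:::p_mul(y, x)))
    lhs <- pysub:::p_mul(x, pysub:::p_add(y, z))
    rhs <- pysub:::p_add(pysub:::p_mul(x, y), pysub:::p_mul(x, z))
    expect_true(pysub:::p_is_zero(pysub:::p_sub(lhs, rhs)))
    expect_true(pysub:::p_is_zero(pysub:::p_sub(x, x)))
    # evaluation is a homomorphism
    vals <- stats::setNames(runif(3, -2, 2), syms)
    expect_equal(pysub:::p_eval(pysub:::p_mul(x, y), vals),
                 pysub:::p_eval(x, vals) * pysub:::p_eval(y, vals),
                 tolerance = 1e-8)
  }
})

test_that("exact division inverts multiplication and rejects non-divisors", {
  set.seed(7)
  syms <- c("a", "b", "c")
  for (i in 1:25) {
    x <- random_poly(syms, sample(1:4, 1))
    y <- random_poly(syms, sample(1:4, 1))
    if (pysub:::p_is_zero(x) || pysub:::p_is_zero(y)) next
    prod <- pysub:::p_mul(x, y)
    q <- pysub:::p_div_exact(prod, y)
    expect_false(is.null(q))
    expect_true(pysub:::p_is_zero(pysub:::p_sub(q, x)))
  }
  # a+b does not divide a^2 + b
  num <- pysub:::p_add(pysub:::p_pow(P("a"), 2), P("b"))
  den <- pysub:::p_add(P("a"), P("b"))
  expect_null(pysub:::p_div_exact(num, den))
})

test_that("rational arithmetic cancels and zero-tests exactly", {
  a <- P("a"); b <- P("b")
  x <- pysub:::rf(pysub:::p_mul(a, b), pysub:::p_mul(b, b))  # a*b/b^2 = a/b
  expect_identical(pysub:::rf_deparse(x), "a/b")
  # (a/b + b/a) * a*b == a^2 + b^2
  s <- pysub:::rf_add(pysub:::rf(a, b), pysub:::rf(b, a))
  lhs <- pysub:::rf_mul(s, pysub:::rf(pysub:::p_mul(a, b)))
  rhs <- pysub:::rf(pysub:::p_add(pysub:::p_pow(a, 2), pysub:::p_pow(b, 2)))
  expect_true(pysub:::rf_equal(lhs, rhs))
  expect_true(pysub:::rf_is_zero(pysub:::rf_sub(x, x)))
})

test_that("fraction-free Jordan matches numeric rank and null space", {
  set.seed(11)
  for (i in 1:20) {
    nr <- sample(3:5, 1); nc <- sample(3:6, 1)
    A <- matrix(sample(-3:3, nr * nc, replace = TRUE), nr, nc)
    if (i %% 3 == 0) A[, nc] <- A[, 1] - 2 * A[, 2]
    M <- matrix(vector("list", nr * nc), nr, nc)
    for (r in seq_len(nr)) for (cn in seq_len(nc)) M[[r, cn]] <- PC(A[r, cn])
    ff <- pysub:::poly_ff_jordan(M)
    expect_identical(ff$rank, qr(A)$rank)
    nb <- pysub:::ff_null_basis(ff, nc)
    for (k in seq_along(nb$free)) {
      v <- vapply(seq_len(nc), function(r)
        pysub:::rf_eval(nb$B[[r, k]], c()), numeric(1))
      expect_lt(max(abs(A %*% v)), 1e-9)
    }
  }
})

test_that("fraction-free Jordan stays exact on generic symbolic matrices", {
  M <- matrix(vector("list", 12), 3, 4)
  for (i in 1:3) for (j in 1:4) M[[i, j]] <- P(paste0("a", i, j))
  ff <- expect_no_error(pysub:::poly_ff_jordan(M))
  expect_identical(ff$rank, 3L)
  # null vector annihilates the symbolic matrix at random numeric points
  nb <- pysub:::ff_null_basis(ff, 4)
  set.seed(3)
  vals <- stats::setNames(runif(12, 0.5, 2), paste0("a", rep(1:3, each = 4), rep(1:4, 3)))
  An <- matrix(vals[paste0("a", rep(1:3, 4), rep(1:4, each = 3))], 3, 4)
  v <- vapply(1:4, function(r) pysub:::rf_eval(nb$B[[r, 1]], vals), numeric(1))
  expect_lt(max(abs(An %*% v)), 1e-8)
})

test_that("bareiss determinant equals cofactor determinant", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    M <- matrix(vector("list", n * n), n, n)
    Mr <- matrix(vector("list", n * n), n, n)
    for (r in seq_len(n)) for (cn in seq_len(n)) {
      p <- random_poly(c("x", "y"), sample(1:2, 1), maxdeg = 1)
      M[[r, cn]] <- p
      Mr[[r, cn]] <- pysub:::as_rf(p)
    }
    d1 <- pysub:::poly_det_bareiss(M)
    d2 <- pysub:::rf_det(Mr)
    expect_true(pysub:::rf_is_zero(pysub:::rf_sub(pysub:::as_rf(d1), d2)))
  }
})

test_that("modular evaluation certifies nonzero polynomials", {
  set.seed(9)
  vals <- pysub:::mod_points(c("x", "y"), 1)
  for (i in 1:20) {
    p <- random_poly(c("x", "y"), sample(1:5, 1))
    if (pysub:::p_is_zero(p)) next
    m1 <- pysub:::p_eval_mod(p, vals)
    # the zero polynomial always maps to 0; a nonzero residue proves p != 0
    if (m1 != 0) expect_false(pysub:::p_is_zero(p))
    diff <- pysub:::p_sub(p, p)
    expect_identical(pysub:::p_eval_mod(diff, vals), 0)
  }
})

test_that("deparse is deterministic and round-trip stable", {
  x <- pysub:::p_add(pysub:::p_mul(P("beta"), P("alpha")),
                     pysub:::p_scal(pysub:::p_pow(P("alpha"), 2), -3))
  expect_identical(pysub:::p_deparse(x), pysub:::p_deparse(x))
  expect_identical(pysub:::p_deparse(x), "-3*alpha^2 + alpha*beta")
})
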