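# Exact sparse multivariate polynomial and rational-function arithmetic.
#
# Every symbolic object in the package bottoms out here. A polynomial is a
# numeric coefficient vector plus an integer exponent matrix (one row per
# term, one column per symbol, colnames = symbols in radix order), so that
# addition and multiplication are vectorized. Coefficients are integer-valued
# doubles; divisions happen only through exact polynomial division or by
# forming a rational function, so zero-tests are exact, not floating-point.

# ---- construction and canonicalisation ------------------------------------

term_keys <- function(expo) {
  n <- nrow(expo)
  if (n == 0L) return(character(0))
  if (ncol(expo) == 0L) return(rep("1", n))
  parts <- lapply(seq_len(ncol(expo)), function(j) {
    e <- expo[, j]
    s <- colnames(expo)[j]
    out <- character(n)
    pos <- e != 0L
    out[pos & e == 1L] <- paste0(s, "*")
    hi <- pos & e != 1L
    if (any(hi)) out[hi] <- paste0(s, "^", e[hi], "*")
    out
  })
  keys <- do.call(paste0, parts)
  keys <- sub("\\*$", "", keys)
  keys[keys == ""] <- "1"
  keys
}

# canonical form: drop all-zero columns, order columns, aggregate duplicate
# terms, drop zero coefficients
make_poly <- function(coefs, expo) {
  if (length(coefs) == 0L) {
    out <- list(coefs = numeric(0),
                expo = matrix(0L, 0L, 0L), keys = character(0))
    class(out) <- "pspoly"
    return(out)
  }
  if (is.null(dim(expo))) expo <- matrix(expo, nrow = length(coefs))
  keep <- colSums(abs(expo)) > 0L
  expo <- expo[, keep, drop = FALSE]
  if (ncol(expo) > 1L)
    expo <- expo[, order(colnames(expo), method = "radix"), drop = FALSE]
  keys <- term_keys(expo)
  if (anyDuplicated(keys)) {
    agg <- rowsum(coefs, keys, reorder = FALSE)
    first <- !duplicated(keys)
    expo <- expo[first, , drop = FALSE]
    keys <- keys[first]
    coefs <- as.numeric(agg[match(keys, rownames(agg)), 1L])
  }
  nz <- coefs != 0
  if (!all(nz)) {
    coefs <- coefs[nz]
    expo <- expo[nz, , drop = FALSE]
    keys <- keys[nz]
    keep <- colSums(abs(expo)) > 0L
    if (!all(keep)) {
      expo <- expo[, keep, drop = FALSE]
      keys <- term_keys(expo)
    }
  }
  out <- list(coefs = coefs, expo = expo, keys = keys)
  class(out) <- "pspoly"
  out
}

# compatibility constructor from a list of named integer exponent vectors
new_poly <- function(coefs, monos) {
  stopifnot(length(coefs) == length(monos))
  syms <- sort(unique(unlist(lapply(monos, names))), method = "radix")
  expo <- matrix(0L, length(coefs), length(syms),
                 dimnames = list(NULL, syms))
  for (i in seq_along(monos)) {
    e <- monos[[i]]
    e <- e[e != 0L]
    if (length(e)) expo[i, names(e)] <- as.integer(e)
  }
  make_poly(coefs, expo)
}

poly_zero <- function() make_poly(numeric(0), matrix(0L, 0L, 0L))
poly_const <- function(c) {
  if (c == 0) return(poly_zero())
  make_poly(c, matrix(0L, 1L, 0L))
}
poly_one <- function() poly_const(1)
poly_sym <- function(s) {
  make_poly(1, matrix(1L, 1L, 1L, dimnames = list(NULL, s)))
}
poly_monomial <- function(coef, expo) new_poly(coef, list(expo))

is_poly <- function(p) inherits(p, "pspoly")
p_is_zero <- function(p) length(p$coefs) == 0L
p_nterms <- function(p) length(p$coefs)
p_vars <- function(p) colnames(p$expo) %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# named integer exponent vector of term i
p_mono <- function(p, i) {
  e <- p$expo[i, ]
  e <- e[e != 0L]
  if (length(e)) stats::setNames(as.integer(e), names(e)) else
    stats::setNames(integer(0), character(0))
}

# align two exponent matrices on the union of their symbols
align_expo <- function(ea, eb) {
  sa <- colnames(ea) %||% character(0)
  sb <- colnames(eb) %||% character(0)
  if (identical(sa, sb)) return(list(a = ea, b = eb))
  syms <- sort(union(sa, sb), method = "radix")
  wa <- matrix(0L, nrow(ea), length(syms), dimnames = list(NULL, syms))
  wb <- matrix(0L, nrow(eb), length(syms), dimnames = list(NULL, syms))
  if (length(sa)) wa[, sa] <- ea
  if (length(sb)) wb[, sb] <- eb
  list(a = wa, b = wb)
}

# ---- ring operations ------------------------------------------------------

p_add <- function(a, b) {
  if (p_is_zero(a)) return(b)
  if (p_is_zero(b)) return(a)
  al <- align_expo(a$expo, b$expo)
  make_poly(c(a$coefs, b$coefs), rbind(al$a, al$b))
}

p_neg <- function(a) {
  a$coefs <- -a$coefs
  a
}

p_sub <- function(a, b) p_add(a, p_neg(b))

p_scal <- function(a, k) {
  if (k == 0) return(poly_zero())
  a$coefs <- a$coefs * k
  a
}

mono_mul <- function(e1, e2) {
  if (length(e1) == 0L) return(e2)
  if (length(e2) == 0L) return(e1)
  syms <- union(names(e1), names(e2))
  v <- stats::setNames(integer(length(syms)), syms)
  v[names(e1)] <- e1
  v[names(e2)] <- v[names(e2)] + e2
  v[v != 0L]
}

p_mul <- function(a, b) {
  if (p_is_zero(a) || p_is_zero(b)) return(poly_zero())
  na <- length(a$coefs); nb <- length(b$coefs)
  al <- align_expo(a$expo, b$expo)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  make_poly(a$coefs[ia] * b$coefs[ib],
            al$a[ia, , drop = FALSE] + al$b[ib, , drop = FALSE])
}

p_pow <- function(a, n) {
  stopifnot(n >= 0L)
  out <- poly_one()
  for (i in seq_len(n)) out <- p_mul(out, a)
  out
}

p_deg <- function(p, sym = NULL) {
  if (p_is_zero(p)) return(-Inf)
  if (is.null(sym)) {
    if (ncol(p$expo) == 0L) return(0)
    max(rowSums(p$expo))
  } else {
    if (!(sym %in% colnames(p$expo))) return(0)
    max(p$expo[, sym])
  }
}

p_eval <- function(p, vals) {
  if (p_is_zero(p)) return(0)
  res <- p$coefs
  for (s in colnames(p$expo)) {
    res <- res * vals[[s]]^p$expo[, s]
  }
  sum(res)
}

# coefficients of p viewed as univariate in `sym`: list indexed by degree+1
p_univariate <- function(p, sym) {
  d <- p_deg(p, sym)
  if (!is.finite(d)) d <- 0
  out <- replicate(d + 1L, poly_zero(), simplify = FALSE)
  if (p_is_zero(p)) return(out)
  degs <- if (sym %in% colnames(p$expo)) p$expo[, sym] else
    rep(0L, p_nterms(p))
  rest <- p$expo[, setdiff(colnames(p$expo), sym), drop = FALSE]
  for (k in unique(degs)) {
    sel <- degs == k
    out[[k + 1L]] <- make_poly(p$coefs[sel], rest[sel, , drop = FALSE])
  }
  out
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

# integer content of the coefficient vector (1 if any coefficient non-integral)
p_content <- function(p) {
  if (p_is_zero(p)) return(1)
  cf <- p$coefs
  if (any(abs(cf - round(cf)) > 1e-9)) return(1)
  g <- 0
  for (c in round(abs(cf))) {
    g <- gcd2(g, c)
    if (g == 1) break
  }
  if (g == 0) 1 else g
}

# common monomial factor of all terms, as a named integer vector
p_mono_content <- function(p) {
  if (p_is_zero(p) || ncol(p$expo) == 0L)
    return(stats::setNames(integer(0), character(0)))
  mins <- apply(p$expo, 2L, min)
  mins <- mins[mins > 0L]
  stats::setNames(as.integer(mins), names(mins))
}

p_div_mono <- function(p, coef, expo) {
  if (p_is_zero(p)) return(p)
  expo <- expo[expo != 0L]
  if (length(expo)) {
    if (!all(names(expo) %in% colnames(p$expo))) return(NULL)
    sub <- p$expo
    sub[, names(expo)] <- sweep(sub[, names(expo), drop = FALSE], 2L,
                                as.integer(expo))
    if (any(sub < 0L)) return(NULL)
  } else sub <- p$expo
  make_poly(p$coefs / coef, sub)
}

# leading term under true lexicographic order on the (radix-sorted) symbols
p_lead <- function(p) {
  n <- p_nterms(p)
  if (n == 1L) return(list(coef = p$coefs[1L], expo = p_mono(p, 1L)))
  cand <- seq_len(n)
  for (j in seq_len(ncol(p$expo))) {
    e <- p$expo[cand, j]
    cand <- cand[e == max(e)]
    if (length(cand) == 1L) break
  }
  i <- cand[1L]
  list(coef = p$coefs[i], expo = p_mono(p, i))
}

# exact polynomial division a / b; NULL if not exact
p_div_exact <- function(a, b) {
  if (p_is_zero(b)) stop("division by zero polynomial")
  if (p_is_zero(a)) return(poly_zero())
  if (p_nterms(b) == 1L) {
    return(p_div_mono(a, b$coefs[1L], p_mono(b, 1L)))
  }
  lb <- p_lead(b)
  qt <- poly_zero()
  r <- a
  for (guard in seq_len(p_nterms(a) * 4L + 16L)) {
    if (p_is_zero(r)) return(qt)
    lr <- p_lead(r)
    t <- mono_mul(lr$expo, -lb$expo)
    if (length(t) && any(t < 0L)) return(NULL)
    term <- poly_monomial(lr$coef / lb$coef, t)
    qt <- p_add(qt, term)
    r <- p_sub(r, p_mul(term, b))
  }
  NULL
}

p_term_order <- function(p) {
  if (ncol(p$expo) == 0L) return(seq_len(p_nterms(p)))
  do.call(order, c(lapply(seq_len(ncol(p$expo)), function(j) -p$expo[, j]),
                   list(method = "radix")))
}

p_deparse <- function(p) {
  if (p_is_zero(p)) return("0")
  ord <- p_term_order(p)
  parts <- vapply(ord, function(i) {
    cf <- p$coefs[i]
    key <- p$keys[i]
    if (key == "1") return(format(cf, digits = 15))
    mag <- if (abs(abs(cf) - 1) < 1e-12) "" else
      paste0(format(abs(cf), digits = 15), "*")
    paste0(if (cf < 0) "-" else "", mag, key)
  }, character(1))
  out <- parts[1L]
  for (s in parts[-1L]) {
    out <- if (startsWith(s, "-")) paste0(out, " - ", substring(s, 2L))
           else paste0(out, " + ", s)
  }
  out
}

# ---------------------------------------------------------------------------
# rational functions

new_rf <- function(num, den) {
  out <- list(num = num, den = den)
  class(out) <- "psrat"
  out
}

rf_reduce <- function(x) {
  num <- x$num; den <- x$den
  if (p_is_zero(num)) return(new_rf(poly_zero(), poly_one()))
  if (p_is_zero(den)) stop("zero denominator in rational function")
  # common monomial factor
  mc <- p_mono_content(num)
  md <- p_mono_content(den)
  keep <- intersect(names(mc), names(md))
  common <- pmin(mc[keep], md[keep])
  common <- common[common > 0L]
  if (length(common)) {
    num <- p_div_mono(num, 1, common)
    den <- p_div_mono(den, 1, common)
  }
  # integer content
  g <- gcd2(p_content(num), p_content(den))
  if (g > 1) {
    num <- p_scal(num, 1 / g)
    den <- p_scal(den, 1 / g)
  }
  # exact cancellation (skipped for very large operands; correctness does not
  # depend on it, zero-tests always expand the numerator)
  if (as.numeric(p_nterms(num)) * as.numeric(p_nterms(den)) <= 4096) {
    q <- p_div_exact(num, den)
    if (!is.null(q)) {
      num <- q; den <- poly_one()
    } else if (p_nterms(num) > 1L || p_nterms(den) > 1L) {
      q <- p_div_exact(den, num)
      if (!is.null(q) && p_nterms(q) == 1L) {
        num <- poly_one(); den <- q
      }
    }
  }
  # sign normalisation: leading denominator coefficient positive
  if (p_lead(den)$coef < 0) {
    num <- p_neg(num); den <- p_neg(den)
  }
  new_rf(num, den)
}

rf <- function(num, den = poly_one()) {
  if (is.numeric(num)) num <- poly_const(num)
  if (is.numeric(den)) den <- poly_const(den)
  rf_reduce(new_rf(num, den))
}

rf_sym <- function(s) new_rf(poly_sym(s), poly_one())
rf_const <- function(c) new_rf(poly_const(c), poly_one())
rf_zero <- function() new_rf(poly_zero(), poly_one())
rf_one <- function() new_rf(poly_one(), poly_one())

is_rf <- function(x) inherits(x, "psrat")
rf_is_zero <- function(x) p_is_zero(x$num)

as_rf <- function(x) {
  if (is_rf(x)) return(x)
  if (is_poly(x)) return(new_rf(x, poly_one()))
  if (is.numeric(x)) return(rf_const(x))
  stop("cannot coerce to rational function")
}

rf_add <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  if (rf_is_zero(a)) return(b)
  if (rf_is_zero(b)) return(a)
  if (identical(a$den$keys, b$den$keys) &&
      identical(a$den$coefs, b$den$coefs)) {
    return(rf_reduce(new_rf(p_add(a$num, b$num), a$den)))
  }
  rf_reduce(new_rf(p_add(p_mul(a$num, b$den), p_mul(b$num, a$den)),
                   p_mul(a$den, b$den)))
}

rf_neg <- function(a) new_rf(p_neg(a$num), a$den)
rf_sub <- function(a, b) rf_add(a, rf_neg(as_rf(b)))

rf_mul <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  if (rf_is_zero(a) || rf_is_zero(b)) return(rf_zero())
  rf_reduce(new_rf(p_mul(a$num, b$num), p_mul(a$den, b$den)))
}

rf_div <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  if (rf_is_zero(b)) stop("division by zero rational function")
  rf_reduce(new_rf(p_mul(a$num, b$den), p_mul(a$den, b$num)))
}

rf_pow <- function(a, n) {
  out <- rf_one()
  for (i in seq_len(n)) out <- rf_mul(out, a)
  out
}

rf_eval <- function(x, vals) {
  d <- p_eval(x$den, vals)
  if (d == 0) stop("division by zero while evaluating: ", rf_deparse(x))
  p_eval(x$num, vals) / d
}

rf_vars <- function(x) union(p_vars(x$num), p_vars(x$den))

rf_equal <- function(a, b) rf_is_zero(rf_sub(a, b))

rf_deparse <- function(x) {
  if (rf_is_zero(x)) return("0")
  n <- p_deparse(x$num)
  if (p_nterms(x$den) == 1L && x$den$keys[1L] == "1" &&
      x$den$coefs[1L] == 1) {
    return(n)
  }
  if (p_nterms(x$num) > 1L) n <- paste0("(", n, ")")
  d <- p_deparse(x$den)
  if (p_nterms(x$den) > 1L || sum(x$den$expo) > 1L || x$den$coefs[1L] != 1)
    d <- paste0("(", d, ")")
  paste0(n, "/", d)
}

#' @export
print.psrat <- function(x, ...) {
  cat(rf_deparse(x), "\n")
  invisible(x)
}

#' @export
print.pspoly <- function(x, ...) {
  cat(p_deparse(x), "\n")
  invisible(x)
}

# substitute rational functions for symbols in a polynomial; `env` is a named
# list sym -> psrat. Symbols absent from `env` are left in place.
p_subst <- function(p, env) {
  if (p_is_zero(p)) return(rf_zero())
  acc <- rf_zero()
  for (i in seq_along(p$coefs)) {
    e <- p_mono(p, i)
    term <- rf_const(p$coefs[i])
    if (length(e)) {
      for (s in names(e)) {
        base <- if (!is.null(env[[s]])) env[[s]] else rf_sym(s)
        term <- rf_mul(term, rf_pow(base, e[[s]]))
      }
    }
    acc <- rf_add(acc, term)
  }
  acc
}

rf_subst <- function(x, env) rf_div(p_subst(x$num, env), p_subst(x$den, env))

# ---------------------------------------------------------------------------
# rational-function matrices (stored as plain list matrices)

rf_matrix <- function(nrow, ncol) {
  m <- matrix(vector("list", nrow * ncol), nrow = nrow, ncol = ncol)
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) m[[i, j]] <- rf_zero()
  m
}

rf_mat_deparse <- function(m) {
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- rf_deparse(m[[i, j]])
  out
}

rf_mat_eval <- function(m, vals) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- rf_eval(m[[i, j]], vals)
  out
}

# Gauss-Jordan reduction to reduced row echelon form over the fraction field,
# greedy lowest-index column pivoting.
rf_rref <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pivots <- integer(0)
  r <- 1L
  for (cidx in seq_len(nc)) {
    if (r > nr) break
    prow <- 0L
    for (i in r:nr) {
      if (!rf_is_zero(m[[i, cidx]])) { prow <- i; break }
    }
    if (prow == 0L) next
    if (prow != r) {
      tmp <- m[r, ]; m[r, ] <- m[prow, ]; m[prow, ] <- tmp
    }
    piv <- m[[r, cidx]]
    for (j in seq_len(nc)) m[[r, j]] <- rf_div(m[[r, j]], piv)
    for (i in seq_len(nr)) {
      if (i == r) next
      f <- m[[i, cidx]]
      if (rf_is_zero(f)) next
      for (j in seq_len(nc)) {
        m[[i, j]] <- rf_sub(m[[i, j]], rf_mul(f, m[[r, j]]))
      }
    }
    pivots <- c(pivots, cidx)
    r <- r + 1L
  }
  list(rref = m, pivots = pivots, rank = length(pivots))
}

# special-solution null space basis from an rref: identity on free rows
rf_null_basis <- function(rr, nc) {
  pivots <- rr$pivots
  free <- setdiff(seq_len(nc), pivots)
  B <- rf_matrix(nc, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    B[[f, k]] <- rf_one()
    for (r in seq_along(pivots)) {
      B[[pivots[r], k]] <- rf_neg(rr$rref[[r, f]])
    }
  }
  list(B = B, free = free, pivots = pivots)
}

# exact symbolic determinant of an rf list matrix by cofactor expansion
rf_det <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m[[1L, 1L]])
  if (n == 2L) {
    return(rf_sub(rf_mul(m[[1, 1]], m[[2, 2]]),
                  rf_mul(m[[1, 2]], m[[2, 1]])))
  }
  acc <- rf_zero()
  sign <- 1
  for (j in seq_len(n)) {
    a <- m[[1L, j]]
    if (!rf_is_zero(a)) {
      sub <- m[-1L, -j, drop = FALSE]
      term <- rf_mul(a, rf_det(sub))
      acc <- if (sign > 0) rf_add(acc, term) else rf_sub(acc, term)
    }
    sign <- -sign
  }
  acc
}

# ---------------------------------------------------------------------------
# exact modular screening (a nonzero modular determinant certifies a nonzero
# symbolic determinant; zero is inconclusive and needs the exact route)

MOD_P <- 2147483629

mod_inv <- function(a, p = MOD_P) {
  t0 <- 0; t1 <- 1; r0 <- p; r1 <- a
  while (r1 != 0) {
    q <- floor(r0 / r1)
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  t0 %% p
}

mod_mul <- function(a, b, p = MOD_P) {
  hi <- floor(a / 94906)
  lo <- a - hi * 94906
  (((hi * b) %% p) * 94906 + lo * b) %% p
}

mod_pow <- function(a, e, p = MOD_P) {
  r <- 1
  while (e > 0) {
    if (e %% 2 == 1) r <- mod_mul(r, a, p)
    a <- mod_mul(a, a, p)
    e <- e %/% 2
  }
  r
}

p_eval_mod <- function(p_, vals, p = MOD_P) {
  if (p_is_zero(p_)) return(0)
  acc <- 0
  for (i in seq_along(p_$coefs)) {
    t <- round(p_$coefs[i]) %% p
    e <- p_mono(p_, i)
    if (length(e)) {
      for (s in names(e)) t <- mod_mul(t, mod_pow(vals[[s]], e[[s]], p), p)
    }
    acc <- (acc + t) %% p
  }
  acc
}

rf_eval_mod <- function(x, vals, p = MOD_P) {
  d <- p_eval_mod(x$den, vals, p)
  if (d == 0) return(NA_real_)
  mod_mul(p_eval_mod(x$num, vals, p), mod_inv(d, p), p)
}

det_mod <- function(m_num, p = MOD_P) {
  n <- nrow(m_num)
  det <- 1
  for (c in seq_len(n)) {
    piv <- 0L
    for (i in c:n) if (m_num[i, c] != 0) { piv <- i; break }
    if (piv == 0L) return(0)
    if (piv != c) {
      tmp <- m_num[c, ]; m_num[c, ] <- m_num[piv, ]; m_num[piv, ] <- tmp
      det <- p - det
    }
    det <- mod_mul(det, m_num[c, c], p)
    inv <- mod_inv(m_num[c, c], p)
    for (i in seq_len(n)) {
      if (i == c || m_num[i, c] == 0) next
      f <- mod_mul(m_num[i, c], inv, p)
      for (j in c:n) {
        m_num[i, j] <- (m_num[i, j] - mod_mul(f, m_num[c, j], p)) %% p
      }
    }
  }
  det
}

# ---------------------------------------------------------------------------
# fraction-free elimination over the polynomial ring (Bareiss / Montante).
# All divisions below are exact by construction, so entries stay polynomials
# of minor size instead of swelling as unreduced fractions.

p_div_assert <- function(a, b) {
  if (p_nterms(b) == 1L && b$coefs[1L] == 1 && b$keys[1L] == "1") return(a)
  q <- p_div_exact(a, b)
  if (is.null(q)) stop("internal error: inexact division in fraction-free elimination")
  q
}

# complete fraction-free Gauss-Jordan. M is a list matrix of pspoly.
# Returns list(M = reduced polynomial matrix, pivots, rank, pivot_value):
# every pivot row r has M[[r, pivots[r]]] == pivot_value, and the reduced row
# echelon form over the fraction field is M / pivot_value.
poly_ff_jordan <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  pivots <- integer(0)
  prev <- poly_one()
  r <- 1L
  for (cidx in seq_len(nc)) {
    if (r > nr) break
    prow <- 0L
    for (i in r:nr) if (!p_is_zero(M[[i, cidx]])) { prow <- i; break }
    if (prow == 0L) next
    if (prow != r) { tmp <- M[r, ]; M[r, ] <- M[prow, ]; M[prow, ] <- tmp }
    piv <- M[[r, cidx]]
    for (i in seq_len(nr)) {
      if (i == r) next
      mic <- M[[i, cidx]]
      for (j in seq_len(nc)) {
        if (j == cidx) next
        t1 <- p_mul(piv, M[[i, j]])
        t2 <- if (p_is_zero(mic)) poly_zero() else p_mul(mic, M[[r, j]])
        M[[i, j]] <- p_div_assert(p_sub(t1, t2), prev)
      }
      M[[i, cidx]] <- poly_zero()
    }
    prev <- piv
    pivots <- c(pivots, cidx)
    r <- r + 1L
  }
  list(M = M, pivots = pivots, rank = length(pivots), pivot_value = prev)
}

# null-space basis (special-solution normalization) from a fraction-free
# Jordan form: identity on free rows, -M[r, f]/pivot_value on pivot rows
ff_null_basis <- function(ff, nc) {
  pivots <- ff$pivots
  free <- setdiff(seq_len(nc), pivots)
  B <- rf_matrix(nc, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    B[[f, k]] <- rf_one()
    for (r in seq_along(pivots)) {
      B[[pivots[r], k]] <- rf(p_neg(ff$M[[r, f]]), ff$pivot_value)
    }
  }
  list(B = B, free = free, pivots = pivots)
}

# rref over the fraction field, recovered from the fraction-free form
ff_rref <- function(ff, nc) {
  nr <- nrow(ff$M)
  R <- rf_matrix(nr, nc)
  for (r in seq_along(ff$pivots)) {
    for (j in seq_len(nc)) R[[r, j]] <- rf(ff$M[[r, j]], ff$pivot_value)
  }
  R
}

# exact determinant of a square polynomial list matrix by fraction-free
# Gaussian elimination (Bareiss); returns a pspoly
poly_det_bareiss <- function(M) {
  n <- nrow(M)
  stopifnot(n == ncol(M))
  sign <- 1
  prev <- poly_one()
  for (c in seq_len(n - 1L)) {
    prow <- 0L
    for (i in c:n) if (!p_is_zero(M[[i, c]])) { prow <- i; break }
    if (prow == 0L) return(poly_zero())
    if (prow != c) { tmp <- M[c, ]; M[c, ] <- M[prow, ]; M[prow, ] <- tmp; sign <- -sign }
    piv <- M[[c, c]]
    for (i in (c + 1L):n) {
      mic <- M[[i, c]]
      for (j in (c + 1L):n) {
        t1 <- p_mul(piv, M[[i, j]])
        t2 <- if (p_is_zero(mic)) poly_zero() else p_mul(mic, M[[c, j]])
        M[[i, j]] <- p_div_assert(p_sub(t1, t2), prev)
      }
      M[[i, c]] <- poly_zero()
    }
    prev <- piv
  }
  d <- M[[n, n]]
  if (sign < 0) d <- p_neg(d)
  d
}
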