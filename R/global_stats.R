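## Align a (possibly named) value vector with a weights object and validate.
align_values <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(names(x)) && !is.null(w$ids)) {
    missing <- setdiff(w$ids, names(x))
    if (length(missing)) {
      stop("values missing for unit(s): ", paste(missing, collapse = ", "))
    }
    x <- x[w$ids]
  }
  x <- as.numeric(x)
  if (length(x) != w$n) stop("length(x) != number of units in weights")
  if (!all(is.finite(x))) stop("non-finite values in x")
  x
}

## Link matrix with any self-links removed (Eqs. with i != j).
off_diag_w <- function(w) {
  m <- w$w
  diag(m) <- 0
  m
}

#' Global Moran's I
#'
#' I = n * sum_ij w_ij (x_i - xbar)(x_j - xbar) / (S0 * sum_i (x_i - xbar)^2)
#' with S0 = sum_ij w_ij and the double sum over i != j. The S0
#' normalization makes the statistic exact for both binary and
#' row-standardized weights. Positive I indicates that similar values
#' cluster in space; the null expectation is -1/(n-1).
#'
#' @param x numeric values, one per unit (named vectors are aligned to the
#'   weight object's unit order).
#' @param w a `spatial_weights` object with at least one link.
#' @return the observed statistic (a single number).
#' @export
moran_i <- function(x, w) {
  x <- align_values(x, w)
  if (w$n < 3L) stop("Moran's I needs n >= 3")
  m <- off_diag_w(w)
  s0 <- sum(m)
  if (s0 == 0) stop("empty weights: no links between units")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("degenerate variable: x is constant")
  w$n * as.numeric(crossprod(z, m %*% z)) / (s0 * ss)
}

#' Null expectation of Moran's I
#'
#' Under the null of no spatial autocorrelation, E(I) = -1/(n-1), a small
#' negative number that approaches 0 as the number of areal units grows
#' (for n = 16 provinces, -1/15 = -0.0667).
#'
#' @param n number of areal units (>= 2).
#' @return -1/(n-1).
#' @export
expected_moran_i <- function(n) {
  if (n < 2L) stop("n must be >= 2")
  -1 / (n - 1)
}

## Cliff-Ord weight sums S0, S1, S2.
cliff_ord_sums <- function(m) {
  list(s0 = sum(m),
       s1 = sum((m + t(m))^2) / 2,
       s2 = sum((rowSums(m) + colSums(m))^2))
}

#' Null variance of Moran's I
#'
#' Closed-form Cliff-Ord variance of I under either the normality
#' assumption (x i.i.d. Gaussian) or the randomization assumption (x fixed,
#' locations exchangeable — the default throughout the package, since
#' disease rates are not Gaussian). The randomization form involves the
#' sample kurtosis b2 = m4/m2^2 of x.
#'
#' @inheritParams moran_i
#' @param assumption `"randomization"` or `"normality"`.
#' @return the variance (a single nonnegative number).
#' @export
variance_moran_i <- function(x, w, assumption = c("randomization", "normality")) {
  assumption <- match.arg(assumption)
  x <- align_values(x, w)
  n <- w$n
  if (n < 4L) stop("variance formulas need n >= 4")
  m <- off_diag_w(w)
  s <- cliff_ord_sums(m)
  ei <- expected_moran_i(n)
  if (assumption == "normality") {
    v <- (n^2 * s$s1 - n * s$s2 + 3 * s$s0^2) / (s$s0^2 * (n^2 - 1)) - ei^2
  } else {
    z <- x - mean(x)
    m2 <- mean(z^2)
    if (m2 == 0) stop("degenerate variable: x is constant")
    b2 <- mean(z^4) / m2^2
    num <- n * ((n^2 - 3 * n + 3) * s$s1 - n * s$s2 + 3 * s$s0^2) -
      b2 * ((n^2 - n) * s$s1 - 2 * n * s$s2 + 6 * s$s0^2)
    v <- num / ((n - 1) * (n - 2) * (n - 3) * s$s0^2) - ei^2
  }
  max(v, 0)
}

#' Global Getis-Ord G
#'
#' G = sum_{i != j} w_ij x_i x_j / sum_{i != j} x_i x_j for a nonnegative
#' variable and binary weights: the share of the total cross-product that
#' falls within linked pairs. G near its expectation S0/(n(n-1)) indicates
#' no concentration; larger G indicates that high values co-locate.
#' G lies in [0, 1] for binary weights.
#'
#' @inheritParams moran_i
#' @return the observed statistic.
#' @export
getis_ord_g <- function(x, w) {
  x <- align_values(x, w)
  if (w$style != "binary") stop("global G requires binary weights")
  if (any(x < 0)) stop("global G requires a nonnegative variable")
  if (all(x == 0)) stop("degenerate variable: all values zero")
  m <- off_diag_w(w)
  if (sum(m) == 0) stop("empty weights: no links between units")
  denom <- sum(x)^2 - sum(x^2)        # sum over ordered pairs i != j
  if (denom == 0) stop("degenerate variable: only one nonzero value")
  as.numeric(crossprod(x, m %*% x)) / denom
}

#' Null expectation of the global G
#'
#' @param w binary `spatial_weights`.
#' @return S0 / (n (n - 1)).
#' @export
expected_getis_ord_g <- function(w) {
  m <- off_diag_w(w)
  sum(m) / (w$n * (w$n - 1))
}

## Exact permutation variance of the global G. The denominator of G is
## invariant under relabeling of the units, so Var(G) follows from the
## second moment of the numerator N = sum_{i!=j} w_ij x_pi(i) x_pi(j),
## decomposed over index-coincidence patterns of ordered pairs
## ((i,j),(k,l)): identical, reversed, sharing exactly one index, disjoint.
## Equivalent to the Getis-Ord (1992) moment formulas.
variance_getis_ord_g <- function(x, w) {
  x <- align_values(x, w)
  n <- w$n
  if (n < 4L) stop("variance needs n >= 4")
  m <- off_diag_w(w)
  s0 <- sum(m)
  a1 <- sum(m^2)            # (k,l) = (i,j)
  a2 <- sum(m * t(m))       # (k,l) = (j,i)
  r <- rowSums(m); cs <- colSums(m)
  s_one <- sum(m * (outer(r + cs, r + cs, "+") - 2 * m - 2 * t(m)))
  s_dis <- s0^2 - a1 - a2 - s_one
  p1 <- sum(x); p2 <- sum(x^2); p3 <- sum(x^3); p4 <- sum(x^4)
  # ordered sums over distinct indices
  d2 <- p1^2 - p2
  d4 <- p1^4 - 6 * p1^2 * p2 + 3 * p2^2 + 8 * p1 * p3 - 6 * p4
  sq_pair <- p2^2 - p4                                  # sum_{r!=s} x_r^2 x_s^2
  sq_one <- sum(x^2 * ((p1 - x)^2 - (p2 - x^2)))        # sum x_r^2 x_s x_t, distinct
  e_xx <- d2 / (n * (n - 1))
  e_n <- s0 * e_xx
  e_n2 <- (a1 + a2) * sq_pair / (n * (n - 1)) +
    s_one * sq_one / (n * (n - 1) * (n - 2)) +
    s_dis * d4 / (n * (n - 1) * (n - 2) * (n - 3))
  max((e_n2 - e_n^2) / d2^2, 0)
}

#' Global autocorrelation test with analytic and permutation inference
#'
#' Computes a global statistic (Moran's I or Getis-Ord G), its analytic
#' null moments and z-score, the normal-approximation p value, and a
#' permutation p value obtained by randomly relabeling the values over the
#' units. The permutation p uses the standard counting rule
#' (1 + #more-extreme) / (1 + n_perm).
#'
#' @inheritParams moran_i
#' @param stat `"moran_i"` or `"getis_ord_g"`.
#' @param n_perm number of permutations (>= 99); `0` skips permutation.
#' @param seed integer RNG seed for reproducible permutation inference.
#' @param alternative `"greater"` (default: the clustering hypotheses of
#'   hot-spot epidemiology are one-sided) or `"two_sided"`.
#' @param assumption moment assumption for Moran's I variance.
#' @return a `global_stat_result` list: `statistic_name`, `observed`,
#'   `expected`, `variance`, `z`, `p_normal`, `p_perm`, `n_perm`, `seed`,
#'   `perm_mean` (mean of the permuted statistics, `NULL` if none).
#' @export
permutation_test <- function(x, w, stat = c("moran_i", "getis_ord_g"),
                             n_perm = 999L, seed = NULL,
                             alternative = c("greater", "two_sided"),
                             assumption = "randomization") {
  stat <- match.arg(stat)
  alternative <- match.arg(alternative)
  x <- align_values(x, w)
  f <- switch(stat, moran_i = moran_i, getis_ord_g = getis_ord_g)
  obs <- f(x, w)
  if (stat == "moran_i") {
    e <- expected_moran_i(w$n)
    v <- variance_moran_i(x, w, assumption)
  } else {
    e <- expected_getis_ord_g(w)
    v <- variance_getis_ord_g(x, w)
  }
  z <- if (v > 0) (obs - e) / sqrt(v) else NA_real_
  p_norm <- if (is.na(z)) NA_real_ else switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    two_sided = 2 * stats::pnorm(-abs(z)))
  p_perm <- NULL; perm_mean <- NULL
  if (n_perm > 0L) {
    if (n_perm < 99L) stop("n_perm must be >= 99 (or 0 to skip)")
    if (!is.null(seed)) set.seed(seed)
    sims <- vapply(seq_len(n_perm), function(k) f(sample(x), w), 0)
    perm_mean <- mean(sims)
    p_hi <- (1 + sum(sims >= obs)) / (1 + n_perm)
    if (alternative == "greater") {
      p_perm <- p_hi
    } else {
      p_lo <- (1 + sum(sims <= obs)) / (1 + n_perm)
      p_perm <- min(1, 2 * min(p_hi, p_lo))
    }
  }
  structure(list(statistic_name = stat, observed = obs, expected = e,
                 variance = v, z = z, p_normal = p_norm, p_perm = p_perm,
                 n_perm = if (n_perm > 0L) n_perm else NULL,
                 seed = seed, perm_mean = perm_mean),
            class = "global_stat_result")
}

#' @export
print.global_stat_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4f, E %.4f, Var %.5f, z %.3f, p_normal %.4f",
              x$statistic_name, x$observed, x$expected, x$variance,
              x$z, x$p_normal))
  if (!is.null(x$p_perm)) cat(sprintf(", p_perm %.4f (%d perms)",
                                      x$p_perm, x$n_perm))
  cat("\n")
  invisible(x)
}
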