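#' Spearman rank correlation between per-unit vectors
#'
#' Pairs two named vectors (e.g. an exposure covariate and a morbidity
#' rate, or male and female rates) by the intersection of their unit ids,
#' ranks each with midrank tie handling, and returns the Pearson
#' correlation of the rank vectors. Units present in only one vector are
#' dropped and reported.
#'
#' @param x,y named numeric vectors (unit id -> value); non-finite entries
#'   are treated as missing.
#' @return a `correlation_result` list: `r_s`, `n` (complete pairs),
#'   `dropped` (ids not in both vectors), `tie_note`, `p_perm` (`NULL`
#'   until [spearman_perm_p()] is used).
#' @export
spearman <- function(x, y) {
  ids <- intersect(names(x), names(y))
  dropped <- union(setdiff(names(x), ids), setdiff(names(y), ids))
  xv <- as.numeric(x[ids]); yv <- as.numeric(y[ids])
  keep <- is.finite(xv) & is.finite(yv)
  dropped <- c(dropped, ids[!keep])
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  rx <- rank(xv); ry <- rank(yv)   # midranks for ties
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("degenerate ranks: one variable is all ties")
  }
  tx <- sum(table(xv) > 1L); ty <- sum(table(yv) > 1L)
  note <- if (tx + ty == 0) "no ties" else
    sprintf("%d tie group(s) in x, %d in y (midranks used)", tx, ty)
  structure(list(r_s = stats::cor(rx, ry), n = n, dropped = dropped,
                 tie_note = note, p_perm = NULL),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r_s = %.3f on n = %d pairs (%s)", x$r_s, x$n,
              x$tie_note))
  if (!is.null(x$p_perm)) cat(sprintf(", permutation p = %.4f", x$p_perm))
  cat("\n")
  if (length(x$dropped)) {
    cat("  dropped (incomplete):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Two-sided permutation p value for Spearman's r_s
#'
#' Shuffles `y` over the paired units and counts permutations with
#' |r_s| at least the observed |r_s|, using the counting rule
#' (1 + #more-extreme) / (1 + n_perm).
#'
#' @inheritParams spearman
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return a `correlation_result` with `p_perm` filled.
#' @export
spearman_perm_p <- function(x, y, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  res <- spearman(x, y)
  ids <- intersect(names(x), names(y))
  xv <- as.numeric(x[ids]); yv <- as.numeric(y[ids])
  keep <- is.finite(xv) & is.finite(yv)
  rx <- rank(xv[keep]); ry <- rank(yv[keep])
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(stats::cor(rx, ry))
  sims <- vapply(seq_len(n_perm),
                 function(k) abs(stats::cor(rx, sample(ry))), 0)
  res$p_perm <- (1 + sum(sims >= obs - 1e-14)) / (1 + n_perm)
  res$n_perm <- n_perm
  res
}
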