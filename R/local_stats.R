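## Conditional (self fixed) sampling moments of a weighted sum
## L_i = sum_j w_ij b_pi(j), where the n-1 values b = x[-i] are assigned to
## the other units uniformly at random. Exact first and second moments of
## sampling without replacement:
##   E[b_a]       = sum(b)/N
##   E[b_a b_a']  = ((sum b)^2 - sum b^2) / (N (N-1)),  a != a'
## with N = n - 1. Works for arbitrary (not just binary) weight rows.
cond_sum_moments <- function(wrow, b) {
  N <- length(b)
  sw <- sum(wrow); sw2 <- sum(wrow^2)
  sb <- sum(b); sb2 <- sum(b^2)
  e1 <- sb / N
  e11 <- (sb^2 - sb2) / (N * (N - 1))
  el <- sw * e1
  el2 <- sw2 * sb2 / N + (sw^2 - sw2) * e11
  list(mean = el, var = max(el2 - el^2, 0))
}

#' Local Getis-Ord Gi and Gi* hot-spot statistics
#'
#' For each unit i, the share of the variable's total found in i's
#' neighborhood. The plain Gi excludes the unit itself from both sums:
#' Gi = sum_{j != i} w_ij x_j / sum_{j != i} x_j. The starred variant Gi*
#' includes j = i with a unit self-weight in numerator and denominator —
#' the convention behind standard GIS hot-spot maps.
#'
#' z-scores come from the Ord-Getis moments of the chosen variant: for Gi,
#' conditional finite-sampling moments with the self value held fixed
#' (E(Gi) = W_i/(n-1), reducing to the classic Ord-Getis formula for
#' binary weights); for Gi*, full-randomization moments with
#' E(Gi*) = W_i*/n. Large positive z marks a hot spot (high values
#' cluster near i), large negative z a cold spot.
#'
#' @param x nonnegative values, one per unit, not all equal.
#' @param w binary `spatial_weights` (distance band); for `star = TRUE`
#'   self-links are implied, the object need not store them.
#' @param star compute Gi* (include self) instead of Gi.
#' @return a `local_stat_table` data.frame: `unit_id`, `statistic`, `z`,
#'   `p_normal` (two-sided), plus metadata attributes. Island units get
#'   `NA` statistics.
#' @export
local_gi <- function(x, w, star = FALSE) {
  x <- align_values(x, w)
  if (w$style != "binary") stop("Gi statistics require binary weights")
  if (any(x < 0)) stop("Gi requires a nonnegative variable")
  if (length(unique(x)) == 1L) stop("degenerate variable: x is constant")
  n <- w$n
  m <- off_diag_w(w)
  island <- w$ids %in% w$island_ids
  g <- z <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (island[i]) next
    wrow <- m[i, -i]
    if (star) {
      wi <- sum(wrow) + 1               # implied self-weight 1
      num <- sum(wrow * x[-i]) + x[i]
      den <- sum(x)
      g[i] <- num / den
      # full-randomization Ord-Getis moments (n-denominator)
      xb <- sum(x) / n
      s2 <- sum(x^2) / n - xb^2
      eg <- wi / n
      vg <- wi * (n - wi) / (n^2 * (n - 1)) * s2 / xb^2
    } else {
      b <- x[-i]
      den <- sum(b)
      if (den == 0) stop("Gi undefined: all non-self values are zero")
      g[i] <- sum(wrow * b) / den
      mo <- cond_sum_moments(wrow, b)
      eg <- mo$mean / den
      vg <- mo$var / den^2
    }
    z[i] <- if (vg > 0) (g[i] - eg) / sqrt(vg) else NA_real_
  }
  local_stat_table(w$ids, g, z,
                   statistic_name = if (star) "gi_star" else "gi",
                   weights_note = sprintf("binary, threshold %s",
                                          format(w$threshold)))
}

#' Local Moran's I (LISA)
#'
#' Anselin's per-unit decomposition of global Moran's I:
#' I_i = ((x_i - xbar)/m2) * sum_{j != i} w_ij (x_j - xbar), with
#' m2 = sum_k (x_k - xbar)^2 / n. With this scaling the local values
#' satisfy sum_i I_i = S0 * I_global for any weights. z-scores use exact
#' conditional-permutation moments (the value at i held fixed, the others
#' exchangeable).
#'
#' @inheritParams moran_i
#' @return a `local_stat_table` (see [local_gi()]); `p_normal` is
#'   two-sided.
#' @export
local_moran <- function(x, w) {
  x <- align_values(x, w)
  if (w$n < 3L) stop("local Moran needs n >= 3")
  n <- w$n
  m <- off_diag_w(w)
  zc <- x - mean(x)
  m2 <- sum(zc^2) / n
  if (m2 == 0) stop("degenerate variable: x is constant")
  island <- w$ids %in% w$island_ids
  ii <- zsc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (island[i]) next
    wrow <- m[i, -i]
    ii[i] <- zc[i] / m2 * sum(wrow * zc[-i])
    mo <- cond_sum_moments(wrow, zc[-i])
    e_ii <- zc[i] / m2 * mo$mean
    v_ii <- (zc[i] / m2)^2 * mo$var
    zsc[i] <- if (v_ii > 0) (ii[i] - e_ii) / sqrt(v_ii) else NA_real_
  }
  local_stat_table(w$ids, ii, zsc, statistic_name = "local_moran",
                   weights_note = sprintf("%s, threshold %s", w$style,
                                          format(w$threshold)))
}

## Shared constructor for per-unit statistic tables.
local_stat_table <- function(ids, statistic, z, ...) {
  t <- data.frame(unit_id = ids, statistic = statistic, z = z,
                  p_normal = 2 * stats::pnorm(-abs(z)),
                  p_perm = NA_real_,
                  label = ifelse(is.na(statistic), "not_evaluated",
                                 "not_significant"),
                  stringsAsFactors = FALSE)
  meta <- list(...)
  for (nm in names(meta)) attr(t, nm) <- meta[[nm]]
  class(t) <- c("local_stat_table", "data.frame")
  t
}

#' Conditional permutation p values for local statistics
#'
#' For each unit i the observed value x_i is held fixed and the remaining
#' n - 1 values are randomly reassigned to the other units; the local
#' statistic at i is recomputed for each draw. p_i uses the counting rule
#' (1 + #at-least-as-extreme) / (1 + n_perm), two-sided on the z scale
#' via |stat - permutation mean|.
#'
#' @inheritParams local_gi
#' @param stat `"local_moran"`, `"gi"` or `"gi_star"`.
#' @param n_perm number of conditional permutations per unit (>= 99).
#' @param seed integer RNG seed.
#' @return numeric vector of per-unit p values (NA for islands), with the
#'   matrix of permuted statistics available via attribute `"perm_mean"`/
#'   `"perm_sd"` (per-unit reference moments).
#' @export
conditional_permutation <- function(x, w, stat = c("local_moran", "gi", "gi_star"),
                                    n_perm = 999L, seed = NULL) {
  stat <- match.arg(stat)
  if (n_perm < 99L) stop("n_perm must be >= 99")
  x <- align_values(x, w)
  if (!is.null(seed)) set.seed(seed)
  n <- w$n
  m <- off_diag_w(w)
  island <- w$ids %in% w$island_ids
  zc <- x - mean(x)
  m2 <- sum(zc^2) / n
  obs_stat <- switch(stat,
    local_moran = local_moran(x, w)$statistic,
    gi = local_gi(x, w, star = FALSE)$statistic,
    gi_star = local_gi(x, w, star = TRUE)$statistic)
  p <- pm <- ps <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (island[i]) next
    wrow <- m[i, -i]
    nz <- which(wrow != 0)
    sims <- numeric(n_perm)
    if (stat == "local_moran") {
      b <- zc[-i]
      for (k in seq_len(n_perm)) {
        sims[k] <- zc[i] / m2 * sum(wrow[nz] * b[sample.int(n - 1L, length(nz))])
      }
    } else if (stat == "gi") {
      b <- x[-i]; den <- sum(b)
      for (k in seq_len(n_perm)) {
        sims[k] <- sum(wrow[nz] * b[sample.int(n - 1L, length(nz))]) / den
      }
    } else {
      b <- x[-i]; den <- sum(x)
      for (k in seq_len(n_perm)) {
        sims[k] <- (sum(wrow[nz] * b[sample.int(n - 1L, length(nz))]) + x[i]) / den
      }
    }
    pm[i] <- mean(sims); ps[i] <- stats::sd(sims)
    dev <- abs(obs_stat[i] - pm[i])
    p[i] <- (1 + sum(abs(sims - pm[i]) >= dev - 1e-14)) / (1 + n_perm)
  }
  structure(p, perm_mean = pm, perm_sd = ps, names = w$ids)
}

#' Hot/cold-spot classification from z-scores
#'
#' Assigns GIS-standard confidence bins: `hot_90/95/99` for z at or above
#' 1.645 / 1.960 / 2.576, `cold_*` for z at or below the negated
#' thresholds, the strongest applicable bin winning; `not_significant`
#' otherwise; `not_evaluated` where the statistic is missing (islands).
#'
#' @param t a `local_stat_table` with a `z` column.
#' @param thresholds increasing positive z cutoffs for the 90/95/99 bins.
#' @return `t` with the `label` column filled.
#' @export
hot_cold_classify <- function(t, thresholds = c(1.645, 1.960, 2.576)) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0))
  lab <- rep("not_significant", nrow(t))
  z <- t$z
  for (k in 1:3) {
    lv <- c("90", "95", "99")[k]
    lab[!is.na(z) & z >= thresholds[k]] <- paste0("hot_", lv)
    lab[!is.na(z) & z <= -thresholds[k]] <- paste0("cold_", lv)
  }
  lab[is.na(z)] <- "not_evaluated"
  t$label <- lab
  t
}

#' LISA cluster typing
#'
#' Types each unit significant at `alpha` (conditional-permutation p) by
#' the quadrant of the Moran scatterplot: High-High (`HH`) when both the
#' unit's value and its spatial lag (neighbor mean) exceed their means,
#' Low-Low (`LL`) when both fall below, `LH`/`HL` for the discordant
#' quadrants. Non-significant units are `not_significant`; islands
#' `not_evaluated`.
#'
#' @param t a `local_stat_table` from [local_moran()].
#' @param x the values the table was computed from.
#' @param w the same `spatial_weights`.
#' @param p_perm per-unit conditional-permutation p values (from
#'   [conditional_permutation()]); computed on the fly (999 draws,
#'   unseeded) when omitted.
#' @param alpha significance level for cluster membership.
#' @return `t` with `p_perm` and quadrant `label` columns filled,
#'   and attribute `alpha`.
#' @export
lisa_classify <- function(t, x, w, p_perm = NULL, alpha = 0.05) {
  x <- align_values(x, w)
  if (is.null(p_perm)) {
    p_perm <- conditional_permutation(x, w, "local_moran")
  }
  m <- off_diag_w(w)
  deg <- rowSums(m)
  lag <- ifelse(deg > 0, as.numeric(m %*% x) / ifelse(deg > 0, deg, 1), NA)
  lag_mean <- mean(lag, na.rm = TRUE)
  hi_x <- x > mean(x)
  hi_l <- lag > lag_mean
  lab <- rep("not_significant", nrow(t))
  sig <- !is.na(p_perm) & p_perm <= alpha
  lab[sig & hi_x & hi_l] <- "HH"
  lab[sig & !hi_x & !hi_l] <- "LL"
  lab[sig & !hi_x & hi_l] <- "LH"
  lab[sig & hi_x & !hi_l] <- "HL"
  lab[is.na(t$statistic)] <- "not_evaluated"
  t$p_perm <- as.numeric(p_perm)
  t$label <- lab
  attr(t, "alpha") <- alpha
  t
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control over a vector of per-unit p
#' values; a thin wrapper over [stats::p.adjust()]. Off by default in the
#' pipeline (local cluster maps are conventionally reported unadjusted);
#' available for sensitivity analyses.
#'
#' @param p p values in (0, 1] (NA allowed, never selected).
#' @param q target FDR level.
#' @return logical mask, TRUE where the adjusted p is at or below `q`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  !is.na(adj) & adj <= q
}
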