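#' Run the full areal cluster-analysis pipeline
#'
#' Orchestrates the complete analysis on one study frame: raw morbidity
#' rates per stratum, one shared distance-band weight matrix (geometry does
#' not differ by stratum), global Moran's I and Getis-Ord G with analytic
#' moments and permutation inference, local Gi* hot-spot and local-Moran
#' LISA tables per stratum, and Spearman correlations of each covariate
#' (and of male vs female rates) with the all-stratum rate. All defaulted
#' decisions (threshold distance, weight style, alternative, z bins) are
#' logged; identical inputs and seed reproduce identical outputs.
#'
#' @param rs a [region_set].
#' @param ct a `case_table` whose ids join cleanly with `rs` (see
#'   [join_check()]).
#' @param covariates optional list of named covariate vectors.
#' @param strata strata to analyze.
#' @param distance distance-band radius; `NULL` uses the calculated
#'   [threshold_distance()].
#' @param n_perm permutations for global and local inference.
#' @param alpha significance level for LISA cluster membership.
#' @param seed integer seed controlling all permutation inference.
#' @param out_dir optional directory; when given, writes `rates.csv`,
#'   `weights.gal`, `global_stats.csv`, `local_<stat>_<stratum>.csv`,
#'   `correlation.csv` and `run_log.txt` there.
#' @param allow_islands proceed (with a warning) when the band leaves
#'   units without neighbors; islands get missing local statistics.
#' @param allow_mismatch proceed when region and case ids disagree,
#'   restricting to the common units is NOT done — mismatches abort unless
#'   this override is set and the mismatch only leaves extra case rows.
#' @return a `pipeline_result` list: `rates` (per stratum), `weights`,
#'   `global` (data.frame, one row per stratum x statistic), `local`
#'   (nested list `local[[stat]][[stratum]]`), `correlations` (data.frame),
#'   `log` (character), `seed`.
#' @export
run_pipeline <- function(rs, ct, covariates = list(),
                         strata = c("all", "male", "female"),
                         distance = NULL, n_perm = 999L, alpha = 0.05,
                         seed = 1L, out_dir = NULL,
                         allow_islands = FALSE, allow_mismatch = FALSE) {
  strata <- match.arg(strata, c("all", "male", "female"), several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 99L)
  jc <- join_check(rs, ct)
  if (!jc$ok) {
    msg <- paste0("region/case id mismatch — missing cases: [",
                  paste(jc$missing_cases, collapse = ", "),
                  "]; missing geometry: [",
                  paste(jc$missing_geometry, collapse = ", "), "]")
    if (!allow_mismatch || length(jc$missing_cases)) stop("join_check: ", msg)
    warning("join_check override: ", msg)
    ct <- ct[ct$unit_id %in% rs$ids, , drop = FALSE]  # analysis frame = regions
  }
  log <- c(sprintf("mesospat %s pipeline run",
                   as.character(utils::packageVersion("mesospat"))),
           sprintf("seed: %d; n_perm: %d; alpha: %g", seed, n_perm, alpha))
  d <- distance %||% threshold_distance(rs)
  log <- c(log, sprintf("distance band: %.6g (%s)", d,
                        if (is.null(distance)) "calculated threshold: max nearest-neighbor distance"
                        else "user override"))
  w <- distance_band(rs, d)
  if (length(w$island_ids)) {
    msg <- paste("islands at band distance:",
                 paste(w$island_ids, collapse = ", "))
    if (!allow_islands) stop(msg, " (set allow_islands = TRUE to proceed)")
    warning(msg)
    log <- c(log, msg)
  }
  log <- c(log, "weights: binary distance band (shared across strata)",
           "global alternative: greater (positive clustering hypothesis)",
           "local z bins: 1.645/1.960/2.576 (90/95/99%)",
           "moment assumption: randomization; FDR: off")

  rates <- list(); glb <- list(); loc <- list(gi_star = list(),
                                              local_moran = list())
  for (s in seq_along(strata)) {
    st <- strata[s]
    rv <- raw_morbidity_rate(ct, st)
    rv <- structure(as.numeric(rv)[match(rs$ids, names(rv))],
                    names = rs$ids, stratum = st,
                    period = attr(rv, "period"), class = "rate_vector")
    rates[[st]] <- rv
    for (stat in c("moran_i", "getis_ord_g")) {
      res <- permutation_test(rv, w, stat, n_perm = n_perm,
                              seed = seed + 1000L * s)
      glb[[paste(st, stat)]] <- data.frame(
        stratum = st, statistic = stat, observed = res$observed,
        expected = res$expected, variance = res$variance, z = res$z,
        p_normal = res$p_normal, p_perm = res$p_perm,
        stringsAsFactors = FALSE)
    }
    gi <- hot_cold_classify(local_gi(rv, w, star = TRUE))
    p_gi <- conditional_permutation(rv, w, "gi_star", n_perm = n_perm,
                                    seed = seed + 1000L * s + 1L)
    gi$p_perm <- as.numeric(p_gi)
    loc$gi_star[[st]] <- gi
    lm <- local_moran(rv, w)
    p_lm <- conditional_permutation(rv, w, "local_moran", n_perm = n_perm,
                                    seed = seed + 1000L * s + 2L)
    loc$local_moran[[st]] <- lisa_classify(lm, rv, w, p_perm = p_lm,
                                           alpha = alpha)
  }
  global <- do.call(rbind, glb)
  rownames(global) <- NULL

  cors <- list()
  if (all(c("male", "female") %in% strata)) {
    r <- spearman_perm_p(rates$male, rates$female, n_perm = n_perm,
                         seed = seed + 77L)
    cors[["male_vs_female_rate"]] <- data.frame(
      pair = "male_rate~female_rate", r_s = r$r_s, n = r$n,
      p_perm = r$p_perm, stringsAsFactors = FALSE)
  }
  ref <- rates[[strata[1L]]]
  for (cv in covariates) {
    lab <- attr(cv, "label") %||% "covariate"
    r <- spearman_perm_p(cv, ref, n_perm = n_perm, seed = seed + 78L)
    cors[[lab]] <- data.frame(
      pair = paste0(lab, "~", strata[1L], "_rate"), r_s = r$r_s, n = r$n,
      p_perm = r$p_perm, stringsAsFactors = FALSE)
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else
    data.frame(pair = character(0), r_s = numeric(0), n = integer(0),
               p_perm = numeric(0))
  rownames(correlations) <- NULL

  out <- structure(list(rates = rates, weights = w, global = global,
                        local = loc, correlations = correlations,
                        log = log, seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

## Serialize a pipeline_result into its csv/gal/log bundle. Written
## atomically enough for reruns: files are plain overwrites, and any error
## removes the partial bundle.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline output failed: ", conditionMessage(e))
  }
  tryCatch({
    p <- file.path(out_dir, "rates.csv")
    rt <- do.call(rbind, lapply(names(res$rates), function(st) {
      rv <- res$rates[[st]]
      cls <- classify_rates(rv)$class_of
      data.frame(unit_id = names(rv), stratum = st,
                 rate_per_100k = as.numeric(rv), class = cls[names(rv)],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rt, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    p <- file.path(out_dir, "weights.gal")
    write_gal(res$weights, p); written <- c(written, p)
    p <- file.path(out_dir, "global_stats.csv")
    utils::write.csv(res$global, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    for (stat in names(res$local)) {
      for (st in names(res$local[[stat]])) {
        p <- file.path(out_dir, sprintf("local_%s_%s.csv", stat, st))
        utils::write.csv(as.data.frame(res$local[[stat]][[st]]), p,
                         row.names = FALSE, quote = FALSE)
        written <- c(written, p)
      }
    }
    p <- file.path(out_dir, "correlation.csv")
    utils::write.csv(res$correlations, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    writeLines(res$log, file.path(out_dir, "run_log.txt"))
  }, error = on_fail)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result over", x$weights$n, "units;",
      length(x$rates), "strata\n\nGlobal statistics:\n")
  print(x$global, digits = 4)
  invisible(x)
}
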