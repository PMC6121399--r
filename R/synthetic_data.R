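#' Simulation configuration for synthetic areal studies
#'
#' Defines a registry-style study frame on a square lattice: stratified
#' (male/female) Poisson case counts over a run of years, lognormal
#' mid-year populations, a circular planted risk cluster, and an exposure
#' covariate correlated with true risk. Defaults emulate a province-scale
#' mesothelioma-type study: 16 units (4 x 4), years 1999-2013, a baseline
#' incidence of 0.5 cases per 100,000 person-years (a rare-cancer order of
#' magnitude), populations around 2 million (lognormal, sdlog 0.45, the
#' spread of Polish province populations), and a 64%/36% male/female case
#' split.
#'
#' @param n_side lattice side; the frame has `n_side^2` units.
#' @param years integer `c(first, last)`.
#' @param baseline_rate baseline incidence, cases per 100,000 person-years
#'   (both sexes combined).
#' @param population_log_mean,population_log_sd lognormal parameters of the
#'   per-unit mid-year population.
#' @param cluster_seed_unit unit id at the cluster center, or `"random"`.
#' @param cluster_radius planted-cluster radius in grid units (centroid
#'   distance); `0` plants a single-unit cluster.
#' @param relative_risk rate multiplier (>= 1) inside the cluster; 1 means
#'   no planted structure (the null).
#' @param sex_split proportion of cases that are male.
#' @param covariate_noise_sd Gaussian noise sd of the exposure covariate,
#'   in rate units (per 100,000 person-years).
#' @param rng_seed integer seed; the whole study is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_side = 4L, years = c(1999L, 2013L),
                       baseline_rate = 0.5,
                       population_log_mean = log(2e6),
                       population_log_sd = 0.45,
                       cluster_seed_unit = "random", cluster_radius = 1.0,
                       relative_risk = 2.0, sex_split = 0.64,
                       covariate_noise_sd = 0.25, rng_seed = 1L) {
  stopifnot(n_side >= 2L, years[1L] <= years[2L], baseline_rate >= 0,
            relative_risk >= 1, sex_split > 0, sex_split < 1,
            cluster_radius >= 0, covariate_noise_sd >= 0)
  structure(list(n_side = as.integer(n_side), years = as.integer(years),
                 baseline_rate = baseline_rate,
                 population_log_mean = population_log_mean,
                 population_log_sd = population_log_sd,
                 cluster_seed_unit = cluster_seed_unit,
                 cluster_radius = cluster_radius,
                 relative_risk = relative_risk, sex_split = sex_split,
                 covariate_noise_sd = covariate_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate the areal frame: a unit-spaced square lattice
#'
#' Units are unit squares with centroids at integer coordinates, ids
#' `U_<row>_<col>` (0-based), in row-major order. The lattice preserves
#' everything the spatial statistics consume — centroids, distances,
#' adjacency — while being freely redistributable, unlike national
#' administrative geometries.
#'
#' @param cfg a [sim_config()].
#' @return a [region_set] of `n_side^2` units.
#' @export
simulate_regions <- function(cfg) {
  s <- cfg$n_side
  rc <- expand.grid(col = 0:(s - 1L), row = 0:(s - 1L))[, c("row", "col")]
  ids <- sprintf("U_%d_%d", rc$row, rc$col)
  cents <- cbind(rc$row, rc$col)
  bounds <- lapply(seq_len(nrow(rc)), function(i) {
    list(cbind(rc$row[i] + c(-.5, .5, .5, -.5, -.5),
               rc$col[i] + c(-.5, -.5, .5, .5, -.5)))
  })
  region_set(ids, cents, boundaries = bounds,
             crs_note = "synthetic unit lattice (planar)")
}

#' Simulate a stratified areal case study with a planted risk cluster
#'
#' Per unit: a mid-year population drawn once from a lognormal and jittered
#' by at most 1% per year; a true rate equal to `baseline_rate` times
#' `relative_risk` for units within `cluster_radius` of the cluster seed;
#' per year and sex, case counts drawn Poisson with mean
#' `true_rate x sex_share x population / 100,000` (sex shares
#' `sex_split`/`1 - sex_split`); recorded per-sex populations are half the
#' unit total, so the male stratum carries the higher rate, as in real
#' mesothelioma registries. An exposure covariate equal to the true rate
#' plus Gaussian noise emulates an asbestos-type exposure proxy. The whole
#' study, including the truth record, is reproducible from `rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @param rs optional pre-built [region_set] (defaults to
#'   [simulate_regions()] of `cfg`).
#' @return a `synthetic_study` list: `regions`, `cases` (a `case_table`),
#'   `covariates` (list with one covariate vector), `truth` (list:
#'   `cluster_units`, `seed_unit`, `true_rate` named per unit, `config`).
#' @export
simulate_cases <- function(cfg, rs = NULL) {
  set.seed(cfg$rng_seed)
  if (is.null(rs)) rs <- simulate_regions(cfg)
  n <- rs$n
  years <- seq.int(cfg$years[1L], cfg$years[2L])
  seed_unit <- if (identical(cfg$cluster_seed_unit, "random")) {
    rs$ids[sample.int(n, 1L)]
  } else {
    if (!cfg$cluster_seed_unit %in% rs$ids) {
      stop("cluster_seed_unit not in region set: ", cfg$cluster_seed_unit)
    }
    cfg$cluster_seed_unit
  }
  d_seed <- sqrt(colSums((t(rs$centroids) - rs$centroids[seed_unit, ])^2))
  in_cluster <- d_seed <= cfg$cluster_radius
  true_rate <- cfg$baseline_rate *
    ifelse(in_cluster, cfg$relative_risk, 1)
  names(true_rate) <- rs$ids
  base_pop <- stats::rlnorm(n, cfg$population_log_mean, cfg$population_log_sd)
  share <- c(male = cfg$sex_split, female = 1 - cfg$sex_split)
  recs <- vector("list", n * length(years))
  k <- 0L
  for (i in seq_len(n)) {
    for (y in years) {
      k <- k + 1L
      pop <- base_pop[i] * stats::runif(1L, 0.99, 1.01)
      cases <- stats::rpois(2L, true_rate[i] * share * pop / 1e5)
      recs[[k]] <- data.frame(unit_id = rs$ids[i], year = y,
                              stratum = c("male", "female"),
                              cases = cases, population = pop / 2,
                              stringsAsFactors = FALSE)
    }
  }
  ct <- case_table(do.call(rbind, recs))
  cov <- covariate_vector(
    true_rate + stats::rnorm(n, 0, cfg$covariate_noise_sd),
    rs$ids, label = "exposure_index")
  structure(list(regions = rs, cases = ct, covariates = list(cov),
                 truth = list(cluster_units = rs$ids[in_cluster],
                              seed_unit = seed_unit,
                              true_rate = true_rate, config = cfg)),
            class = "synthetic_study")
}

#' Recovery report: detected clusters and rate accuracy versus truth
#'
#' Compares a hot-spot call set against the planted cluster membership and
#' the estimated raw rates against the true rates of a
#' [simulate_cases()] study.
#'
#' @param study a `synthetic_study`.
#' @param local_table a `local_stat_table` computed on the study's rates.
#' @param rv the rate vector the table was computed from (optional; adds
#'   bias diagnostics when given).
#' @param z_threshold z cutoff defining a "hot" call (default 1.96).
#' @return list: `sensitivity` (planted units called hot), `specificity`
#'   (background units not called hot), `n_true`, `n_called`, and (when
#'   `rv` given) `rate_bias` (mean of SS - true rate) and `rate_rmse`.
#' @export
parameter_recovery_report <- function(study, local_table, rv = NULL,
                                      z_threshold = 1.96) {
  truth <- study$truth$cluster_units
  ids <- local_table$unit_id
  hot <- !is.na(local_table$z) & local_table$z >= z_threshold
  is_true <- ids %in% truth
  sens <- if (any(is_true)) mean(hot[is_true]) else NA_real_
  spec <- if (any(!is_true)) mean(!hot[!is_true]) else NA_real_
  out <- list(sensitivity = sens, specificity = spec,
              n_true = sum(is_true), n_called = sum(hot))
  if (!is.null(rv)) {
    err <- as.numeric(rv)[match(ids, names(rv))] -
      study$truth$true_rate[ids]
    out$rate_bias <- mean(err)
    out$rate_rmse <- sqrt(mean(err^2))
  }
  out
}

#' Write a synthetic study to an output directory
#'
#' Produces the package's exchange formats: `regions.geojson`,
#' `cases.csv`, one `covariate_<label>.csv` per covariate, and
#' `truth.json`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_regions(study$regions, file.path(dir, "regions.geojson"))
  write_cases(study$cases, file.path(dir, "cases.csv"))
  for (cv in study$covariates) {
    utils::write.csv(
      data.frame(unit_id = names(cv), value = as.numeric(cv)),
      file.path(dir, paste0("covariate_", attr(cv, "label"), ".csv")),
      row.names = FALSE, quote = FALSE)
  }
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
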