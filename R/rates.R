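#' Raw morbidity rate per areal unit
#'
#' Cumulative cases over cumulative person-years, scaled to cases per
#' 100,000: for each unit, SS = (sum of yearly cases) / (sum of yearly
#' mid-year populations) x 100,000 over the requested period and stratum.
#' Person-years in the denominator are exact under changing populations and
#' reduce to mean population x years when the population is constant. The
#' rate is unadjusted for age (a "raw" rate).
#'
#' @param ct a `case_table` (see [read_cases()]).
#' @param stratum one of `"all"`, `"male"`, `"female"`.
#' @param period integer `c(first_year, last_year)`; defaults to the full
#'   year range present in `ct`.
#' @return a `rate_vector`: named numeric (cases per 100,000 person-years)
#'   in case-table unit order, with attributes `stratum` and `period`.
#' @export
raw_morbidity_rate <- function(ct, stratum = c("all", "male", "female"),
                               period = NULL) {
  stratum <- match.arg(stratum)
  sub <- ct[ct$stratum == stratum, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for stratum ", stratum)
  if (is.null(period)) period <- range(sub$year)
  years <- seq.int(period[1L], period[2L])
  sub <- sub[sub$year %in% years, , drop = FALSE]
  units <- unique(ct$unit_id)
  have <- paste(sub$unit_id, sub$year)
  want <- as.vector(outer(units, years, paste))
  gaps <- setdiff(want, have)
  if (length(gaps)) {
    stop("missing (unit, year) records for stratum ", stratum, ": ",
         paste(utils::head(gaps, 5L), collapse = "; "),
         if (length(gaps) > 5L) " ..." else "")
  }
  k <- tapply(sub$cases, sub$unit_id, sum)[units]
  p <- tapply(sub$population, sub$unit_id, sum)[units]
  if (any(p <= 0)) stop("zero total person-years for unit ",
                        units[which(p <= 0)[1L]])
  rv <- as.numeric(k) / as.numeric(p) * 1e5
  names(rv) <- units
  structure(rv, stratum = stratum, period = period, class = "rate_vector")
}

#' Classify rates into K map classes
#'
#' Breaks a rate (or covariate) vector into `K` ordered classes for
#' choropleth mapping, class 1 being the lowest rates. The `quantile`
#' scheme places breakpoints at the 1/K, ..., (K-1)/K empirical quantiles
#' (robust to the right skew typical of rare-disease rates);
#' `equal_interval` uses K equal-width bins over the observed range. Values
#' tied with a breakpoint fall in the lower class.
#'
#' @param rv numeric rate vector (named by unit).
#' @param K number of classes (default 5, the usual choropleth convention).
#' @param scheme `"quantile"` or `"equal_interval"`.
#' @return list of class `rate_classification`: `class_of` (named integer
#'   1..K), `K`, `breakpoints` (K-1 strictly increasing rates), `scheme`.
#' @export
classify_rates <- function(rv, K = 5L, scheme = c("quantile", "equal_interval")) {
  scheme <- match.arg(scheme)
  x <- as.numeric(rv)
  if (K < 2L) stop("K must be >= 2")
  if (length(unique(x)) == 1L) {
    warning("constant rates: single class returned")
    cls <- rep.int(1L, length(x)); names(cls) <- names(rv)
    return(structure(list(class_of = cls, K = 1L,
                          breakpoints = numeric(0), scheme = scheme),
                     class = "rate_classification"))
  }
  if (scheme == "quantile") {
    if (length(x) < K) stop("quantile scheme needs n >= K")
    br <- stats::quantile(x, probs = seq_len(K - 1L) / K, names = FALSE)
  } else {
    br <- min(x) + diff(range(x)) * seq_len(K - 1L) / K
  }
  br <- unique(br)
  if (length(br) < K - 1L) {
    warning("tied breakpoints collapsed: ", length(br) + 1L,
            " effective classes")
  }
  cls <- findInterval(x, br, left.open = TRUE) + 1L  # ties to the lower class
  names(cls) <- names(rv)
  structure(list(class_of = cls, K = length(br) + 1L, breakpoints = br,
                 scheme = scheme),
            class = "rate_classification")
}
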