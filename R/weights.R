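#' Spatial weights
#'
#' Internal constructor for the `spatial_weights` class: a dense n x n
#' matrix of nonnegative link weights with zero diagonal unless
#' `include_self`, plus metadata. Dense storage is deliberate — the class
#' targets province-scale frames (tens of units), where an n x n matrix is
#' both the fastest and the simplest representation.
#'
#' @param w numeric n x n matrix, dimnames set to unit ids.
#' @param style `"binary"` or `"row_standardized"`.
#' @param threshold distance-band threshold used to build it, or `NA`.
#' @param include_self whether self-links (w_ii) are stored.
#' @return object of class `spatial_weights`.
#' @keywords internal
new_spatial_weights <- function(w, style, threshold = NA_real_,
                                include_self = FALSE) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  if (!include_self && any(diag(w) != 0)) {
    stop("self-links present but include_self is FALSE")
  }
  deg <- rowSums(w) - if (include_self) diag(w) else 0
  structure(
    list(n = nrow(w), ids = rownames(w), w = w, style = style,
         threshold = threshold, include_self = include_self,
         island_ids = rownames(w)[deg == 0]),
    class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights:", x$n, "units,", x$style, "style, S0 =",
      format(sum(x$w)), "\n")
  if (!is.na(x$threshold)) cat("  distance-band threshold:", x$threshold, "\n")
  if (length(x$island_ids)) {
    cat("  islands:", paste(x$island_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Calculated threshold distance for a fixed distance band
#'
#' The smallest band radius guaranteeing that every unit has at least one
#' neighbor: the maximum over units of the Euclidean distance to their
#' nearest other centroid. This is the standard "calculated threshold" used
#' by GIS fixed-distance-band tools.
#'
#' @param rs a [region_set].
#' @return a single distance in the units of the centroid coordinates.
#' @export
threshold_distance <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  d <- as.matrix(stats::dist(rs$centroids))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  if (any(nn == 0)) {
    warning("duplicate centroid coordinates across distinct units")
  }
  max(nn)
}

#' Fixed distance-band spatial weights
#'
#' Binary weights with w_ij = 1 iff 0 < dist(i, j) <= d (Euclidean,
#' centroid to centroid). The link set is symmetric by construction. Units
#' with no neighbor within the band are recorded as islands. When
#' `include_self` is `TRUE` a unit-weight self-link is added to every unit
#' (the Gi* convention).
#'
#' @param rs a [region_set].
#' @param d band radius; defaults to [threshold_distance()] of `rs`.
#' @param include_self add w_ii = 1 self-links.
#' @return a binary [new_spatial_weights()] object.
#' @export
distance_band <- function(rs, d = NULL, include_self = FALSE) {
  stopifnot(inherits(rs, "region_set"))
  if (is.null(d)) d <- threshold_distance(rs)
  if (!(d > 0)) stop("band radius d must be positive")
  dm <- as.matrix(stats::dist(rs$centroids))
  w <- (dm > 0 & dm <= d) * 1
  dimnames(w) <- list(rs$ids, rs$ids)
  if (include_self) diag(w) <- 1
  new_spatial_weights(w, "binary", threshold = d, include_self = include_self)
}

#' Row-standardize binary weights
#'
#' Rescales each non-island row to sum to one. Island rows stay empty.
#' Idempotent in effect: standardizing already-standardized weights leaves
#' the values unchanged.
#'
#' @param w a `spatial_weights` object.
#' @return a `spatial_weights` object with style `"row_standardized"`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  rs <- rowSums(w$w)
  m <- w$w / ifelse(rs > 0, rs, 1)
  dimnames(m) <- dimnames(w$w)
  out <- new_spatial_weights(m, "row_standardized", threshold = w$threshold,
                             include_self = w$include_self)
  out$island_ids <- w$island_ids
  out
}

#' Read/write adjacency in the GAL exchange format
#'
#' The GAL text format stores binary adjacency: a header line with `n`,
#' then for each unit a line `id k` followed by a line with its `k`
#' neighbor ids. Weights round-trip exactly at the link-set level.
#'
#' @param w binary `spatial_weights`.
#' @param path file path.
#' @return `write_gal`: `path` invisibly; `read_gal`: a binary
#'   `spatial_weights` object (threshold metadata is not stored in GAL).
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style != "binary") stop("GAL stores adjacency only; weights must be binary")
  lines <- as.character(w$n)
  for (i in seq_len(w$n)) {
    nb <- w$ids[w$w[i, ] > 0 & seq_len(w$n) != i]
    lines <- c(lines, paste(w$ids[i], length(nb)),
               paste(nb, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gal
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1L])
  if (is.na(n) || n < 1L) stop("GAL parse error at line 1: bad unit count")
  ids <- character(n); nbrs <- vector("list", n)
  ln <- 1L
  for (i in seq_len(n)) {
    ln <- ln + 1L
    if (ln > length(lines)) stop("GAL parse error: truncated at line ", ln)
    hdr <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(hdr) != 2L) stop("GAL parse error at line ", ln, ": expected 'id k'")
    ids[i] <- hdr[1L]
    k <- as.integer(hdr[2L])
    ln <- ln + 1L
    nb <- if (ln <= length(lines) && nzchar(trimws(lines[ln]))) {
      strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    } else character(0)
    if (length(nb) != k) {
      stop("GAL parse error at line ", ln, ": declared ", k,
           " neighbors but found ", length(nb))
    }
    nbrs[[i]] <- nb
  }
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    unknown <- setdiff(nbrs[[i]], ids)
    if (length(unknown)) {
      stop("GAL parse error: unknown neighbor id ", unknown[1L])
    }
    w[i, nbrs[[i]]] <- 1
  }
  new_spatial_weights(w, "binary")
}
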