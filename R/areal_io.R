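#' Construct a region set
#'
#' A `region_set` is the spatial frame for every downstream computation: an
#' ordered collection of areal units with unique ids and planar centroids.
#' The input order is the canonical index `i = 1..n` used by all vectors and
#' matrices in the package.
#'
#' @param ids character vector of unique unit ids.
#' @param centroids numeric matrix with `n` rows and 2 columns (x, y), in
#'   projected-CRS units (e.g. meters).
#' @param names optional character vector of display names.
#' @param boundaries optional list of polygon rings (each a closed two-column
#'   matrix with at least 3 distinct vertices), one entry per unit; an entry
#'   may itself be a list of rings for multi-part units.
#' @param crs_note free-text note on the coordinate reference system.
#' @return An object of class `region_set` with elements `ids`, `names`,
#'   `centroids`, `boundaries`, `crs_note`, and `n`.
#' @export
region_set <- function(ids, centroids, names = NULL, boundaries = NULL,
                       crs_note = "planar (projected CRS assumed)") {
  ids <- as.character(ids)
  if (length(ids) < 2L) {
    stop("a region_set needs at least 2 units, got ", length(ids))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate unit_id in region set: ", paste(dup, collapse = ", "))
  }
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  if (nrow(centroids) != length(ids) || ncol(centroids) != 2L) {
    stop("centroids must be an n x 2 matrix matching ids")
  }
  if (!all(is.finite(centroids))) stop("non-finite centroid coordinates")
  rownames(centroids) <- ids
  colnames(centroids) <- c("x", "y")
  structure(
    list(ids = ids, names = names %||% ids, centroids = centroids,
         boundaries = boundaries, crs_note = crs_note, n = length(ids)),
    class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", x$n, "areal units (", x$crs_note, ")\n")
  cat("  ids:", paste(utils::head(x$ids, 6L), collapse = ", "),
      if (x$n > 6L) "..." else "", "\n")
  invisible(x)
}

## Signed shoelace area and area-weighted centroid of one closed ring.
## A counter-clockwise outer ring has positive area; clockwise holes
## contribute negatively, so summing signed terms over rings handles holes.
ring_area_centroid <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2L && all(ring[1L, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (nrow(unique(ring)) < 3L) stop("polygon ring needs >= 3 distinct vertices")
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  cx <- sum((x + xn) * cross) / 6
  cy <- sum((y + yn) * cross) / 6
  list(area = a, cx = cx, cy = cy)
}

## Area-weighted centroid of a polygon given as a list of rings (possibly
## nested one level for multipolygons).
polygon_centroid <- function(rings) {
  flat <- list()
  add <- function(r) {
    if (is.list(r) && !is.matrix(r)) lapply(r, add) else flat[[length(flat) + 1L]] <<- r
  }
  add(rings)
  parts <- lapply(flat, ring_area_centroid)
  a <- sum(vapply(parts, `[[`, 0, "area"))
  if (abs(a) < .Machine$double.eps) stop("degenerate polygon with zero area")
  c(x = sum(vapply(parts, `[[`, 0, "cx")) / a,
    y = sum(vapply(parts, `[[`, 0, "cy")) / a)
}

#' Read areal units from GeoJSON or CSV
#'
#' GeoJSON input must be an RFC 7946 FeatureCollection of Polygon or
#' MultiPolygon features carrying a `unit_id` property; centroids are the
#' area-weighted (shoelace) polygon centroids, which are unbiased by vertex
#' density. CSV input must have columns `unit_id, x, y` giving centroids
#' directly. Feature/row order becomes the canonical unit order. Coordinates
#' are taken as planar; supply data in a projected CRS.
#'
#' @param path path to the input file.
#' @param format `"geojson"` or `"csv"`; guessed from the file extension
#'   when omitted.
#' @return A [region_set].
#' @export
read_regions <- function(path, format = c("auto", "geojson", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("unit_id", "x", "y")
    if (!all(need %in% names(df))) {
      stop("region csv must have columns unit_id, x, y")
    }
    return(region_set(df$unit_id, cbind(df$x, df$y),
                      names = if ("name" %in% names(df)) df$name else NULL))
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("GeoJSON root must be a FeatureCollection")
  }
  feats <- gj$features
  ids <- character(0); cents <- NULL; bounds <- list(); nms <- character(0)
  for (f in feats) {
    id <- f$properties$unit_id
    if (is.null(id)) stop("feature without a unit_id property")
    geom <- f$geometry
    if (is.null(geom$type) || !geom$type %in% c("Polygon", "MultiPolygon")) {
      stop("unsupported geometry type for unit ", id, ": ",
           geom$type %||% "none", " (only Polygon/MultiPolygon)")
    }
    coords_to_rings <- function(poly) {
      lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
      })
    }
    rings <- if (geom$type == "Polygon") coords_to_rings(geom$coordinates)
             else unlist(lapply(geom$coordinates, coords_to_rings),
                         recursive = FALSE)
    ids <- c(ids, as.character(id))
    nms <- c(nms, as.character(f$properties$name %||% id))
    cents <- rbind(cents, polygon_centroid(rings))
    bounds[[length(bounds) + 1L]] <- rings
  }
  region_set(ids, cents, names = nms, boundaries = bounds)
}

#' Write a region set as GeoJSON
#'
#' Units with stored boundaries are written as Polygon features; units
#' without boundaries are written as unit squares centered on their
#' centroids, so that round-tripping preserves centroids.
#'
#' @param rs a [region_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  feats <- lapply(seq_len(rs$n), function(i) {
    rings <- if (!is.null(rs$boundaries)) rs$boundaries[[i]] else NULL
    if (is.null(rings)) {
      cx <- rs$centroids[i, 1L]; cy <- rs$centroids[i, 2L]
      rings <- list(cbind(cx + c(-.5, .5, .5, -.5, -.5),
                          cy + c(-.5, -.5, .5, .5, -.5)))
    }
    coords <- lapply(rings, function(r) {
      r <- as.matrix(r)
      if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1L], r[k, 2L]))
    })
    list(type = "Feature",
         properties = list(unit_id = rs$ids[i], name = rs$names[i]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stratified case/population table
#'
#' Expects a CSV with header `unit_id, year, sex, cases, population`, one row
#' per unit, year and sex (`M`/`F`). Cases are nonnegative integers and
#' population is the positive mid-year count for that stratum. Rows for the
#' combined stratum `all` are synthesized as male + female per (unit, year),
#' with populations summed; if the file supplies explicit `all` rows they
#' must equal the male + female sums, otherwise a consistency error is
#' raised (prevents silent double counting).
#'
#' @param path csv path.
#' @return A `case_table`: a data.frame with columns `unit_id`, `year`,
#'   `stratum` (one of `all`, `male`, `female`), `cases`, `population`.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("case table is empty: ", path)
  need <- c("unit_id", "year", "sex", "cases", "population")
  if (!all(need %in% names(df))) {
    stop("case csv must have columns ", paste(need, collapse = ", "))
  }
  sex <- toupper(as.character(df$sex))
  ok <- sex %in% c("M", "F", "ALL")
  if (any(!ok)) {
    stop("invalid sex value(s) at row(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ", "),
         " (expected M or F)")
  }
  bad <- which(df$cases < 0 | df$cases != round(df$cases))
  if (length(bad)) stop("negative or non-integer cases at row ", bad[1L])
  bad <- which(!(df$population > 0))
  if (length(bad)) stop("nonpositive population at row ", bad[1L])
  stratum <- c(M = "male", F = "female", ALL = "all")[sex]
  ct <- data.frame(unit_id = as.character(df$unit_id),
                   year = as.integer(df$year),
                   stratum = unname(stratum),
                   cases = as.integer(df$cases),
                   population = as.numeric(df$population),
                   stringsAsFactors = FALSE)
  case_table(ct)
}

#' Build (and validate) a case table
#'
#' @param records data.frame with columns `unit_id`, `year`, `stratum`,
#'   `cases`, `population`; strata `male`/`female` mandatory per record key,
#'   `all` derived when absent.
#' @return a validated `case_table` data.frame including the `all` stratum.
#' @export
case_table <- function(records) {
  ct <- as.data.frame(records, stringsAsFactors = FALSE)
  key <- paste(ct$unit_id, ct$year, ct$stratum)
  if (anyDuplicated(key)) {
    stop("duplicate (unit_id, year, stratum) key: ", key[duplicated(key)][1L])
  }
  if (any(ct$cases > 0 & !(ct$population > 0))) {
    stop("cases > 0 with nonpositive population")
  }
  sexed <- ct[ct$stratum %in% c("male", "female"), , drop = FALSE]
  if (nrow(sexed)) {
    agg <- stats::aggregate(cbind(cases, population) ~ unit_id + year,
                            data = sexed, FUN = sum)
    agg$stratum <- "all"
    supplied <- ct[ct$stratum == "all", , drop = FALSE]
    if (nrow(supplied)) {
      m <- merge(supplied, agg, by = c("unit_id", "year"),
                 suffixes = c("", ".derived"))
      off <- which(m$cases != m$cases.derived |
                     abs(m$population - m$population.derived) > 1e-6)
      if (length(off)) {
        stop("supplied 'all' stratum disagrees with male+female for (",
             m$unit_id[off[1L]], ", ", m$year[off[1L]], ")")
      }
      agg <- agg[!paste(agg$unit_id, agg$year) %in%
                   paste(supplied$unit_id, supplied$year), , drop = FALSE]
    }
    ct <- rbind(ct, agg[, names(ct)])
  }
  ct <- ct[order(ct$unit_id, ct$year, ct$stratum), , drop = FALSE]
  rownames(ct) <- NULL
  class(ct) <- c("case_table", "data.frame")
  ct
}

#' Write a case table back to the CSV exchange format
#'
#' Only the sexed strata are written (`all` is always derivable), using the
#' `unit_id, year, sex, cases, population` layout accepted by [read_cases()].
#'
#' @param ct a `case_table`.
#' @param path output csv path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(ct, path) {
  sexed <- ct[ct$stratum %in% c("male", "female"), , drop = FALSE]
  out <- data.frame(unit_id = sexed$unit_id, year = sexed$year,
                    sex = c(male = "M", female = "F")[sexed$stratum],
                    cases = sexed$cases, population = sexed$population)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-unit covariate vector
#'
#' @param path csv with columns `unit_id, value`.
#' @param label covariate label (defaults to the file name).
#' @return named numeric vector with a `label` attribute.
#' @export
read_covariate <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "value") %in% names(df))) {
    stop("covariate csv must have columns unit_id, value")
  }
  covariate_vector(df$value, df$unit_id,
                   label %||% sub("\\.csv$", "", basename(path)))
}

#' @rdname read_covariate
#' @param values numeric values.
#' @param ids unit ids (must be unique).
#' @export
covariate_vector <- function(values, ids, label = "covariate") {
  if (anyDuplicated(ids)) stop("duplicate unit_id in covariate")
  if (!all(is.finite(values))) stop("non-finite covariate values")
  v <- as.numeric(values)
  names(v) <- as.character(ids)
  attr(v, "label") <- label
  v
}

#' Check that regions and cases refer to the same units
#'
#' @param rs a [region_set].
#' @param ct a `case_table`.
#' @return list with `missing_cases` (ids with geometry but no records),
#'   `missing_geometry` (ids with records but no geometry), and `ok`.
#' @export
join_check <- function(rs, ct) {
  ct_ids <- unique(ct$unit_id)
  list(missing_cases = setdiff(rs$ids, ct_ids),
       missing_geometry = setdiff(ct_ids, rs$ids),
       ok = setequal(rs$ids, ct_ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
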