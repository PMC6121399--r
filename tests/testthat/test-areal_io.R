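test_that("csv regions pass centroids through in input order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,x,y", "A,0,0", "B,1,0"), f)
  rs <- read_regions(f)
  expect_s3_class(rs, "region_set")
  expect_identical(rs$ids, c("A", "B"))
  expect_equal(unname(rs$centroids), rbind(c(0, 0), c(1, 0)))
})

geojson_of <- function(rings_by_id) {
  feats <- lapply(names(rings_by_id), function(id) {
    coords <- lapply(rings_by_id[[id]], function(r) {
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature", properties = list(unit_id = id),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  f <- withr::local_tempfile(fileext = ".geojson", .local_envir = parent.frame())
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       f, auto_unbox = TRUE, digits = NA)
  f
}

test_that("polygon centroids are area-weighted (unit square and L-shape)", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  ell <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2), c(0, 0))
  f <- geojson_of(list(P1 = list(sq), P2 = list(ell)))
  rs <- read_regions(f)
  expect_equal(unname(rs$centroids["P1", ]), c(0.5, 0.5))
  # fan-triangulation oracle for the L-shape
  v <- ell[-nrow(ell), ]
  tri_a <- 0; tri_c <- c(0, 0)
  for (k in 2:(nrow(v) - 1)) {
    a <- ((v[k, 1] - v[1, 1]) * (v[k + 1, 2] - v[1, 2]) -
            (v[k + 1, 1] - v[1, 1]) * (v[k, 2] - v[1, 2])) / 2
    tri_a <- tri_a + a
    tri_c <- tri_c + a * colMeans(v[c(1, k, k + 1), ])
  }
  expect_equal(unname(rs$centroids["P2", ]), unname(tri_c / tri_a),
               tolerance = 1e-12)
})

test_that("region reading rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,x,y", "A,0,0", "A,1,0"), f)
  expect_error(read_regions(f), "duplicate unit_id.*A")
  writeLines(c("unit_id,x,y", "A,0,0"), f)
  expect_error(read_regions(f), "at least 2")
  g <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(unit_id = "A"),
         geometry = list(type = "Point", coordinates = c(0, 0))))),
    g, auto_unbox = TRUE)
  expect_error(read_regions(g), "unsupported geometry")
})

test_that("case tables synthesize the all stratum additively", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,year,sex,cases,population",
               "A,1999,M,2,100000", "A,1999,F,1,110000"), f)
  ct <- read_cases(f)
  all_row <- ct[ct$stratum == "all", ]
  expect_equal(all_row$cases, 3L)
  expect_equal(all_row$population, 210000)
})

test_that("explicit all rows must agree with male + female", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,year,sex,cases,population",
               "A,1999,M,2,100000", "A,1999,F,1,110000",
               "A,1999,ALL,4,210000"), f)
  expect_error(read_cases(f), "disagrees with male\\+female")
})

test_that("case validation reports offending rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("unit_id,year,sex,cases,population", f)
  expect_error(read_cases(f), "empty")
  writeLines(c("unit_id,year,sex,cases,population", "A,1999,M,-1,1000"), f)
  expect_error(read_cases(f), "negative.*row 1")
  writeLines(c("unit_id,year,sex,cases,population", "A,1999,M,1,0"), f)
  expect_error(read_cases(f), "nonpositive population at row 1")
  writeLines(c("unit_id,year,sex,cases,population",
               "A,1999,M,1,10", "A,1999,M,2,10"), f)
  expect_error(read_cases(f), "duplicate")
})

test_that("a full synthetic case table round-trips through write/read", {
  study <- simulate_cases(sim_config(rng_seed = 42L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cases(study$cases, f)
  back <- read_cases(f)
  orig <- as.data.frame(study$cases)
  expect_equal(back$unit_id, orig$unit_id)
  expect_equal(back$cases, orig$cases)
  expect_equal(back$population, orig$population, tolerance = 1e-9)
  expect_equal(back$stratum, orig$stratum)
})

test_that("region sets round-trip through GeoJSON with centroids intact", {
  study <- simulate_cases(sim_config(rng_seed = 3L))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_regions(study$regions, f)
  back <- read_regions(f)
  expect_identical(back$ids, study$regions$ids)
  expect_equal(back$centroids, study$regions$centroids, tolerance = 1e-9)
})

test_that("join_check reports mismatches in both directions", {
  rs <- region_set(c("A", "B"), rbind(c(0, 0), c(1, 0)))
  ct <- case_table(data.frame(unit_id = "A", year = 1999L, stratum = "male",
                              cases = 1L, population = 1000))
  rep <- join_check(rs, ct)
  expect_false(rep$ok)
  expect_identical(rep$missing_cases, "B")
  expect_identical(rep$missing_geometry, character(0))
  ct2 <- case_table(data.frame(unit_id = c("A", "B", "C"), year = 1999L,
                               stratum = "male", cases = 1L,
                               population = 1000))
  rep2 <- join_check(rs, ct2)
  expect_identical(rep2$missing_geometry, "C")
  ct3 <- case_table(data.frame(unit_id = c("A", "B"), year = 1999L,
                               stratum = "male", cases = 1L,
                               population = 1000))
  expect_true(join_check(rs, ct3)$ok)
})
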