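# readers/writers and domain-type invariants for nuclei, masks, features

test_that("delimited nuclei tables read with types, ids and row order kept", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,type", "1.5,2,immune", "10,20,tumour", "3,4,stromal"), p)
  nk <- read_nuclei(p)
  expect_equal(nrow(nk), 3)
  expect_equal(as.character(nk$nucleus_type), c("immune", "tumour", "stromal"))
  expect_equal(nk$x, c(1.5, 10, 3))
  expect_true(all(is.na(nk$area_px)))
})

test_that("unknown nucleus labels map to 'other' with one warning", {
  expect_warning(
    nk <- nuclei_table(1:3, 1:3, c("immune", "lymphocyte-like", "tumour")),
    "lymphocyte-like"
  )
  expect_equal(as.character(nk$nucleus_type)[2], "other")
})

test_that("missing columns and non-numeric coordinates fail with context", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,type", "1,immune"), p)
  expect_error(read_nuclei(p), "y")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,type", "1,2,immune", "oops,4,tumour"), p2)
  expect_error(read_nuclei(p2), "row\\(s\\) 2")
})

test_that("GeoJSON polygons yield centroid and shoelace area", {
  p <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(list(c(0, 0), c(10, 0),
                                                   c(10, 10), c(0, 10)))),
           properties = list(type = "immune")),
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(3, 4)),
           properties = list(type = "tumour"))
    )
  )
  jsonlite::write_json(gj, p, auto_unbox = TRUE)
  nk <- read_nuclei(p)
  expect_equal(nk$x[1], 5)
  expect_equal(nk$y[1], 5)
  expect_equal(nk$area_px[1], 100)
  expect_equal(nk$x[2], 3)
  expect_true(is.na(nk$area_px[2]))
})

test_that("nuclei CSV round-trips exactly", {
  set.seed(5)
  nk <- random_nuclei(50)
  p <- withr::local_tempfile(fileext = ".csv")
  write_nuclei(nk, p)
  back <- read_nuclei(p)
  expect_equal(back$x, nk$x)
  expect_equal(back$y, nk$y)
  expect_equal(as.character(back$nucleus_type),
               as.character(nk$nucleus_type))
})

test_that("mask sets repair tumour/stroma overlap and report pixel counts", {
  tum <- matrix(FALSE, 10, 10); tum[2:5, 2:5] <- TRUE
  str <- matrix(FALSE, 10, 10); str[4:8, 4:8] <- TRUE  # overlaps 2x2 = 4 px
  expect_warning(
    ms <- region_mask_set(list(tumour = tum, stroma = str)),
    "4 pixel"
  )
  expect_false(any(ms$tumour & ms$stroma))
  expect_true(all(ms$tumour[2:5, 2:5]))
  # repair is idempotent
  expect_silent(ms2 <- region_mask_set(list(tumour = ms$tumour,
                                            stroma = ms$stroma,
                                            tissue = ms$tissue)))
  expect_identical(ms2$stroma, ms$stroma)
})

test_that("mask shape mismatch errors name the offenders", {
  a <- matrix(FALSE, 100, 100)
  b <- matrix(FALSE, 101, 100)
  expect_error(region_mask_set(list(tumour = a, stroma = b)),
               "tumour.*100x100.*stroma.*101x100")
})

test_that("masks round-trip through PNG files", {
  set.seed(9)
  tum <- random_blob_mask(32, 32, 2, c(4, 8))
  str <- !tum
  str[1:2, ] <- FALSE
  ms <- suppressWarnings(region_mask_set(list(tumour = tum, stroma = str)))
  d <- withr::local_tempdir()
  paths <- write_masks(ms, d)
  back <- read_masks(paths)
  expect_identical(back$tumour, ms$tumour)
  expect_identical(back$stroma, ms$stroma)
  expect_identical(back$tissue, ms$tissue)
})

test_that("slide features JSON round-trips exactly, including the CM", {
  cm <- matrix(c(5L, 2L, 7L,
                 2L, 9L, 8L,
                 7L, 8L, 1L), 3, 3,
               dimnames = list(c("tumour", "stromal", "immune"),
                               c("tumour", "stromal", "immune")))
  sf <- slide_features(3, 2, 6, 7.6, cm,
                       heterogeneity = 2.1234567890123,
                       contrast = 0.4444444444444)
  p <- withr::local_tempfile(fileext = ".json")
  write_features(sf, p)
  back <- read_features(p)
  expect_identical(back$cm, sf$cm)
  expect_identical(back$stils_pct, 7.6)
  expect_identical(back$heterogeneity, sf$heterogeneity)
  expect_identical(back$contrast, sf$contrast)
  expect_equal(back$cm["tumour", "immune"], 7L, ignore_attr = TRUE)
  # NA percentage (empty TAS) survives the round trip as missing
  sf2 <- slide_features(0, 0, 0, NA_real_, cm * 0L, 0, 0)
  write_features(sf2, p)
  expect_true(is.na(read_features(p)$stils_pct))
})

test_that("cohort tables reject time 0 and duplicate ids at load", {
  d <- withr::local_tempdir()
  co <- tibble::tibble(patient_id = c("a", "b"), time_months = c(5, 0),
                       event = c(TRUE, FALSE))
  p <- file.path(d, "c.csv")
  readr::write_csv(co, p)
  expect_error(read_cohort(p), "time")
  co2 <- tibble::tibble(patient_id = c("a", "a"), time_months = c(5, 3),
                        event = c(TRUE, FALSE))
  readr::write_csv(co2, p)
  expect_error(read_cohort(p), "unique")
})
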