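make_regions <- function() {
  tum <- matrix(FALSE, 40, 40); tum[5:20, 5:20] <- TRUE
  tas <- matrix(FALSE, 40, 40); tas[5:20, 21:30] <- TRUE
  oth <- matrix(FALSE, 40, 40); oth[25:39, 2:39] <- TRUE
  analysis_regions(tum, tas, oth)
}

test_that("region assignment follows pixel membership with rounding tie-break", {
  rg <- make_regions()
  nk <- nuclei_table(
    x = c(25, 10, 3, 4.5, 1),
    y = c(10, 10, 30, 4.5, 5),
    type = c("immune", "immune", "stromal", "tumour", "immune")
  )
  nk$x[5] <- -1  # out-of-grid coordinate injected downstream of the reader
  expect_warning(lab <- assign_regions(nk, rg), "outside")
  expect_equal(as.character(lab$region_label),
               c("tas", "tumour_region", "other", "tumour_region", "excluded"))
})

test_that("centroids on a .5 boundary round half-up into the next pixel", {
  # region occupies 0-based rows/cols 3..9; a nucleus at 2.5 rounds to 3
  tum <- matrix(FALSE, 12, 12); tum[4:10, 4:10] <- TRUE
  rg <- analysis_regions(tum, matrix(FALSE, 12, 12), !tum)
  lab <- assign_regions(nuclei_table(c(2.5, 2.4), c(2.5, 2.4),
                                     c("immune", "immune")), rg)
  expect_equal(as.character(lab$region_label), c("tumour_region", "other"))
})

test_that("nuclei on unlabelled pixels are excluded and never counted", {
  rg <- make_regions()
  nk <- nuclei_table(x = c(1, 25), y = c(1, 10), type = c("immune", "immune"))
  lab <- assign_regions(nk, rg)
  expect_equal(as.character(lab$region_label), c("excluded", "tas"))
  ct <- count_tils(lab)
  expect_equal(ct$total_tils, 1)
})

test_that("TILs counts match a per-nucleus brute-force tally", {
  rg <- make_regions()
  set.seed(3)
  nk <- nuclei_table(x = runif(500, 0, 39), y = runif(500, 0, 39),
                     type = sample(c("immune", "tumour", "stromal"), 500,
                                   replace = TRUE))
  lab <- assign_regions(nk, rg)
  ct <- count_tils(lab)
  # brute force recount
  stils <- 0; ttils <- 0; tot <- 0
  for (i in seq_len(500)) {
    if (as.character(lab$nucleus_type[i]) != "immune") next
    l <- as.character(lab$region_label[i])
    if (l == "tas") stils <- stils + 1
    if (l == "tumour_region") ttils <- ttils + 1
    if (l != "excluded") tot <- tot + 1
  }
  expect_equal(ct$stils_count, stils)
  expect_equal(ct$ttils_count, ttils)
  expect_equal(ct$total_tils, tot)
  # conservation: stils + ttils + immune(other) = total
  n_other <- sum(lab$nucleus_type == "immune" & lab$region_label == "other")
  expect_equal(ct$stils_count + ct$ttils_count + n_other, ct$total_tils)
})

test_that("sTILs percentage is area ratio, clamped, and NA on empty TAS", {
  rg <- make_regions()  # tas area = 16 * 10 = 160
  nk <- nuclei_table(x = c(25, 26), y = c(10, 11), type = c("immune", "immune"),
                     area_px = c(50, NA))
  lab <- assign_regions(nk, rg)
  expect_equal(stils_percentage(lab, rg, default_nucleus_area = 28),
               100 * (50 + 28) / 160)
  # worked arithmetic: 76 px immune over 1000 px TAS = 7.6%
  tas1000 <- analysis_regions(matrix(FALSE, 50, 50),
                              rbind(matrix(TRUE, 20, 50),
                                    matrix(FALSE, 30, 50)),
                              matrix(FALSE, 50, 50))
  nk2 <- nuclei_table(x = c(10, 20), y = c(5, 6), type = c("immune", "immune"),
                      area_px = c(40, 36))
  expect_equal(stils_percentage(assign_regions(nk2, tas1000), tas1000), 7.6)
  # no immune in TAS -> 0
  expect_equal(stils_percentage(assign_regions(
    nuclei_table(5, 5, "stromal"), rg), rg), 0)
  # clamp
  nk3 <- nuclei_table(25, 10, "immune", area_px = 1e6)
  expect_warning(p <- stils_percentage(assign_regions(nk3, rg), rg), "clamp")
  expect_equal(p, 100)
  # empty TAS -> NA with warning
  e <- matrix(FALSE, 5, 5)
  rg0 <- analysis_regions(e, e, e)
  expect_warning(p0 <- stils_percentage(assign_regions(nk3, rg0), rg0), "TAS")
  expect_true(is.na(p0))
})

test_that("co-occurrence pairs follow the distance rule exactly", {
  nk <- nuclei_table(x = c(0, 0), y = c(0, 10), type = c("immune", "stromal"))
  cm12 <- cooccurrence_matrix(nk, radius_px = 12)
  expect_equal(cm12["immune", "stromal"], 1, ignore_attr = TRUE)
  expect_equal(cm12["stromal", "immune"], 1, ignore_attr = TRUE)
  expect_equal(sum(cm12), 2)
  expect_equal(sum(cooccurrence_matrix(nk, radius_px = 5)), 0)
  # three mutually close nuclei of distinct types: each cross entry 1
  nk3 <- nuclei_table(x = c(0, 3, 0), y = c(0, 0, 3),
                      type = c("tumour", "stromal", "immune"))
  cm <- cooccurrence_matrix(nk3, radius_px = 10)
  expect_true(all(diag(cm) == 0))
  expect_true(all(cm[upper.tri(cm)] == 1))
  expect_error(cooccurrence_matrix(nk3, radius_px = 0), "radius")
})

test_that("spatial-index CM equals the all-pairs oracle and is monotone in radius", {
  set.seed(17)
  for (i in 1:5) {
    nk <- random_nuclei(300, extent = 400)
    r <- sample(c(10, 32, 60), 1)
    expect_identical(cooccurrence_matrix(nk, radius_px = r),
                     oracle_cm(nk, r))
  }
  nk <- random_nuclei(400, extent = 300)
  c1 <- cooccurrence_matrix(nk, radius_px = 15)
  c2 <- cooccurrence_matrix(nk, radius_px = 40)
  expect_true(all(c2 >= c1))
})

test_that("CM scalars: entropy, contrast, and named co-occurrence cells", {
  one <- matrix(0L, 3, 3, dimnames = list(c("tumour", "stromal", "immune"),
                                          c("tumour", "stromal", "immune")))
  one["tumour", "tumour"] <- 12L
  f <- cm_features(one)
  expect_equal(f$heterogeneity, 0)

  # uniform over the 6 unordered pairs -> log2(6) bits
  unif <- matrix(2L, 3, 3, dimnames = dimnames(one))
  diag(unif) <- 2L
  f2 <- cm_features(unif)
  expect_equal(f2$heterogeneity, log2(6))

  # hand-evaluated contrast: (8 + 4) / 16 = 0.75
  cm <- matrix(0L, 3, 3, dimnames = dimnames(one))
  cm["stromal", "immune"] <- cm["immune", "stromal"] <- 8L
  cm["tumour", "immune"] <- cm["immune", "tumour"] <- 4L
  cm["tumour", "stromal"] <- cm["stromal", "tumour"] <- 4L
  f3 <- cm_features(cm)
  expect_equal(f3$contrast, 0.75)
  expect_equal(f3$stroma_immune_cooc, 8L)
  expect_equal(f3$tumour_immune_cooc, 4L)
  # all-zero CM -> all features 0
  f0 <- cm_features(one * 0L)
  expect_equal(unlist(f0), c(stroma_immune_cooc = 0, tumour_immune_cooc = 0,
                             heterogeneity = 0, contrast = 0))
  # asymmetric CM violates the contract
  bad <- one; bad[1, 2] <- 5L
  expect_error(cm_features(bad), "symmetric")
})

test_that("slide features are order- and translation-invariant", {
  sl <- generate_slide(slide_sim_config(width = 128, height = 128, seed = 5))
  sf <- compute_slide_features(sl$nuclei, sl$masks)
  set.seed(1)
  perm <- sample(nrow(sl$nuclei))
  sf_perm <- compute_slide_features(sl$nuclei[perm, ], sl$masks)
  expect_identical(tidy(sf), tidy(sf_perm))
  expect_identical(sf$cm, sf_perm$cm)

  # translate masks and nuclei by the same offset
  off <- 7
  shift_mask <- function(m) {
    out <- matrix(FALSE, nrow(m) + off, ncol(m) + off)
    out[off + seq_len(nrow(m)), off + seq_len(ncol(m))] <- m
    out
  }
  ms2 <- suppressWarnings(region_mask_set(list(
    tissue = shift_mask(sl$masks$tissue),
    tumour = shift_mask(sl$masks$tumour),
    stroma = shift_mask(sl$masks$stroma)
  ), scale_note = "shifted"))
  nk2 <- dplyr::mutate(sl$nuclei, x = x + off, y = y + off)
  sf_shift <- compute_slide_features(nk2, ms2)
  expect_identical(tidy(sf), tidy(sf_shift))
})

test_that("a slide with no tumour yields zero tTILs and missing percentage", {
  str <- matrix(TRUE, 60, 60)
  ms <- region_mask_set(list(tumour = matrix(FALSE, 60, 60), stroma = str))
  nk <- nuclei_table(x = c(10, 20), y = c(10, 20),
                     type = c("immune", "immune"))
  sf <- suppressWarnings(compute_slide_features(nk, ms))
  expect_equal(sf$ttils_count, 0L)
  expect_equal(sf$stils_count, 0L)
  expect_true(is.na(sf$stils_pct))
  expect_equal(sf$total_tils, 2L)  # immune in 'other' tissue still counted
})
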