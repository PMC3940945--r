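# Area fraction, micro-vessel density, Chalkley count.

test_that("area fraction boundary cases and oracle equivalence", {
  ev <- matrix(TRUE, 32, 32)
  full <- matrix(TRUE, 32, 32)
  empty <- matrix(FALSE, 32, 32)
  roi <- roi_circle(c(0.16, 0.16), area_mm2 = pi * 0.08^2)
  expect_equal(area_fraction(full, roi, ev, mpp = 10), 100)
  expect_equal(area_fraction(empty, roi, ev, mpp = 10), 0)
  expect_error(area_fraction(full, roi, matrix(FALSE, 32, 32), mpp = 10),
               "no evaluable")

  for (s in 1:30) {
    m <- random_mask(32, 32, seed = s, p_seed = 0.05, grow = 1L)
    rp <- roi_pixels(roi, c(32, 32), 10)
    expect_equal(area_fraction(m, roi, ev, mpp = 10),
                 oracle_area_fraction(m, rp, ev))
  }
})

test_that("MVD counts disjoint vessels and bridges interrupted rings", {
  ev <- matrix(TRUE, 40, 40)
  # three disjoint disks, centroids inside the whole-slide ROI
  m <- paint_disks(toy_mask(40, 40),
                   rbind(c(0.01, 0.01), c(0.03, 0.03), c(0.01, 0.03)),
                   radius_mm = 0.003, mpp = 1)
  expect_equal(microvessel_density(m, roi_whole_slide(), ev, merge_gap_um = 0,
                                   mpp = 1)$count, 3L)
  expect_equal(microvessel_density(matrix(FALSE, 40, 40), roi_whole_slide(), ev,
                                   merge_gap_um = 0, mpp = 1)$count, 0L)

  # a ring broken by a 1-pixel gap: two components raw, one after closing
  ring <- toy_mask(21, 21)
  for (r in 1:21) for (cc in 1:21) {
    d <- sqrt((r - 11)^2 + (cc - 11)^2)
    if (d >= 6 && d <= 8) ring[r, cc] <- TRUE
  }
  ring[11, ] <- FALSE # split into two arcs by a full horizontal cut of width 1
  expect_equal(oracle_label_count(ring), 2L)
  expect_equal(microvessel_density(ring, roi_whole_slide(), matrix(TRUE, 21, 21),
                                   merge_gap_um = 0, mpp = 1)$count, 2L)
  expect_equal(microvessel_density(ring, roi_whole_slide(), matrix(TRUE, 21, 21),
                                   merge_gap_um = 1, mpp = 1)$count, 1L)
})

test_that("MVD with zero merge gap equals brute-force 8-connected labeling", {
  for (s in 1:50) {
    m <- random_mask(48, 48, seed = 100 + s, p_seed = 0.03, grow = 1L)
    got <- microvessel_density(m, roi_whole_slide(), matrix(TRUE, 48, 48),
                               merge_gap_um = 0, mpp = 1)$count
    expect_equal(got, oracle_label_count(m))
  }
})

test_that("Chalkley extremes are attained on blank and full masks", {
  hs <- roi_circle(c(0.32, 0.32), area_mm2 = 0.26)
  blank <- matrix(FALSE, 64, 64)
  full <- matrix(TRUE, 64, 64)
  expect_equal(chalkley_count(blank, hs, mpp = 10), 0L)
  expect_equal(chalkley_count(full, hs, mpp = 10), 25L)
  expect_error(chalkley_count(full, roi_whole_slide(), mpp = 10), "circular")
})

test_that("Chalkley equals exhaustive placement search on structured masks", {
  grat <- chalkley_graticule()
  expect_equal(nrow(grat$dots), 25L)
  expect_true(all(rowSums(grat$dots^2) <= 1))
  d <- as.matrix(dist(grat$dots))
  expect_gte(min(d[upper.tri(d)]), 0.18)

  hs <- roi_circle(c(0.6, 0.6), area_mm2 = 0.26)
  masks <- list()
  half <- matrix(FALSE, 120, 120); half[, 1:60] <- TRUE # half-plane through centre
  masks[[1]] <- half
  for (s in 1:12) masks[[s + 1]] <- random_mask(120, 120, seed = 200 + s,
                                                p_seed = 0.02, grow = 2L)
  for (m in masks) {
    got <- chalkley_count(m, hs, grat, n_rotations = 16, n_offsets = 5,
                          jitter_frac = 0.1, mpp = 10)
    want <- oracle_chalkley(m, hs$center, hs$radius_mm, grat$dots, 10,
                            n_rotations = 16, n_offsets = 5, jitter_frac = 0.1)
    expect_equal(got, want)
    expect_gte(got, 0L); expect_lte(got, 25L)
  }
})

test_that("Chalkley count is monotone under mask dilation", {
  hs <- roi_circle(c(0.6, 0.6), area_mm2 = 0.26)
  brush <- EBImage::makeBrush(5, "disc")
  for (s in 1:8) {
    m1 <- random_mask(120, 120, seed = 300 + s, p_seed = 0.01, grow = 1L)
    m2 <- EBImage::dilate(matrix(as.numeric(m1), 120, 120), brush) > 0.5
    expect_lte(chalkley_count(m1, hs, n_rotations = 8, n_offsets = 3, mpp = 10),
               chalkley_count(m2, hs, n_rotations = 8, n_offsets = 3, mpp = 10))
  }
})

test_that("area fraction correlates strongly with MVD and Chalkley in fixed ROIs", {
  plan <- cohort_plan(10, marker_spec = default_marker_spec()["cd31"],
                      master_seed = 21L, mpp = 8)
  cfg <- ihc_config()
  afs <- c(); mvds <- c(); cks <- c()
  for (i in seq_len(nrow(plan))) {
    sl <- render_cohort_slide(plan, i)
    maps <- deconvolve_stains(sl$slide)
    thr <- estimate_threshold(maps$chromogen, sl$slide$tissue_mask, cfg$od_floor)
    mask <- immunoreactive_mask(maps$chromogen, sl$slide$tissue_mask, thr,
                                cfg$min_object_px, mpp = sl$slide$mpp)
    for (ctr in list(c(3, 3), c(4, 4), c(5, 4.5))) {
      roi <- roi_circle(ctr, 0.26)
      afs <- c(afs, area_fraction(mask, roi, sl$slide$tissue_mask))
      mvds <- c(mvds, microvessel_density(mask, roi, sl$slide$tissue_mask,
                                          merge_gap_um = cfg$merge_gap_um)$count)
      cks <- c(cks, chalkley_count(mask, roi, mpp = sl$slide$mpp))
    }
  }
  expect_gte(pearson_correlation(afs, mvds, pair = c("af", "mvd"))$r, 0.7)
  expect_gte(pearson_correlation(afs, cks, pair = c("af", "chalkley"))$r, 0.7)
})
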