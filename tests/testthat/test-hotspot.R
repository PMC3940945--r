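# Hot-spot selection and the evident-hot-spot index.

test_that("zero mask picks the first valid grid centres in scan order", {
  nr <- 200; nc <- 200; mpp <- 10 # 2 x 2 mm
  ev <- matrix(TRUE, nr, nc)
  m <- matrix(FALSE, nr, nc)
  hs <- select_hotspots(m, ev, k = 2, hotspot_area_mm2 = 0.26, mpp = mpp)
  expect_equal(hs$density, c(0, 0))
  # reproduce the contract independently: stride grid, row-major, first valid
  r_px <- sqrt(0.26 / pi) / (mpp / 1000)
  kr <- ceiling(r_px); stride <- floor(0.25 * r_px)
  grows <- seq(kr + 1, nr - kr, by = stride)
  gcols <- seq(kr + 1, nc - kr, by = stride)
  first <- c(grows[1], gcols[1])
  # with a fully evaluable raster the first candidate is valid
  expect_equal(hs$hotspots[[1]]$center,
               c((first[2] - 0.5) * mpp / 1000, (first[1] - 0.5) * mpp / 1000))
  # second pick: next candidate in scan order at distance >= 2r
  cand <- cbind(rep(grows, each = length(gcols)), rep(gcols, length(grows)))
  ok <- (cand[, 1] - first[1])^2 + (cand[, 2] - first[2])^2 >= (2 * r_px)^2
  second <- cand[which(ok)[1], ]
  expect_equal(hs$hotspots[[2]]$center,
               c((second[2] - 0.5) * mpp / 1000, (second[1] - 0.5) * mpp / 1000))
})

test_that("a planted dense cluster is found and clusters rank by density", {
  mpp <- 10
  ev <- matrix(TRUE, 300, 300) # 3 x 3 mm
  set.seed(5)
  parent <- c(1.1, 1.4)
  pts <- cbind(rnorm(120, parent[1], 0.1), rnorm(120, parent[2], 0.1))
  m <- paint_disks(toy_mask(300, 300), pts, radius_mm = 0.012, mpp = mpp)
  hs <- select_hotspots(m, ev, k = 1, mpp = mpp)
  expect_lt(sqrt(sum((hs$hotspots[[1]]$center - parent)^2)), 0.2)

  # second, weaker cluster: hot spots rank in density order
  parent2 <- c(2.3, 2.2)
  pts2 <- cbind(rnorm(40, parent2[1], 0.1), rnorm(40, parent2[2], 0.1))
  m2 <- paint_disks(m, pts2, radius_mm = 0.012, mpp = mpp)
  hs2 <- select_hotspots(m2, ev, k = 2, mpp = mpp)
  expect_lt(sqrt(sum((hs2$hotspots[[1]]$center - parent)^2)), 0.2)
  expect_lt(sqrt(sum((hs2$hotspots[[2]]$center - parent2)^2)), 0.2)
  expect_true(all(diff(hs2$density) <= 0))
  # non-overlap
  d <- sqrt(sum((hs2$hotspots[[1]]$center - hs2$hotspots[[2]]$center)^2))
  expect_gte(d, 2 * hs2$hotspots[[1]]$radius_mm - 1e-9)
})

test_that("greedy selection matches exhaustive densest-pair search on small rasters", {
  mpp <- 20 # hot-spot radius ~14.4 px on a 128 px raster
  ev <- matrix(TRUE, 128, 128)
  r_px <- sqrt(0.26 / pi) / (mpp / 1000)
  stride <- floor(0.25 * r_px)
  for (s in 1:6) {
    m <- random_mask(128, 128, seed = 400 + s, p_seed = 0.004, grow = 3L)
    hs <- select_hotspots(m, ev, k = 2, mpp = mpp)
    oracle <- oracle_best_pair(m, ev, r_px, stride)
    expect_equal(sum(hs$density), oracle$total)
  }
})

test_that("evidence ratio is exactly one when the mask fills the tissue", {
  ev <- matrix(TRUE, 150, 150)
  hs <- select_hotspots(ev, ev, k = 3, mpp = 10)
  res <- hotspot_evidence(hs, whole_slide_fraction = 100)
  expect_equal(res$evidence_ratio, 1)
  expect_false(res$evident)
  expect_true(res$defined)
})

test_that("uniform random texture gives a mild ratio; a single cluster an extreme one", {
  mpp <- 16
  nr <- 500 # 8 x 8 mm
  ev <- matrix(TRUE, nr, nr)
  # perfectly uniform texture (checkerboard): ratio 1 up to discretization
  m <- outer(seq_len(nr), seq_len(nr), function(i, j) (i + j) %% 2L == 0L)
  hs <- select_hotspots(m, ev, k = 3, mpp = mpp)
  ws <- 100 * mean(m)
  res <- hotspot_evidence(hs, ws)
  expect_lt(abs(res$evidence_ratio - 1), 0.05)
  expect_false(res$evident)

  # all stain inside one hot-spot-sized cluster on an otherwise blank slide
  m2 <- paint_disks(toy_mask(nr, nr), rbind(c(4, 4)), radius_mm = sqrt(0.26 / pi),
                    mpp = mpp)
  hs2 <- select_hotspots(m2, ev, k = 3, mpp = mpp)
  ws2 <- 100 * mean(m2)
  res2 <- hotspot_evidence(hs2, ws2)
  expect_gt(res2$evidence_ratio, 2)
  expect_true(res2$evident)
  # closed-form bound: ratio cannot exceed slide area / (k x hot-spot area)
  expect_lte(res2$evidence_ratio, (8 * 8) / (3 * 0.26) + 1)

  # zero whole-slide fraction: flagged, not computed
  und <- hotspot_evidence(hs2, 0)
  expect_false(und$defined)
  expect_true(is.na(und$evidence_ratio))
})

test_that("evidence ratio under homogeneous masks concentrates near 1 as intensity grows", {
  mpp <- 16; nr <- 250 # 4 x 4 mm
  ev <- matrix(TRUE, nr, nr)
  ratio_at <- function(lambda, seeds) {
    vapply(seeds, function(s) {
      p <- spatial_pattern_params("homogeneous", intensity = lambda,
                                  object_kind = "cell", cell_radius = 0.012)
      reg <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
      pts <- sample_point_pattern(p, reg, seed = s)
      m <- paint_disks(toy_mask(nr, nr), pts, radius_mm = 0.012, mpp = mpp)
      hs <- select_hotspots(m, ev, k = 3, mpp = mpp)
      hotspot_evidence(hs, 100 * mean(m))$evidence_ratio
    }, numeric(1))
  }
  lo <- ratio_at(30, 1:100)
  hi <- ratio_at(300, 101:200)
  expect_gt(mean(lo), mean(hi)) # enrichment shrinks with intensity
  expect_lt(mean(hi), 1.5)      # and concentrates towards 1
})

test_that("tissue too small for the requested hot spots is rejected", {
  ev <- matrix(FALSE, 100, 100)
  ev[40:60, 40:60] <- TRUE # ~0.044 mm^2 at 10 um/px
  m <- matrix(FALSE, 100, 100)
  expect_error(select_hotspots(m, ev, k = 3, mpp = 10), "too small")
})
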