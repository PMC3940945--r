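# Color deconvolution, per-slide thresholding, immunoreactive mask.

test_that("pure white pixels carry zero stain and pure chromogen round-trips", {
  v <- stain_vectors()
  white <- array(255L, c(1, 1, 3))
  maps <- deconvolve_stains(white, v)
  expect_equal(maps$counterstain[1, 1], 0)
  expect_equal(maps$chromogen[1, 1], 0)

  rgb <- compose_rgb(cbind(0, 1), v) # chromogen at OD 1.0, no counterstain
  px <- array(as.integer(rgb), c(1, 1, 3))
  m2 <- deconvolve_stains(px, v)
  expect_equal(m2$chromogen[1, 1], 1, tolerance = 0.02)
  expect_lt(m2$counterstain[1, 1], 0.02)
})

test_that("random stain mixtures are recovered through the 8-bit round trip", {
  v <- stain_vectors()
  set.seed(41)
  n <- 10000L
  conc <- cbind(runif(n, 0, 2), runif(n, 0, 2))
  # float path: exact inversion to 1e-6
  od_float <- conc %*% unclass(v)[1:2, ]
  rec_float <- od_float %*% solve(unclass(v))
  expect_lt(max(abs(rec_float[, 1:2] - conc)), 1e-6)
  expect_lt(max(abs(rec_float[, 3])), 1e-6)

  # quantized path: error bounded by the propagated half-step OD perturbation
  rgb <- compose_rgb(conc, v)
  px <- array(as.integer(rgb), c(n, 1, 3))
  maps <- deconvolve_stains(px, v)
  rec <- cbind(maps$counterstain[, 1], maps$chromogen[, 1])
  od_quant <- -log10((rgb + 1 / 255) / 255)
  od_err <- apply(abs(od_quant - od_float), 1, max)
  m_inv_norm <- max(rowSums(abs(solve(unclass(v)))))
  bound <- 3 * m_inv_norm * od_err + 1e-9
  expect_true(all(abs(rec - conc) <= cbind(bound, bound)))
  # and the typical error is at the quantization scale
  expect_lt(stats::median(abs(rec - conc)), 0.01)
})

test_that("unclipped deconvolution recomposes the OD image exactly", {
  v <- stain_vectors()
  set.seed(7)
  conc <- cbind(runif(400, 0.1, 1.5), runif(400, 0.1, 1.5))
  px <- array(as.integer(compose_rgb(conc, v)), c(20, 20, 3))
  od <- -log10((px + 1 / 255) / 255)
  exact <- deconvolve_stains(px, v, clip = FALSE)
  expect_lt(max(abs(recompose_od(exact) - od)), 1e-9)
  # the default clipped maps only lose the negative quantization noise
  clipped <- deconvolve_stains(px, v)
  expect_lt(max(abs(recompose_od(clipped) - od)), 0.05)
})

test_that("near-singular stain matrices are rejected with the condition number", {
  expect_error(stain_vectors(c(1, 0, 0), c(0.999, 0.04, 0.001), max_condition = 10),
               "condition number")
})

test_that("Otsu threshold matches brute force and respects the OD floor", {
  # clearly bimodal map
  set.seed(13)
  vals <- c(rnorm(600, 0.1, 0.02), rnorm(400, 1.0, 0.05))
  m <- matrix(vals, 40, 25)
  tis <- matrix(TRUE, 40, 25)
  thr <- estimate_threshold(m, tis, od_floor = 0)
  expect_gt(thr, 0.1)
  expect_lt(thr, 1.0)

  # constant map returns the floor
  expect_equal(estimate_threshold(matrix(0.4, 10, 10), matrix(TRUE, 10, 10),
                                  od_floor = 0.15), 0.15)
  expect_error(estimate_threshold(m, matrix(FALSE, 40, 25)), "empty")

  # brute-force equivalence on random maps: the partition induced by the
  # returned threshold must agree with the exhaustive maximizer's partition
  # up to points within one histogram bin of the cut (between well-separated
  # modes any threshold in the empty gap is an equally valid maximizer)
  for (s in 1:40) {
    set.seed(s)
    n1 <- sample(50:300, 1)
    v <- c(rnorm(n1, runif(1, 0, 0.3), 0.05), rnorm(576 - n1, runif(1, 0.6, 1.4), 0.1))
    v <- pmax(v, 0)
    mm <- matrix(v, 24, 24)
    thr <- estimate_threshold(mm, matrix(TRUE, 24, 24), od_floor = 0)
    bin <- diff(range(v)) / 256
    bt <- oracle_otsu(v)
    disagree <- v[xor(v >= thr, v >= bt)]
    expect_true(all(abs(disagree - thr) <= bin + 1e-12))
    # and the achieved between-class variance is the oracle's maximum
    bcv <- function(t) {
      lo <- v[v < t]; hi <- v[v >= t]
      if (!length(lo) || !length(hi)) return(0)
      length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    }
    expect_gte(bcv(thr), 0.99 * bcv(bt))
  }
})

test_that("immunoreactive mask applies threshold, tissue and size filter", {
  tis <- matrix(TRUE, 10, 10)
  m <- matrix(0, 10, 10); m[5, 5] <- 2
  expect_equal(sum(immunoreactive_mask(m, tis, 1, min_object_px = 2)$mask), 0)
  expect_equal(sum(immunoreactive_mask(m, tis, 1, min_object_px = 1)$mask), 1)
  u <- matrix(2, 10, 10)
  tis2 <- matrix(FALSE, 10, 10); tis2[3:8, 3:8] <- TRUE
  expect_identical(immunoreactive_mask(u, tis2, 1, min_object_px = 1)$mask, tis2)
})

test_that("masks are monotone in the threshold before size filtering", {
  set.seed(3)
  m <- matrix(runif(400, 0, 2), 20, 20)
  tis <- matrix(TRUE, 20, 20)
  for (pair in list(c(0.2, 0.8), c(0.5, 0.6), c(1.0, 1.7))) {
    lo <- immunoreactive_mask(m, tis, pair[1], min_object_px = 1)$mask
    hi <- immunoreactive_mask(m, tis, pair[2], min_object_px = 1)$mask
    expect_true(all(lo[hi])) # hi subset of lo
  }
})

test_that("mask pixel count on a rendered slide matches ground truth within 2%", {
  p <- spatial_pattern_params("homogeneous", intensity = 40, object_kind = "vessel")
  r <- render_slide(p, stain = stain_model_params(mpp = 8), canvas_mm = c(4, 4), seed = 23)
  maps <- deconvolve_stains(r$slide)
  # threshold below the minimum painted OD (0.6), above unmixing noise
  mask <- immunoreactive_mask(maps$chromogen, r$slide$tissue_mask, 0.3,
                              min_object_px = 4, mpp = 8)
  expect_lt(abs(sum(mask$mask) - sum(r$truth$painted_mask)) / sum(r$truth$painted_mask),
            0.02)
})

test_that("measured area fraction converges to truth as resolution increases", {
  p <- spatial_pattern_params("homogeneous", intensity = 30, object_kind = "vessel")
  err <- vapply(c(8, 4), function(mpp) {
    r <- render_slide(p, stain = stain_model_params(mpp = mpp),
                      canvas_mm = c(4, 4), seed = 31)
    maps <- deconvolve_stains(r$slide)
    thr <- estimate_threshold(maps$chromogen, r$slide$tissue_mask)
    mask <- immunoreactive_mask(maps$chromogen, r$slide$tissue_mask, thr, mpp = mpp)
    abs(area_fraction(mask, roi_whole_slide(), r$slide$tissue_mask) -
          r$truth$true_area_fraction)
  }, numeric(1))
  expect_lt(err[2], 0.2)
  expect_lt(err[2], err[1] + 0.05)
})
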