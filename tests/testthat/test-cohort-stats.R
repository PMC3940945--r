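# Exclusion filtering, Pearson correlation, interobserver variability,
# method comparison.

make_records <- function(ws, hs, marker = "cd31", marker_kind = "vessel",
                         area = 40, pattern = NA_character_) {
  n <- length(ws)
  data.frame(slide_id = sprintf("S%02d", seq_len(n)), marker = marker,
             marker_kind = marker_kind, evaluable_area_mm2 = area,
             excluded = FALSE, threshold = 0.3,
             whole_slide_area_fraction = ws, hotspot_mean_area_fraction = hs,
             evidence_ratio = hs / ws, evident = hs / ws >= 2,
             whole_slide_cell_density = if (marker_kind == "cell") ws else NA_real_,
             hotspot_mean_cell_density = if (marker_kind == "cell") hs else NA_real_,
             pattern_kind = pattern, true_area_fraction = NA_real_,
             hotspot_area_fractions = I(lapply(hs, function(v) rep(v, 3))),
             mvd = I(lapply(seq_len(n), function(i) c(3L, 4L, 5L))),
             mvd_per_mm2 = I(lapply(seq_len(n), function(i) c(3, 4, 5) / 0.26)),
             chalkley = I(lapply(seq_len(n), function(i) c(5L, 6L, 7L))),
             hotspot_cell_densities = I(lapply(hs, function(v) rep(v, 3))),
             stringsAsFactors = FALSE)
}

test_that("exclusion is strict at the boundary, idempotent, and keeps records", {
  rec <- make_records(ws = c(5, 6, 7), hs = c(6, 7, 8))
  rec$evaluable_area_mm2 <- c(4.9, 5.0, 70)
  out <- apply_exclusion_filter(rec, 5)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(out), 3L) # marked, never deleted
  expect_identical(apply_exclusion_filter(out, 5), out)
  empty <- apply_exclusion_filter(rec[0, ], 5)
  expect_equal(nrow(empty), 0L)
})

test_that("Pearson correlation: exact cases, hand-computed oracle, validation", {
  x <- c(1, 3, 5, 7)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  # direct product-moment formula as the oracle
  oracle_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  ct <- pearson_correlation(a, b)
  expect_equal(ct$r, oracle_r, tolerance = 1e-12)
  # two-sided p from the t transform with n - 2 df
  tstat <- oracle_r * sqrt(3 / (1 - oracle_r^2))
  expect_equal(ct$p, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)

  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
})

test_that("Pearson r is invariant under affine rescaling", {
  set.seed(99)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(10 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -0.5 * y + 7)$r, -r0, tolerance = 1e-12)
})

test_that("interobserver variability: formula, strict 10% bound, modes", {
  # one slide at the boundary: |10 - 11| / 10 * 100 = 10% -> not acceptable
  res <- interobserver_variability(c(10, 10), c(11, 9))
  expect_equal(res$cohort_mean, 10)
  expect_equal(res$per_slide_variability, c(10, 10))
  expect_equal(res$acceptable, c(FALSE, FALSE))

  eq <- interobserver_variability(c(3, 4, 5), c(3, 4, 5))
  expect_true(all(eq$per_slide_variability == 0))
  expect_true(all(eq$acceptable))

  # worked example: cohort mean 3.5, |delta| = 1 -> 28.571%
  ex <- interobserver_variability(c(2, 4), c(3, 5))
  expect_equal(ex$cohort_mean, 3.5)
  expect_equal(ex$per_slide_variability, c(100 / 3.5, 100 / 3.5))

  ps <- interobserver_variability(c(2, 4), c(3, 5), mean_mode = "per_slide")
  expect_equal(ps$per_slide_variability, c(1 / 2.5, 1 / 4.5) * 100)

  expect_error(interobserver_variability(c(0, 0), c(0, 0)), "positive")
  expect_error(interobserver_variability(1:3, 1:2), "length")
})

test_that("self-copied hot-spot values give r = 1 and small cohorts are flagged", {
  set.seed(4)
  ws <- runif(12, 2, 10)
  rec <- make_records(ws = ws, hs = ws)
  cmp <- compare_methods(rec, min_n = 10)
  expect_equal(cmp$marker_correlations$cd31$r, 1)
  expect_true(all(cmp$ratios$ratio == 1))

  small <- make_records(ws = ws[1:5], hs = ws[1:5] * 2)
  cmp2 <- compare_methods(small, min_n = 10)
  expect_null(cmp2$marker_correlations$cd31)
  expect_true(any(grepl("cd31", cmp2$flags)))

  # excluded slides never enter the statistics
  rec$evaluable_area_mm2[1:3] <- 1
  cmp3 <- compare_methods(rec, min_n = 5)
  expect_equal(cmp3$n_excluded, 3L)
  expect_equal(cmp3$marker_correlations$cd31$n, 9L)
})

test_that("simulated observers stay close on a rendered slide", {
  p <- spatial_pattern_params("homogeneous", intensity = 40, object_kind = "vessel")
  r <- render_slide(p, stain = stain_model_params(mpp = 8), canvas_mm = c(4, 4),
                    seed = 77)
  obs <- simulate_observers(r$slide, ihc_config(), seed = 3)
  expect_equal(nrow(obs), 2L)
  expect_true(all(obs$whole_slide_area_fraction > 0))
  io <- interobserver_variability(obs$whole_slide_area_fraction[1],
                                  obs$whole_slide_area_fraction[2])
  expect_true(is.finite(io$per_slide_variability))
})
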