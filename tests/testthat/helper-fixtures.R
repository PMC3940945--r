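# Shared fixtures. Heavy synthetic cohorts are built lazily once per test run
# and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small square slide (no tissue ellipse) built directly from a mask: handy for
# metric unit tests.
toy_mask <- function(nr = 64L, nc = 64L, fill = FALSE) {
  matrix(fill, nr, nc)
}

# Paint disks (mm coordinates) onto a logical raster; independent-enough
# helper for building structured masks without the renderer.
paint_disks <- function(mask, centers, radius_mm, mpp) {
  s <- mpp / 1000
  nr <- nrow(mask); nc <- ncol(mask)
  rpx <- ceiling(radius_mm / s) + 1L
  for (i in seq_len(nrow(centers))) {
    c0 <- round(centers[i, 1L] / s); r0 <- round(centers[i, 2L] / s)
    rows <- max(1L, r0 - rpx):min(nr, r0 + rpx)
    cols <- max(1L, c0 - rpx):min(nc, c0 + rpx)
    if (!length(rows) || !length(cols)) next
    dx2 <- outer(rep(1, length(rows)), ((cols - 0.5) * s - centers[i, 1L])^2)
    dy2 <- outer(((rows - 0.5) * s - centers[i, 2L])^2, rep(1, length(cols)))
    mask[rows, cols] <- mask[rows, cols] | (dx2 + dy2 <= radius_mm^2)
  }
  mask
}

# Random blobby binary mask for oracle-equivalence sweeps.
random_mask <- function(nr, nc, seed, p_seed = 0.01, grow = 2L) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc) < p_seed, nr, nc)
  if (grow > 0L) {
    brush <- EBImage::makeBrush(2L * grow + 1L, "disc")
    m <- EBImage::dilate(matrix(as.numeric(m), nr, nc), brush) > 0.5
  }
  m
}

# 20-slide ground-truth-recovery cohort at the full working resolution
# (8 x 8 mm at 4 um/px): 10 vessel-marker and 10 cell-marker slides, rendered
# and quantified once.
crit_recovery_cohort <- function() {
  fixture("recovery_cohort", function() {
    cfg <- ihc_config()
    out <- list()
    for (marker in c("cd31", "foxp3")) {
      plan <- cohort_plan(10, marker_spec = default_marker_spec()[marker],
                          master_seed = 42L, mpp = 4)
      for (i in seq_len(nrow(plan))) {
        sl <- render_cohort_slide(plan, i)
        q <- quantify_slide(sl$slide, cfg, marker_kind = plan$object_kind[i],
                            truth = sl$truth, marker = plan$marker[i])
        out[[plan$slide_id[i]]] <- list(
          record = as.data.frame(q),
          true_area_fraction = sl$truth$true_area_fraction,
          truth_cells = sl$truth$cell_centroids[[marker]],
          detected_cells = q$cell_centroids,
          pattern_kind = sl$truth$pattern_kind)
      }
    }
    out
  })
}

# Criterion-scale correlation cohorts at 8 um/px (sizes chosen to keep a
# full test run desk-scale; the contrast is a cohort-level property, not a
# resolution-level one).
crit_correlation_cohorts <- function() {
  fixture("correlation_cohorts", function() {
    spec_v <- default_marker_spec()["cd31"]
    spec_f <- default_marker_spec()["foxp3"]
    list(
      homogeneous = quantify_cohort(cohort_plan(
        20, heterogeneous_fraction = 0, marker_spec = spec_v,
        master_seed = 7L, mpp = 8)),
      clustered = quantify_cohort(cohort_plan(
        20, heterogeneous_fraction = 1, marker_spec = spec_v,
        master_seed = 7L, mpp = 8)),
      mixture_vessel = quantify_cohort(cohort_plan(
        20, marker_spec = spec_v, master_seed = 7L, mpp = 8)),
      mixture_cell = quantify_cohort(cohort_plan(
        20, marker_spec = spec_f, master_seed = 7L, mpp = 8)))
  })
}
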