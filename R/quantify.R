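# Per-slide quantification: deconvolution, per-slide threshold, mask, whole
# slide vs hot-spot metrics - one record per slide.

#' Quantify a slide end to end
#'
#' Runs the full pipeline on one slide: color deconvolution, per-slide Otsu
#' threshold (with OD floor), immunoreactive mask, whole-slide area fraction,
#' hot-spot selection, and the marker-appropriate metrics (micro-vessel
#' density and Chalkley count per hot spot for vessel markers; cell densities
#' in cells per 0.1 mm^2 for discrete cell markers).
#'
#' @param slide a `slide_image`.
#' @param config an [ihc_config()].
#' @param marker_kind "vessel" or "cell".
#' @param truth optional `ground_truth` (copies `pattern_kind` and
#'   `true_area_fraction` onto the record).
#' @param threshold optional fixed threshold overriding the per-slide
#'   estimate.
#' @param marker marker label stored on the record.
#' @return Object of class `slide_quantification` (a list; see fields in the
#'   source), convertible with [as.data.frame()].
#' @export
quantify_slide <- function(slide, config = ihc_config(),
                           marker_kind = c("vessel", "cell"), truth = NULL,
                           threshold = NULL, marker = NA_character_) {
  stopifnot(inherits(slide, "slide_image"), inherits(config, "ihc_config"))
  marker_kind <- match.arg(marker_kind)
  evaluable <- slide$tissue_mask
  s <- slide$mpp / 1000
  evaluable_area_mm2 <- sum(evaluable) * s^2

  maps <- deconvolve_stains(slide, config$vectors)
  thr <- if (is.null(threshold))
    estimate_threshold(maps$chromogen, evaluable, config$od_floor)
  else threshold
  mask <- immunoreactive_mask(maps$chromogen, evaluable, thr,
                              config$min_object_px, mpp = slide$mpp)

  ws_af <- area_fraction(mask, roi_whole_slide(), evaluable)
  hs <- select_hotspots(mask, evaluable, k = config$hotspot_k,
                        hotspot_area_mm2 = config$hotspot_area_mm2,
                        mpp = slide$mpp)
  ev <- hotspot_evidence(hs, ws_af, config$ratio_threshold)

  rec <- list(slide_id = slide$slide_id, marker = marker,
              marker_kind = marker_kind,
              evaluable_area_mm2 = evaluable_area_mm2,
              excluded = evaluable_area_mm2 < config$min_area_mm2,
              threshold = thr,
              whole_slide_area_fraction = ws_af,
              hotspot_area_fractions = hs$area_fraction,
              hotspot_mean_area_fraction = mean(hs$area_fraction),
              hotspots = hs,
              evidence_ratio = ev$evidence_ratio, evident = ev$evident,
              mvd = NULL, mvd_per_mm2 = NULL, chalkley = NULL,
              whole_slide_cell_density = NA_real_,
              hotspot_cell_densities = NULL,
              hotspot_mean_cell_density = NA_real_,
              pattern_kind = if (!is.null(truth)) truth$pattern_kind else NA_character_,
              true_area_fraction = if (!is.null(truth)) truth$true_area_fraction else NA_real_)

  if (marker_kind == "vessel") {
    grat <- chalkley_graticule()
    mvd <- integer(hs$k); mvdmm <- numeric(hs$k); ck <- integer(hs$k)
    for (j in seq_len(hs$k)) {
      v <- microvessel_density(mask, hs$hotspots[[j]], evaluable,
                               merge_gap_um = config$merge_gap_um)
      mvd[j] <- v$count; mvdmm[j] <- v$per_mm2
      ck[j] <- chalkley_count(mask, hs$hotspots[[j]], grat,
                              n_rotations = config$chalkley_rotations,
                              n_offsets = config$chalkley_offsets,
                              jitter_frac = config$chalkley_jitter_frac)
    }
    rec$mvd <- mvd; rec$mvd_per_mm2 <- mvdmm; rec$chalkley <- ck
  } else {
    cells <- detect_cells(maps$chromogen, evaluable, config$cell_params,
                          mpp = slide$mpp)
    rec$cell_centroids <- cells
    rec$whole_slide_cell_density <-
      cell_density(cells, roi_whole_slide(), evaluable, slide$mpp)$density
    hd <- vapply(hs$hotspots, function(h)
      cell_density(cells, h, evaluable, slide$mpp)$density, numeric(1L))
    rec$hotspot_cell_densities <- hd
    rec$hotspot_mean_cell_density <- mean(hd)
  }
  structure(rec, class = "slide_quantification")
}

#' @export
print.slide_quantification <- function(x, ...) {
  cat(sprintf("<slide_quantification> %s (%s marker)%s\n", x$slide_id,
              x$marker_kind, if (isTRUE(x$excluded)) " [EXCLUDED]" else ""))
  cat(sprintf("  evaluable %.1f mm^2, threshold %.3f OD\n",
              x$evaluable_area_mm2, x$threshold))
  cat(sprintf("  area fraction: whole slide %.3f%%, hot spots %.3f%% (ratio %.2f%s)\n",
              x$whole_slide_area_fraction, x$hotspot_mean_area_fraction,
              x$evidence_ratio,
              if (isTRUE(x$evident)) ", evident hot spots" else ""))
  if (x$marker_kind == "vessel")
    cat(sprintf("  MVD per hot spot: %s; Chalkley: %s\n",
                paste(x$mvd, collapse = ", "), paste(x$chalkley, collapse = ", ")))
  else
    cat(sprintf("  cell density (cells/0.1 mm^2): whole slide %.3f, hot spots %.3f\n",
                x$whole_slide_cell_density, x$hotspot_mean_cell_density))
  invisible(x)
}

#' @export
as.data.frame.slide_quantification <- function(x, ...) {
  data.frame(slide_id = x$slide_id, marker = x$marker,
             marker_kind = x$marker_kind,
             evaluable_area_mm2 = x$evaluable_area_mm2,
             excluded = x$excluded, threshold = x$threshold,
             whole_slide_area_fraction = x$whole_slide_area_fraction,
             hotspot_mean_area_fraction = x$hotspot_mean_area_fraction,
             evidence_ratio = x$evidence_ratio, evident = x$evident,
             whole_slide_cell_density = x$whole_slide_cell_density,
             hotspot_mean_cell_density = x$hotspot_mean_cell_density,
             pattern_kind = x$pattern_kind,
             true_area_fraction = x$true_area_fraction,
             hotspot_area_fractions = I(list(x$hotspot_area_fractions)),
             mvd = I(list(x$mvd)), mvd_per_mm2 = I(list(x$mvd_per_mm2)),
             chalkley = I(list(x$chalkley)),
             hotspot_cell_densities = I(list(x$hotspot_cell_densities)),
             stringsAsFactors = FALSE)
}

#' Render and quantify every slide of a cohort plan
#'
#' Renders one slide at a time (memory stays bounded) and collects the
#' per-slide quantification records.
#'
#' @param plan a [cohort_plan()].
#' @param config an [ihc_config()].
#' @param stain optional [stain_model_params()] override.
#' @return data.frame of per-slide records (one row per subject x marker),
#'   with per-hot-spot metrics as list columns.
#' @export
quantify_cohort <- function(plan, config = ihc_config(), stain = NULL) {
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    sl <- render_cohort_slide(plan, i, stain = stain)
    q <- quantify_slide(sl$slide, config,
                        marker_kind = plan$object_kind[i], truth = sl$truth,
                        marker = plan$marker[i])
    as.data.frame(q)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate two independent observers on one slide
#'
#' The original measurements were made by two humans; here an "observer" is a
#' pipeline run with a jittered threshold (multiplicative) and hot-spot
#' centres displaced by a small random offset, emulating subjective hot-spot
#' placement and threshold tuning.
#'
#' @param slide a `slide_image`.
#' @param config an [ihc_config()].
#' @param marker_kind "vessel" or "cell".
#' @param seed integer seed.
#' @param threshold_jitter multiplicative sd of the per-observer threshold.
#' @param center_jitter_um maximal hot-spot centre displacement, microns.
#' @return data.frame with one row per observer: `whole_slide_area_fraction`,
#'   `hotspot_mean_area_fraction`.
#' @export
simulate_observers <- function(slide, config = ihc_config(),
                               marker_kind = "vessel", seed = 1L,
                               threshold_jitter = 0.05,
                               center_jitter_um = 150) {
  maps <- deconvolve_stains(slide, config$vectors)
  evaluable <- slide$tissue_mask
  thr0 <- estimate_threshold(maps$chromogen, evaluable, config$od_floor)
  one <- function(obs) {
    with_seed(derive_seed(seed, obs), {
      thr <- thr0 * exp(stats::rnorm(1L, 0, threshold_jitter))
      mask <- immunoreactive_mask(maps$chromogen, evaluable, thr,
                                  config$min_object_px, mpp = slide$mpp)
      ws <- area_fraction(mask, roi_whole_slide(), evaluable)
      hs <- select_hotspots(mask, evaluable, k = config$hotspot_k,
                            hotspot_area_mm2 = config$hotspot_area_mm2,
                            mpp = slide$mpp)
      af <- vapply(hs$hotspots, function(h) {
        ang <- stats::runif(1L, 0, 2 * pi)
        rad <- stats::runif(1L, 0, center_jitter_um / 1000)
        hj <- roi_circle(h$center + rad * c(cos(ang), sin(ang)),
                         h$area_mm2, label = h$label)
        area_fraction(mask, hj, evaluable)
      }, numeric(1L))
      data.frame(observer = obs, whole_slide_area_fraction = ws,
                 hotspot_mean_area_fraction = mean(af))
    })
  }
  rbind(one(1L), one(2L))
}
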