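# Synthetic cohort generation: a mixture of homogeneous and hot-spot
# (clustered) slides per marker, with per-subject abundance variation so
# slides span a realistic dynamic range rather than all sharing one expected
# value.

#' Default marker specification for synthetic cohorts
#'
#' Three markers mirroring a vascular marker (CD31-like: elongated vessel
#' rings, clustered in 85% of subjects), a regulatory T-cell marker
#' (FOXP3-like: sparse nuclear-sized disks, homogeneous in 70%), and a
#' cytotoxic T-cell marker (CD8-like: denser disks, homogeneous in 80%).
#' Base intensities are calibrated so the expected whole-slide values sit at
#' the cohort medians typical for osteosarcoma sections (about 6.5%
#' immunoreactive area for the vessel marker; about 0.73 cells/0.1 mm^2 for
#' the FOXP3-like marker).
#'
#' @return Named list; each element has `object_kind`, `base_intensity`
#'   (objects per mm^2), `heterogeneous_fraction`, `cluster_sigma`,
#'   `offspring_per_parent`, and object-geometry fields.
#' @export
default_marker_spec <- function() {
  list(
    cd31 = list(object_kind = "vessel", base_intensity = 86,
                heterogeneous_fraction = 0.85,
                offspring_per_parent = 68, cluster_sigma = 0.25),
    foxp3 = list(object_kind = "cell", base_intensity = 7.3,
                 heterogeneous_fraction = 0.30,
                 offspring_per_parent = 15, cluster_sigma = 0.5,
                 cluster_strength_cv = 0.3),
    cd8 = list(object_kind = "cell", base_intensity = 30,
               heterogeneous_fraction = 0.20,
               offspring_per_parent = 30, cluster_sigma = 0.5,
               cluster_strength_cv = 0.3)
  )
}

#' Plan a synthetic cohort
#'
#' Fixes, per subject and marker, the spatial pattern kind, the per-subject
#' abundance multiplier and the render seed, all derived deterministically
#' from one master seed, so any slide can be regenerated in isolation.
#' Exactly `round(n_slides * heterogeneous_fraction)` subjects carry the
#' clustered pattern for each marker.
#'
#' @param n_slides subjects in the cohort.
#' @param heterogeneous_fraction override of the clustered fraction for the
#'   vessel marker(s); NULL keeps each marker's own default.
#' @param marker_spec see [default_marker_spec()].
#' @param master_seed integer master seed.
#' @param mpp microns per pixel of rendered slides.
#' @param canvas_mm canvas size, mm.
#' @param slide_intensity_range per-subject abundance multipliers are drawn
#'   uniformly from this range (per marker), giving the cohort its
#'   between-slide dynamic range.
#' @return data.frame (one row per subject x marker) with attributes
#'   `marker_spec`, `mpp`, `canvas_mm`, `master_seed`.
#' @export
cohort_plan <- function(n_slides, heterogeneous_fraction = NULL,
                        marker_spec = default_marker_spec(),
                        master_seed = 1L, mpp = 4, canvas_mm = c(8, 8),
                        slide_intensity_range = c(0.2, 1.9)) {
  stopifnot(n_slides >= 1)
  rows <- list()
  for (mi in seq_along(marker_spec)) {
    marker <- names(marker_spec)[mi]
    ms <- marker_spec[[mi]]
    frac <- ms$heterogeneous_fraction
    if (!is.null(heterogeneous_fraction) && ms$object_kind == "vessel")
      frac <- heterogeneous_fraction
    if (frac < 0 || frac > 1)
      stop("heterogeneous_fraction must lie in [0, 1]")
    n_clustered <- round(n_slides * frac)
    clustered_subjects <- with_seed(
      derive_seed(master_seed, 9000L + mi),
      sample.int(n_slides, n_clustered))
    mult <- with_seed(
      derive_seed(master_seed, 8000L + mi),
      stats::runif(n_slides, slide_intensity_range[1L], slide_intensity_range[2L]))
    rows[[mi]] <- data.frame(
      subject = seq_len(n_slides),
      marker = marker,
      object_kind = ms$object_kind,
      pattern_kind = ifelse(seq_len(n_slides) %in% clustered_subjects,
                            "clustered", "homogeneous"),
      multiplier = mult,
      seed = vapply(seq_len(n_slides), function(i)
        derive_seed(master_seed, i * 100L + mi), integer(1L)),
      slide_id = sprintf("S%03d_%s", seq_len(n_slides), marker),
      stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  attr(plan, "marker_spec") <- marker_spec
  attr(plan, "mpp") <- mpp
  attr(plan, "canvas_mm") <- canvas_mm
  attr(plan, "master_seed") <- master_seed
  plan
}

# Spatial pattern parameters for one plan row.
pattern_from_plan <- function(plan, i) {
  ms <- attr(plan, "marker_spec")[[plan$marker[i]]]
  mult <- plan$multiplier[i]
  base_args <- list(pattern_kind = plan$pattern_kind[i],
                    object_kind = ms$object_kind,
                    intensity = ms$base_intensity * mult,
                    parent_intensity = ms$base_intensity * mult /
                      ms$offspring_per_parent,
                    offspring_per_parent = ms$offspring_per_parent,
                    cluster_sigma = ms$cluster_sigma)
  for (f in intersect(names(ms), c("vessel_radius_range",
                                   "vessel_elongation_range", "cell_radius",
                                   "wall_frac", "gap_prob", "gap_frac_range",
                                   "cluster_strength_cv", "hard_core_factor")))
    base_args[[f]] <- ms[[f]]
  do.call(spatial_pattern_params, base_args)
}

#' Render one slide of a cohort plan
#'
#' @param plan a [cohort_plan()] data.frame.
#' @param i row index into the plan.
#' @param stain optional [stain_model_params()]; the plan's mpp is imposed.
#' @return list(slide, truth) as from [render_slide()].
#' @export
render_cohort_slide <- function(plan, i, stain = NULL) {
  if (is.null(stain)) stain <- stain_model_params(mpp = attr(plan, "mpp"))
  else stain$mpp <- attr(plan, "mpp")
  pat <- pattern_from_plan(plan, i)
  if (plan$object_kind[i] == "vessel") {
    render_slide(vessel_pattern = pat, cell_patterns = list(), stain = stain,
                 canvas_mm = attr(plan, "canvas_mm"), seed = plan$seed[i],
                 slide_id = plan$slide_id[i])
  } else {
    cp <- list(pat); names(cp) <- plan$marker[i]
    render_slide(vessel_pattern = NULL, cell_patterns = cp, stain = stain,
                 canvas_mm = attr(plan, "canvas_mm"), seed = plan$seed[i],
                 slide_id = plan$slide_id[i])
  }
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper rendering every slide of a [cohort_plan()]. For large
#' cohorts prefer planning and rendering slide by slide (see
#' [render_cohort_slide()]) to keep memory bounded.
#'
#' @inheritParams cohort_plan
#' @param ... passed to [cohort_plan()].
#' @return list of list(slide, truth), with the plan as attribute `plan`.
#' @export
generate_cohort <- function(n_slides, heterogeneous_fraction = NULL,
                            marker_spec = default_marker_spec(),
                            master_seed = 1L, ...) {
  plan <- cohort_plan(n_slides, heterogeneous_fraction, marker_spec,
                      master_seed, ...)
  out <- lapply(seq_len(nrow(plan)), function(i) render_cohort_slide(plan, i))
  names(out) <- plan$slide_id
  attr(out, "plan") <- plan
  out
}
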