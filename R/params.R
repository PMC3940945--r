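# Parameter objects for the synthetic slide generator and the quantification
# pipeline. All physical quantities carry explicit units: intensities are
# objects per mm^2, lengths are mm unless the name says otherwise (mpp is
# microns per pixel, blob areas are um^2).

#' Spatial pattern parameters for a marker
#'
#' Describes how immunoreactive objects (vessel cross-sections or discrete
#' cells) are laid out in tissue: either a homogeneous Poisson process
#' ("scattered" markers) or a Thomas-type parent-offspring cluster process
#' ("hot-spot" markers), the standard dichotomy for these two morphologies.
#'
#' @param pattern_kind "homogeneous" or "clustered".
#' @param intensity expected objects per mm^2 (homogeneous mode; for the
#'   clustered mode it is implied by `parent_intensity * offspring_per_parent`).
#' @param parent_intensity cluster centres per mm^2 (clustered only).
#' @param offspring_per_parent mean objects per cluster (clustered only).
#' @param cluster_sigma isotropic Gaussian dispersion of offspring around the
#'   parent, mm (clustered only).
#' @param object_kind "vessel" (elongated annular cross-sections) or "cell"
#'   (disks).
#' @param vessel_radius_range outer-radius range of vessel cross-sections, mm.
#' @param vessel_elongation_range axis-ratio range of the elliptical
#'   cross-section (1 = circular).
#' @param cell_radius disk radius for cells, mm.
#' @param wall_frac vessel wall thickness as a fraction of the outer radius;
#'   the lumen is unstained.
#' @param gap_prob probability that a vessel ring carries an arc gap,
#'   emulating interruptions of the endothelial lining by tissue tears or
#'   focally absent staining.
#' @param gap_frac_range arc-gap length range as a fraction of the
#'   circumference.
#' @param cluster_strength_cv coefficient of variation of per-cluster
#'   strength: each parent's offspring mean is `offspring_per_parent` times a
#'   unit-mean lognormal draw, so individual hot spots vary in intensity
#'   independently of the slide's overall abundance (0 disables).
#' @param hard_core_factor vessels are thinned so that no two centres lie
#'   closer than this factor times the sum of their outer radii (vessel
#'   cross-sections are disjoint structures); 0 disables thinning.
#' @return An object of class `spatial_pattern_params`.
#' @export
spatial_pattern_params <- function(pattern_kind = c("homogeneous", "clustered"),
                                   intensity = 10,
                                   parent_intensity = 0.5,
                                   offspring_per_parent = 20,
                                   cluster_sigma = 0.25,
                                   object_kind = c("vessel", "cell"),
                                   vessel_radius_range = c(0.015, 0.045),
                                   vessel_elongation_range = c(1, 1.8),
                                   cell_radius = 0.009,
                                   wall_frac = 0.4,
                                   gap_prob = 0.3,
                                   gap_frac_range = c(0.1, 0.25),
                                   cluster_strength_cv = 0.8,
                                   hard_core_factor = 1.4) {
  pattern_kind <- match.arg(pattern_kind)
  object_kind <- match.arg(object_kind)
  stopifnot(intensity >= 0, parent_intensity >= 0, offspring_per_parent >= 0)
  if (pattern_kind == "clustered" && cluster_sigma <= 0)
    stop("cluster_sigma must be > 0 for the clustered pattern")
  if (vessel_radius_range[1L] > vessel_radius_range[2L] ||
      any(vessel_radius_range <= 0))
    stop("vessel_radius_range must be positive with min <= max")
  if (cell_radius <= 0) stop("cell_radius must be > 0")
  structure(list(pattern_kind = pattern_kind, intensity = intensity,
                 parent_intensity = parent_intensity,
                 offspring_per_parent = offspring_per_parent,
                 cluster_sigma = cluster_sigma, object_kind = object_kind,
                 vessel_radius_range = vessel_radius_range,
                 vessel_elongation_range = vessel_elongation_range,
                 cell_radius = cell_radius, wall_frac = wall_frac,
                 gap_prob = gap_prob, gap_frac_range = gap_frac_range,
                 cluster_strength_cv = cluster_strength_cv,
                 hard_core_factor = hard_core_factor),
            class = "spatial_pattern_params")
}

#' Stain vectors in optical-density space
#'
#' Unit absorption vectors for the counterstain and the chromogen; the third
#' (residual) vector is completed as their normalized cross product so the
#' 3 x 3 matrix is invertible. Defaults are the published hematoxylin and
#' red-chromogen (AEC) vectors of Ruifrok & Johnston's color-deconvolution
#' calibration.
#'
#' @param counterstain,chromogen length-3 absorption vectors (any positive
#'   scale; normalized internally).
#' @param max_condition reject matrices with 2-norm condition number above
#'   this bound.
#' @return Object of class `stain_vectors`: 3 x 3 matrix with rows
#'   counterstain, chromogen, residual.
#' @export
stain_vectors <- function(counterstain = c(0.650, 0.704, 0.286),
                          chromogen = c(0.2743, 0.6796, 0.6803),
                          max_condition = 100) {
  unit <- function(v) v / sqrt(sum(v^2))
  cs <- unit(as.numeric(counterstain)); ch <- unit(as.numeric(chromogen))
  res <- c(cs[2L] * ch[3L] - cs[3L] * ch[2L],
           cs[3L] * ch[1L] - cs[1L] * ch[3L],
           cs[1L] * ch[2L] - cs[2L] * ch[1L])
  nres <- sqrt(sum(res^2))
  if (nres < 1e-8)
    stop("counterstain and chromogen vectors are linearly dependent")
  m <- rbind(counterstain = cs, chromogen = ch, residual = res / nres)
  kappa <- kappa(m, exact = TRUE)
  if (kappa > max_condition)
    stop(sprintf("stain matrix is near-singular (condition number %.3g > %g)",
                 kappa, max_condition))
  structure(m, class = c("stain_vectors", "matrix"))
}

#' Stain model parameters for the slide renderer
#'
#' @param vectors a [stain_vectors()] object.
#' @param chromogen_od_range per-object chromogen optical density is drawn
#'   uniformly from this range, emulating staining-intensity variation within
#'   and across specimens.
#' @param counterstain_od mean hematoxylin OD of tissue pixels.
#' @param counterstain_od_sd pixelwise Gaussian variation of the counterstain.
#' @param background_rgb mean 8-bit intensity of the three channels on bare
#'   glass.
#' @param noise_sd additive Gaussian RGB scanner noise (8-bit units).
#' @param mpp microns per pixel of the rendered raster.
#' @return Object of class `stain_model_params`.
#' @export
stain_model_params <- function(vectors = stain_vectors(),
                               chromogen_od_range = c(0.6, 1.2),
                               counterstain_od = 0.3,
                               counterstain_od_sd = 0.05,
                               background_rgb = c(252, 250, 253),
                               noise_sd = 1.5,
                               mpp = 4) {
  stopifnot(inherits(vectors, "stain_vectors"), mpp > 0,
            length(chromogen_od_range) == 2L)
  if (chromogen_od_range[1L] <= 0 || chromogen_od_range[2L] > 3 ||
      chromogen_od_range[1L] > chromogen_od_range[2L])
    stop("chromogen_od_range must lie within (0, 3] with min <= max")
  structure(list(vectors = vectors, chromogen_od_range = chromogen_od_range,
                 counterstain_od = counterstain_od,
                 counterstain_od_sd = counterstain_od_sd,
                 background_rgb = background_rgb, noise_sd = noise_sd,
                 mpp = mpp),
            class = "stain_model_params")
}

#' Cell detection parameters
#'
#' @param min_blob_area_um2,max_blob_area_um2 connected-component area bounds
#'   for a blob to count as one cell, um^2.
#' @param min_center_separation_um peaks closer than this count as one cell,
#'   um.
#' @param detection_threshold chromogen OD threshold for cell pixels.
#' @return Object of class `cell_detection_params`.
#' @export
cell_detection_params <- function(min_blob_area_um2 = 100,
                                  max_blob_area_um2 = 2000,
                                  min_center_separation_um = 25,
                                  detection_threshold = 0.3) {
  if (min_blob_area_um2 >= max_blob_area_um2)
    stop("min_blob_area_um2 must be below max_blob_area_um2")
  if (min_center_separation_um <= 0)
    stop("min_center_separation_um must be > 0")
  structure(list(min_blob_area_um2 = min_blob_area_um2,
                 max_blob_area_um2 = max_blob_area_um2,
                 min_center_separation_um = min_center_separation_um,
                 detection_threshold = detection_threshold),
            class = "cell_detection_params")
}

#' Pipeline configuration
#'
#' Gathers every tunable default of the quantification pipeline in one place.
#' Defaults follow standard whole-slide IHC practice: three 0.26 mm^2 circular
#' hot spots, exclusion of sections with under 5 mm^2 evaluable tissue, an
#' interobserver acceptability bound of 10%, and per-slide Otsu thresholding
#' with an OD floor of 0.15.
#'
#' @param vectors stain vectors used for deconvolution.
#' @param od_floor minimum admissible chromogen threshold (OD units).
#' @param min_object_px immunoreactive components smaller than this are
#'   discarded as debris.
#' @param merge_gap_um morphological-closing radius bridging interrupted
#'   vessel walls before micro-vessel counting, microns.
#' @param hotspot_k number of hot spots.
#' @param hotspot_area_mm2 physical hot-spot area, mm^2.
#' @param ratio_threshold hot-spot/whole-slide enrichment ratio above which a
#'   slide is called "evident hot spot".
#' @param chalkley_rotations,chalkley_offsets,chalkley_jitter_frac placement
#'   search grid for the digital Chalkley graticule.
#' @param min_area_mm2 evaluable-area exclusion threshold, mm^2.
#' @param cell_params a [cell_detection_params()] object.
#' @param interobserver_limit_pct acceptability bound on interobserver
#'   variability, percent (strict).
#' @return Object of class `ihc_config`.
#' @export
ihc_config <- function(vectors = stain_vectors(),
                       od_floor = 0.15,
                       min_object_px = 8L,
                       merge_gap_um = 8,
                       hotspot_k = 3L,
                       hotspot_area_mm2 = 0.26,
                       ratio_threshold = 2,
                       chalkley_rotations = 64L,
                       chalkley_offsets = 9L,
                       chalkley_jitter_frac = 0.1,
                       min_area_mm2 = 5,
                       cell_params = cell_detection_params(),
                       interobserver_limit_pct = 10) {
  structure(list(vectors = vectors, od_floor = od_floor,
                 min_object_px = as.integer(min_object_px),
                 merge_gap_um = merge_gap_um,
                 hotspot_k = as.integer(hotspot_k),
                 hotspot_area_mm2 = hotspot_area_mm2,
                 ratio_threshold = ratio_threshold,
                 chalkley_rotations = as.integer(chalkley_rotations),
                 chalkley_offsets = as.integer(chalkley_offsets),
                 chalkley_jitter_frac = chalkley_jitter_frac,
                 min_area_mm2 = min_area_mm2, cell_params = cell_params,
                 interobserver_limit_pct = interobserver_limit_pct),
            class = "ihc_config")
}
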