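# The three vessel quantification estimators compared in whole-slide vs
# hot-spot analysis: immunoreactive-area fraction, micro-vessel density, and
# the digital Chalkley count.

#' Immunoreactive area fraction within a region of interest
#'
#' @param mask an `ihc_mask` (or logical matrix) of immunoreactive pixels.
#' @param roi an `ihc_roi`.
#' @param evaluable logical matrix of evaluable tissue.
#' @param mpp microns per pixel (taken from the mask when available).
#' @return Percentage of evaluable ROI pixels that are immunoreactive.
#' @export
area_fraction <- function(mask, roi = roi_whole_slide(), evaluable,
                          mpp = NULL) {
  m <- as_mask_matrix(mask)
  if (is.null(mpp)) mpp <- if (inherits(mask, "ihc_mask")) mask$mpp else NA_real_
  rp <- roi_pixels(roi, dim(m), mpp)
  denom <- rp & evaluable
  nd <- sum(denom)
  if (nd == 0L)
    stop(sprintf("ROI '%s' contains no evaluable tissue pixels", roi$label))
  100 * sum(m & denom) / nd
}

#' Micro-vessel density: count of singular identifiable vessels in a ROI
#'
#' Interruptions of the endothelial lining (tissue tears, focally absent
#' staining) fragment single vessels; a morphological closing with a disk of
#' radius `merge_gap_um` bridges such gaps before 8-connected components are
#' counted. A vessel belongs to the ROI when its centroid does (so adjacent
#' hot spots never double-count one vessel).
#'
#' @inheritParams area_fraction
#' @param merge_gap_um closing radius, microns (0 disables closing).
#' @return list with `count` (vessels whose centroid lies in the ROI) and
#'   `per_mm2` (count over the evaluable ROI area).
#' @export
microvessel_density <- function(mask, roi = roi_whole_slide(), evaluable,
                                merge_gap_um = 8, mpp = NULL) {
  stopifnot(merge_gap_um >= 0)
  m <- as_mask_matrix(mask)
  if (is.null(mpp)) mpp <- if (inherits(mask, "ihc_mask")) mask$mpp else NA_real_
  r_px <- if (is.na(mpp)) 0L else floor(merge_gap_um / mpp)
  if (merge_gap_um > 0 && r_px >= 1L) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    m <- EBImage::closing(matrix(as.numeric(m), nrow(m), ncol(m)), brush) > 0.5
  }
  lab <- label_components(m)
  st <- component_stats(lab)
  if (!nrow(st)) return(list(count = 0L, per_mm2 = 0))
  rp <- roi_pixels(roi, dim(m), mpp)
  rr <- pmin(pmax(round(st$row), 1L), nrow(m))
  cc <- pmin(pmax(round(st$col), 1L), ncol(m))
  inside <- rp[cbind(rr, cc)]
  count <- sum(inside)
  area_mm2 <- sum(rp & evaluable) * (mpp / 1000)^2
  list(count = as.integer(count),
       per_mm2 = if (is.finite(area_mm2) && area_mm2 > 0) count / area_mm2 else NA_real_)
}

#' The 25-dot Chalkley graticule
#'
#' Physical Chalkley eyepiece graticules carry 25 dots in a circular field;
#' the exact layout varies between instruments. The digital graticule here is
#' 25 points sampled uniformly in the unit disk under a minimum-separation
#' constraint from a fixed layout seed, shipped as a package constant so
#' counts are reproducible across runs and installations.
#'
#' @param layout_seed seed fixing the dot layout.
#' @param n_dots number of dots.
#' @param min_separation minimum pairwise dot distance (unit-disk units).
#' @return Object of class `chalkley_graticule`: list with `dots` (n x 2
#'   matrix in the unit disk), `layout_seed`.
#' @export
chalkley_graticule <- function(layout_seed = 73L, n_dots = 25L,
                               min_separation = 0.18) {
  dots <- with_seed(layout_seed, {
    pts <- matrix(numeric(0), 0L, 2L)
    guard <- 0L
    while (nrow(pts) < n_dots) {
      guard <- guard + 1L
      if (guard > 10000L) stop("cannot place dots at this separation")
      x <- stats::runif(1L, -1, 1); y <- stats::runif(1L, -1, 1)
      if (x * x + y * y > 1) next
      if (nrow(pts) == 0L ||
          min(sqrt((pts[, 1L] - x)^2 + (pts[, 2L] - y)^2)) >= min_separation)
        pts <- rbind(pts, c(x, y))
    }
    pts
  })
  structure(list(dots = dots, layout_seed = layout_seed), class = "chalkley_graticule")
}

# The search grid of graticule placements: rotations x small translations.
chalkley_placements <- function(n_rotations, n_offsets, jitter_mm) {
  angles <- 2 * pi * (seq_len(n_rotations) - 1L) / n_rotations
  if (n_offsets <= 1L) {
    offs <- matrix(0, 1L, 2L)
  } else {
    oa <- 2 * pi * (seq_len(n_offsets - 1L) - 1L) / (n_offsets - 1L)
    offs <- rbind(c(0, 0), cbind(jitter_mm * cos(oa), jitter_mm * sin(oa)))
  }
  list(angles = angles, offsets = offs)
}

#' Digital Chalkley count within a hot spot
#'
#' The graticule is scaled to the hot-spot field and placed at its centre;
#' over a deterministic grid of rotations and small translations the placement
#' maximizing the number of dots landing on immunoreactive pixels is selected
#' (the digital analogue of the pathologist adjusting the eyepiece graticule
#' to maximize dot hits). A dot touches a vessel when its nearest raster
#' pixel is mask-positive.
#'
#' @inheritParams area_fraction
#' @param hotspot circular `ihc_roi`.
#' @param graticule a [chalkley_graticule()].
#' @param n_rotations,n_offsets placement search grid.
#' @param jitter_frac translation radius as a fraction of the field radius.
#' @return Integer count in 0..25.
#' @export
chalkley_count <- function(mask, hotspot, graticule = chalkley_graticule(),
                           n_rotations = 64L, n_offsets = 9L,
                           jitter_frac = 0.1, mpp = NULL) {
  stopifnot(inherits(hotspot, "ihc_roi"), n_rotations >= 1L)
  if (hotspot$shape != "circle")
    stop("Chalkley counting requires a circular hot-spot ROI")
  m <- as_mask_matrix(mask)
  if (is.null(mpp)) mpp <- if (inherits(mask, "ihc_mask")) mask$mpp else NA_real_
  s <- mpp / 1000
  r <- hotspot$radius_mm
  pl <- chalkley_placements(n_rotations, n_offsets, jitter_frac * r)
  dots <- graticule$dots * r
  best <- 0L
  for (a in pl$angles) {
    rot <- cbind(dots[, 1L] * cos(a) - dots[, 2L] * sin(a),
                 dots[, 1L] * sin(a) + dots[, 2L] * cos(a))
    for (o in seq_len(nrow(pl$offsets))) {
      x <- hotspot$center[1L] + rot[, 1L] + pl$offsets[o, 1L]
      y <- hotspot$center[2L] + rot[, 2L] + pl$offsets[o, 2L]
      cc <- pmin(pmax(ceiling(x / s), 1L), ncol(m))
      rr <- pmin(pmax(ceiling(y / s), 1L), nrow(m))
      hits <- sum(m[cbind(rr, cc)])
      if (hits > best) best <- hits
      if (best == nrow(dots)) return(as.integer(best))
    }
  }
  as.integer(best)
}
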