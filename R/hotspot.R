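# Hot-spot selection: the top-k non-overlapping circles of fixed physical
# area maximizing immunoreactive density, plus the "evident hot spot" index.

#' Select the top-k density hot spots
#'
#' The density field is the immunoreactive mask convolved with the circular
#' hot-spot kernel (radius r = sqrt(area/pi)), evaluated on a stride grid of
#' candidate centres restricted to circles lying at least `min_inside` within
#' evaluable tissue. Hot spots are picked greedily in decreasing density with
#' non-overlap enforced by a centre distance of at least 2r; ties break by
#' row-major scan order. Fully deterministic.
#'
#' @param mask an `ihc_mask` or logical matrix.
#' @param evaluable logical matrix of evaluable tissue.
#' @param k number of hot spots.
#' @param hotspot_area_mm2 physical hot-spot area, mm^2.
#' @param mpp microns per pixel.
#' @param stride_frac candidate-grid stride as a fraction of the hot-spot
#'   radius.
#' @param min_inside minimum fraction of the circle that must be evaluable.
#' @return Object of class `hotspot_set`: list with `hotspots` (list of
#'   circular `ihc_roi`s), `density` (mask pixels per circle, non-increasing),
#'   `area_fraction` (percent per hot spot), `k`, `mpp`.
#' @export
select_hotspots <- function(mask, evaluable, k = 3L, hotspot_area_mm2 = 0.26,
                            mpp = NULL, stride_frac = 0.25, min_inside = 0.9) {
  stopifnot(k >= 1L, hotspot_area_mm2 > 0)
  m <- as_mask_matrix(mask)
  if (is.null(mpp)) mpp <- if (inherits(mask, "ihc_mask")) mask$mpp else NA_real_
  s <- mpp / 1000
  r_mm <- sqrt(hotspot_area_mm2 / pi)
  r_px <- r_mm / s
  kr <- ceiling(r_px)
  nr <- nrow(m); nc <- ncol(m)
  if (sum(evaluable) * s^2 < k * hotspot_area_mm2)
    stop(sprintf("evaluable tissue (%.2f mm^2) is too small for %d non-overlapping hot spots of %.2f mm^2",
                 sum(evaluable) * s^2, k, hotspot_area_mm2))

  # circular kernel on pixel centres
  off <- seq(-kr, kr)
  kern <- outer(off, off, function(i, j) as.numeric(i^2 + j^2 <= r_px^2))
  ksum <- sum(kern)
  pad <- function(x) {
    out <- matrix(0, nr + 2L * kr, nc + 2L * kr)
    out[kr + seq_len(nr), kr + seq_len(nc)] <- x
    out
  }
  crop <- function(x) x[kr + seq_len(nr), kr + seq_len(nc)]
  dens_full <- crop(EBImage::filter2(pad(matrix(as.numeric(m), nr, nc)), kern,
                                     boundary = 0))
  eval_full <- crop(EBImage::filter2(pad(matrix(as.numeric(evaluable), nr, nc)),
                                     kern, boundary = 0))

  stride <- max(1L, floor(stride_frac * r_px))
  grows <- seq.int(kr + 1L, nr - kr, by = stride)
  gcols <- seq.int(kr + 1L, nc - kr, by = stride)
  if (!length(grows) || !length(gcols))
    stop("raster too small for the hot-spot radius")
  # row-major candidate order
  cand <- cbind(row = rep(grows, each = length(gcols)),
                col = rep(gcols, times = length(grows)))
  dens <- round(dens_full[cand])
  valid <- eval_full[cand] >= min_inside * ksum
  if (sum(valid) < k)
    stop(sprintf("only %d candidate centres lie %.0f%% inside evaluable tissue; cannot place %d hot spots",
                 sum(valid), 100 * min_inside, k))

  chosen <- integer(0)
  avail <- valid
  min_d2 <- (2 * r_px)^2
  for (j in seq_len(k)) {
    if (!any(avail)) break
    dmax <- max(dens[avail])
    pick <- which(avail & dens == dmax)[1L] # first in scan order
    chosen <- c(chosen, pick)
    d2 <- (cand[, 1L] - cand[pick, 1L])^2 + (cand[, 2L] - cand[pick, 2L])^2
    avail <- avail & d2 >= min_d2
  }
  if (length(chosen) < k)
    stop(sprintf("could not place %d non-overlapping hot spots (placed %d)", k, length(chosen)))

  hotspots <- vector("list", k)
  af <- numeric(k)
  for (j in seq_len(k)) {
    ctr <- c((cand[chosen[j], 2L] - 0.5) * s, (cand[chosen[j], 1L] - 0.5) * s)
    hotspots[[j]] <- roi_circle(ctr, hotspot_area_mm2,
                                label = sprintf("hotspot_%d", j))
    af[j] <- 100 * dens[chosen[j]] / max(eval_full[cand[chosen[j], , drop = FALSE]], 1)
  }
  structure(list(hotspots = hotspots, density = dens[chosen],
                 area_fraction = af, k = k, mpp = mpp,
                 hotspot_area_mm2 = hotspot_area_mm2),
            class = "hotspot_set")
}

#' Evident-hot-spot index
#'
#' Ratio of the mean hot-spot area fraction to the whole-slide area fraction.
#' Density-selected hot spots are always at least as stained as the slide
#' average, so the ratio is >= 1 up to discretization; a slide is called
#' "evident" when the enrichment exceeds `ratio_threshold`. A zero
#' whole-slide fraction leaves the index undefined (flagged, not computed).
#'
#' @param hotspot_set a [select_hotspots()] result.
#' @param whole_slide_fraction whole-slide area fraction, percent.
#' @param ratio_threshold enrichment needed to call a hot spot evident.
#' @return list with `evidence_ratio`, `evident`, and `defined` (FALSE when
#'   the whole-slide fraction is zero).
#' @export
hotspot_evidence <- function(hotspot_set, whole_slide_fraction,
                             ratio_threshold = 2) {
  stopifnot(inherits(hotspot_set, "hotspot_set"))
  if (!is.finite(whole_slide_fraction) || whole_slide_fraction <= 0)
    return(list(evidence_ratio = NA_real_, evident = NA, defined = FALSE))
  ratio <- mean(hotspot_set$area_fraction) / whole_slide_fraction
  list(evidence_ratio = ratio, evident = ratio >= ratio_threshold,
       defined = TRUE)
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> k = %d circles of %.2f mm^2\n", x$k, x$hotspot_area_mm2))
  for (j in seq_len(x$k))
    cat(sprintf("  %d: centre (%.3f, %.3f) mm, density %d px, area fraction %.2f%%\n",
                j, x$hotspots[[j]]$center[1L], x$hotspots[[j]]$center[2L],
                x$density[j], x$area_fraction[j]))
  invisible(x)
}
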