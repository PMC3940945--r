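# Discrete immunoreactive cell detection and density quantification
# (cells per 0.1 mm^2, the conventional reporting unit), with the
# semiquantitative low/intermediate/high categorization.

#' Detect discrete immunoreactive cells
#'
#' Deterministic blob detection standing in for a manual count: threshold the
#' chromogen OD map, label 8-connected components, keep blobs whose area lies
#' within the plausible single-cell range, and merge detections closer than
#' the minimum centre separation (single-linkage; a merged group counts
#' once). Only centroids inside evaluable tissue are returned.
#'
#' @param chromogen_map chromogen OD matrix.
#' @param evaluable logical matrix of evaluable tissue.
#' @param params a [cell_detection_params()] object.
#' @param mpp microns per pixel.
#' @return n x 2 matrix of cell centroids (x, y in mm).
#' @export
detect_cells <- function(chromogen_map, evaluable,
                         params = cell_detection_params(), mpp) {
  stopifnot(inherits(params, "cell_detection_params"),
            identical(dim(chromogen_map), dim(evaluable)))
  s <- mpp / 1000
  bin <- (chromogen_map >= params$detection_threshold) & evaluable
  if (!any(bin)) return(matrix(numeric(0), 0L, 2L))
  lab <- label_components(bin)
  st <- component_stats(lab)
  px_area_um2 <- mpp^2
  st <- st[st$size * px_area_um2 >= params$min_blob_area_um2 &
             st$size * px_area_um2 <= params$max_blob_area_um2, , drop = FALSE]
  if (!nrow(st)) return(matrix(numeric(0), 0L, 2L))
  x <- (st$col - 0.5) * s
  y <- (st$row - 0.5) * s
  sep_mm <- params$min_center_separation_um / 1000
  if (nrow(st) > 1L) {
    grp <- stats::cutree(stats::hclust(stats::dist(cbind(x, y)),
                                       method = "single"), h = sep_mm)
    x <- as.numeric(tapply(x, grp, mean))
    y <- as.numeric(tapply(y, grp, mean))
  }
  cc <- pmin(pmax(ceiling(x / s), 1L), ncol(evaluable))
  rr <- pmin(pmax(ceiling(y / s), 1L), nrow(evaluable))
  keep <- evaluable[cbind(rr, cc)]
  cbind(x[keep], y[keep])
}

#' Cell density in cells per 0.1 mm^2
#'
#' @param centroids n x 2 matrix of cell centroids (mm).
#' @param roi an `ihc_roi`.
#' @param evaluable logical matrix of evaluable tissue.
#' @param mpp microns per pixel.
#' @return list with `count` (cells in the evaluable ROI), `area_mm2`, and
#'   `density` (cells per 0.1 mm^2).
#' @export
cell_density <- function(centroids, roi = roi_whole_slide(), evaluable, mpp) {
  s <- mpp / 1000
  rp <- roi_pixels(roi, dim(evaluable), mpp) & evaluable
  area_mm2 <- sum(rp) * s^2
  if (area_mm2 <= 0)
    stop(sprintf("ROI '%s' has zero evaluable area", roi$label))
  count <- 0L
  if (length(centroids) && nrow(centroids)) {
    cc <- pmin(pmax(ceiling(centroids[, 1L] / s), 1L), ncol(evaluable))
    rr <- pmin(pmax(ceiling(centroids[, 2L] / s), 1L), nrow(evaluable))
    count <- sum(rp[cbind(rr, cc)])
  }
  list(count = as.integer(count), area_mm2 = area_mm2,
       density = count / area_mm2 / 10)
}

#' Semiquantitative frequency categories across a cohort
#'
#' Labels each slide's cell density low / intermediate / high, either by the
#' cohort's tertiles (default) or by fixed cut points. Values equal to a cut
#' point fall in the lower category.
#'
#' @param densities numeric vector of per-slide densities (cells/0.1 mm^2).
#' @param cut_points "tertiles" or a numeric length-2 vector c(low_cut,
#'   high_cut).
#' @return Factor with levels low/intermediate/high; attribute `proportions`
#'   carries the category shares, attribute `cut_points` the cuts used.
#' @export
categorize_frequency <- function(densities, cut_points = "tertiles") {
  if (identical(cut_points, "tertiles")) {
    if (length(densities) < 3L)
      stop("tertile categorization needs at least 3 slides")
    cuts <- unname(stats::quantile(densities, c(1, 2) / 3))
  } else {
    cuts <- as.numeric(cut_points)
    stopifnot(length(cuts) == 2L, cuts[1L] <= cuts[2L])
  }
  lab <- ifelse(densities <= cuts[1L], "low",
                ifelse(densities <= cuts[2L], "intermediate", "high"))
  f <- factor(lab, levels = c("low", "intermediate", "high"))
  attr(f, "proportions") <- prop.table(table(f))
  attr(f, "cut_points") <- cuts
  f
}
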