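# Regions of interest: the whole slide, or a circle of fixed physical area
# (the 0.26 mm^2 hot-spot field).

#' Whole-slide region of interest
#' @return Object of class `ihc_roi`.
#' @export
roi_whole_slide <- function() {
  structure(list(shape = "whole_slide", center = NULL, area_mm2 = NA_real_,
                 label = "whole_slide"), class = "ihc_roi")
}

#' Circular region of interest of fixed physical area
#'
#' @param center c(x, y) in mm.
#' @param area_mm2 circle area, mm^2 (default the standard 0.26 mm^2 hot-spot
#'   field).
#' @param label optional identifier.
#' @return Object of class `ihc_roi` with derived `radius_mm`.
#' @export
roi_circle <- function(center, area_mm2 = 0.26, label = "circle") {
  stopifnot(length(center) == 2L, area_mm2 > 0)
  structure(list(shape = "circle", center = as.numeric(center),
                 area_mm2 = area_mm2, radius_mm = sqrt(area_mm2 / pi),
                 label = label), class = "ihc_roi")
}

#' Pixel membership of a region of interest
#'
#' @param roi an `ihc_roi`.
#' @param dim c(nr, nc) raster dimensions.
#' @param mpp microns per pixel.
#' @return Logical matrix: pixels whose centres fall in the ROI.
#' @export
roi_pixels <- function(roi, dim, mpp) {
  stopifnot(inherits(roi, "ihc_roi"))
  if (roi$shape == "whole_slide") return(matrix(TRUE, dim[1L], dim[2L]))
  s <- mpp / 1000
  x <- (seq_len(dim[2L]) - 0.5) * s
  y <- (seq_len(dim[1L]) - 0.5) * s
  dx2 <- outer(rep(1, dim[1L]), (x - roi$center[1L])^2)
  dy2 <- outer((y - roi$center[2L])^2, rep(1, dim[2L]))
  (dx2 + dy2) <= roi$radius_mm^2
}

#' @export
print.ihc_roi <- function(x, ...) {
  if (x$shape == "whole_slide") cat("<ihc_roi> whole slide\n")
  else cat(sprintf("<ihc_roi> circle '%s' at (%.3f, %.3f) mm, %.3f mm^2 (r = %.3f mm)\n",
                   x$label, x$center[1L], x$center[2L], x$area_mm2, x$radius_mm))
  invisible(x)
}
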