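# Polygon utilities shared by the slide generator and the quantification side.
#
# Conventions: physical coordinates are millimetres; a raster of dimension
# (nr, nc) at `mpp` microns per pixel has pixel (r, c) centred at
# x = (c - 0.5) * mpp/1000, y = (r - 0.5) * mpp/1000. A polygon is a list of
# rings (each an n x 2 matrix of x, y vertices, not closed); interior is
# defined by the even-odd rule, so an annulus is simply its two boundary
# circles.

#' Signed area of a polygon ring (shoelace formula)
#'
#' @param ring n x 2 matrix of x, y vertices in mm, not closed.
#' @return Signed area in mm^2 (positive for counter-clockwise vertex order).
#' @keywords internal
ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Absolute area of a single-ring polygon
#' @inheritParams ring_signed_area
#' @return Area in mm^2.
#' @keywords internal
polygon_area <- function(ring) abs(ring_signed_area(ring))

#' Even-odd point-in-polygon test
#'
#' Counts edge crossings strictly to the right of each query point over all
#' rings; odd parity means inside.
#'
#' @param px,py numeric vectors of query coordinates (mm).
#' @param rings list of ring matrices.
#' @return Logical vector.
#' @keywords internal
point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[, 1L]; y1 <- ring[, 2L]
    x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
    for (e in seq_len(n)) {
      if (y1[e] == y2[e]) next
      crosses <- (y1[e] <= py) != (y2[e] <= py)
      if (any(crosses)) {
        xc <- x1[e] + (py[crosses] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
        flip <- px[crosses] < xc
        idx <- which(crosses)[flip]
        inside[idx] <- !inside[idx]
      }
    }
  }
  inside
}

#' Rasterize an even-odd polygon onto a pixel grid by scanline filling
#'
#' @param rings list of ring matrices (mm).
#' @param dim c(nr, nc) raster dimensions.
#' @param mpp microns per pixel.
#' @param origin c(x0, y0) mm of the raster's top-left corner (default 0, 0);
#'   lets callers rasterize into a bounding-box window.
#' @return Logical matrix of pixels whose centres fall inside.
#' @keywords internal
rasterize_rings <- function(rings, dim, mpp, origin = c(0, 0)) {
  nr <- dim[1L]; nc <- dim[2L]
  s <- mpp / 1000
  out <- matrix(FALSE, nr, nc)
  xc <- origin[1L] + (seq_len(nc) - 0.5) * s
  # edge table over all rings
  x1 <- numeric(0); y1 <- numeric(0); x2 <- numeric(0); y2 <- numeric(0)
  for (ring in rings) {
    rx <- ring[, 1L]; ry <- ring[, 2L]
    x1 <- c(x1, rx); y1 <- c(y1, ry)
    x2 <- c(x2, c(rx[-1L], rx[1L])); y2 <- c(y2, c(ry[-1L], ry[1L]))
  }
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) return(out)
  ymin <- min(y1, y2); ymax <- max(y1, y2)
  r_lo <- max(1L, ceiling((ymin - origin[2L]) / s + 0.5))
  r_hi <- min(nr, floor((ymax - origin[2L]) / s + 0.5) + 1L)
  slope <- (x2 - x1) / (y2 - y1)
  for (r in seq.int(r_lo, length.out = max(0L, r_hi - r_lo + 1L))) {
    yc <- origin[2L] + (r - 0.5) * s
    hit <- (y1 <= yc) != (y2 <= yc)
    if (!any(hit)) next
    xs <- sort(x1[hit] + (yc - y1[hit]) * slope[hit])
    k <- findInterval(xc, xs)
    out[r, ] <- ((length(xs) - k) %% 2L) == 1L
  }
  out
}

#' Vertices of an (optionally partial) ellipse
#'
#' @param cx,cy centre (mm); @param a,b semi-axes (mm); @param theta rotation
#'   (radians); @param arc length-2 angular range (radians); @param n vertices.
#' @return n x 2 matrix.
#' @keywords internal
ellipse_ring <- function(cx, cy, a, b, theta = 0, arc = c(0, 2 * pi), n = 48L) {
  full <- abs(diff(arc) - 2 * pi) < 1e-9
  t <- seq(arc[1L], arc[2L], length.out = if (full) n + 1L else n)
  if (full) t <- t[-length(t)]
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(cx + ex * cos(theta) - ey * sin(theta),
        cy + ex * sin(theta) + ey * cos(theta))
}

#' Annulus (vessel cross-section) rings, optionally with an arc gap
#'
#' A full annulus is encoded as outer + inner rings (even-odd); a gapped one
#' as a single C-shaped ring (outer arc forward, inner arc backward).
#'
#' @param cx,cy centre (mm); @param a,b outer semi-axes; @param wall_frac wall
#'   thickness as a fraction of the outer radius; @param theta orientation;
#'   @param gap_arc NULL or c(start, end) radians of the missing arc.
#' @return list of ring matrices.
#' @keywords internal
annulus_rings <- function(cx, cy, a, b, wall_frac = 0.4, theta = 0,
                          gap_arc = NULL, n = 48L) {
  ai <- a * (1 - wall_frac); bi <- b * (1 - wall_frac)
  if (is.null(gap_arc)) {
    list(ellipse_ring(cx, cy, a, b, theta, n = n),
         ellipse_ring(cx, cy, ai, bi, theta, n = n))
  } else {
    span <- c(gap_arc[2L], gap_arc[1L] + 2 * pi) # the kept arc
    outer <- ellipse_ring(cx, cy, a, b, theta, arc = span, n = n)
    inner <- ellipse_ring(cx, cy, ai, bi, theta, arc = rev(span), n = n)
    list(rbind(outer, inner))
  }
}

#' Regular polygon approximating a disk (cell profile)
#' @keywords internal
disk_ring <- function(cx, cy, r, n = 16L) ellipse_ring(cx, cy, r, r, n = n)

#' Bounding box of a list of rings
#' @return c(xmin, ymin, xmax, ymax) in mm.
#' @keywords internal
rings_bbox <- function(rings) {
  m <- do.call(rbind, rings)
  c(min(m[, 1L]), min(m[, 2L]), max(m[, 1L]), max(m[, 2L]))
}
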