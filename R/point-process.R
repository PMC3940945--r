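# Spatial point processes driving the synthetic slide generator.

#' Sample a spatial point pattern inside a polygonal region
#'
#' Homogeneous mode: a Poisson process with the stated intensity restricted to
#' the region (count ~ Poisson(intensity x area), locations uniform).
#' Clustered mode: a Thomas-type parent-offspring process - parents form a
#' Poisson process on the region's bounding box buffered by five cluster
#' standard deviations (so clusters straddling the boundary contribute
#' without edge bias), each parent receives a Poisson number of offspring
#' (mean `offspring_per_parent`, scaled per parent by a unit-mean lognormal
#' strength when `cluster_strength_cv > 0`, so individual clusters vary in
#' intensity independently of overall abundance) displaced by an isotropic
#' Gaussian with sd `cluster_sigma`; offspring outside the region are
#' discarded. The expected total count is unchanged by strength variation.
#'
#' @param params a [spatial_pattern_params()] object.
#' @param region single polygon ring (n x 2 matrix, mm) with positive area.
#' @param seed integer seed; identical seeds give identical patterns.
#' @return n x 2 matrix of object centres (x, y in mm); for the clustered
#'   mode, attribute `parents` carries the parent locations.
#' @export
#' @examples
#' sq <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
#' p <- spatial_pattern_params("homogeneous", intensity = 5, object_kind = "cell")
#' nrow(sample_point_pattern(p, sq, seed = 1))
sample_point_pattern <- function(params, region, seed) {
  stopifnot(inherits(params, "spatial_pattern_params"))
  region <- as.matrix(region)
  area <- polygon_area(region)
  if (!is.finite(area) || area <= 0)
    stop(sprintf("region has non-positive area (%.4g mm^2); a valid sampling region is required", area))
  bb <- rings_bbox(list(region))
  with_seed(seed, {
    if (params$pattern_kind == "homogeneous") {
      n <- stats::rpois(1L, params$intensity * area)
      pts <- runif_in_polygon(n, region, bb)
      attr(pts, "parents") <- NULL
      pts
    } else {
      buf <- 5 * params$cluster_sigma
      bx <- c(bb[1L] - buf, bb[3L] + buf)
      by <- c(bb[2L] - buf, bb[4L] + buf)
      a_buf <- diff(bx) * diff(by)
      n_par <- stats::rpois(1L, params$parent_intensity * a_buf)
      px <- stats::runif(n_par, bx[1L], bx[2L])
      py <- stats::runif(n_par, by[1L], by[2L])
      mu <- rep(params$offspring_per_parent, n_par)
      cv <- params$cluster_strength_cv
      if (!is.null(cv) && cv > 0 && n_par > 0L) {
        sdlog <- sqrt(log(1 + cv^2))
        mu <- mu * stats::rlnorm(n_par, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      n_off <- stats::rpois(n_par, mu)
      tot <- sum(n_off)
      if (tot == 0L) {
        pts <- matrix(numeric(0), 0L, 2L)
      } else {
        ox <- rep(px, n_off) + stats::rnorm(tot, 0, params$cluster_sigma)
        oy <- rep(py, n_off) + stats::rnorm(tot, 0, params$cluster_sigma)
        keep <- point_in_rings(ox, oy, list(region))
        pts <- cbind(ox[keep], oy[keep])
      }
      attr(pts, "parents") <- cbind(px, py)
      pts
    }
  })
}

# Uniform points in a polygon by rejection from its bounding box.
runif_in_polygon <- function(n, region, bb = rings_bbox(list(region))) {
  out <- matrix(numeric(0), 0L, 2L)
  if (n == 0L) return(out)
  frac <- polygon_area(region) / ((bb[3L] - bb[1L]) * (bb[4L] - bb[2L]))
  need <- n
  while (need > 0L) {
    m <- max(16L, ceiling(need / max(frac, 1e-3) * 1.2))
    x <- stats::runif(m, bb[1L], bb[3L])
    y <- stats::runif(m, bb[2L], bb[4L])
    ok <- point_in_rings(x, y, list(region))
    out <- rbind(out, cbind(x[ok], y[ok]))
    need <- n - nrow(out)
  }
  out[seq_len(n), , drop = FALSE]
}
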