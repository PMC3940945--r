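# Synthetic slide renderer: a forward model for scanned IHC sections.
#
# Objects (vessel cross-sections as elliptical rings with an unstained lumen,
# cells as disks) are placed by a spatial point process, rasterized by
# pixel-centre scanline filling, and composed into an 8-bit RGB image by
# Beer-Lambert absorption: each pixel's optical density is the counterstain
# OD times its unit absorption vector plus the painted chromogen OD times its
# vector, and the transmitted intensity per channel is
# background * 10^(-OD). The painted raster itself is the ground truth, so
# the true area fraction is exact by construction.

#' Compose stain concentrations into an 8-bit RGB image
#'
#' @param concentrations N x 2 (or N x 3) matrix of per-pixel stain ODs in the
#'   order of the rows of `vectors`.
#' @param vectors a [stain_vectors()] object.
#' @param background per-channel incident intensity (8-bit scale).
#' @return N x 3 integer matrix of 8-bit RGB values.
#' @export
compose_rgb <- function(concentrations, vectors, background = c(255, 255, 255)) {
  concentrations <- as.matrix(concentrations)
  od <- concentrations %*% vectors[seq_len(ncol(concentrations)), , drop = FALSE]
  i <- round(matrix(background, nrow(od), 3L, byrow = TRUE) * 10^(-od))
  storage.mode(i) <- "integer"
  pmax(pmin(i, 255L), 0L)
}

#' Render a synthetic IHC slide with ground truth
#'
#' @param vessel_pattern [spatial_pattern_params()] for the vessel marker, or
#'   NULL for a slide without vessels.
#' @param cell_patterns named list of [spatial_pattern_params()] for discrete
#'   cell markers (may be empty).
#' @param stain a [stain_model_params()] object (carries the mpp calibration).
#' @param canvas_mm c(width, height) of the canvas, mm.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param slide_id identifier stored on the slide.
#' @param tissue_frac tissue ellipse semi-axes as a fraction of the half
#'   canvas (the remainder is bare glass).
#' @param pixel_budget reject rasters with more pixels than this.
#' @return list with `slide` (class `slide_image`: `pixels` nr x nc x 3
#'   integer array, `mpp`, `tissue_mask`, `slide_id`) and `truth` (class
#'   `ground_truth`: `object_polygons`, `cell_centroids`, `true_area_fraction`
#'   in percent, `pattern_kind`, `seed`, plus the exact `painted_mask`).
#' @export
render_slide <- function(vessel_pattern = NULL, cell_patterns = list(),
                         stain = stain_model_params(), canvas_mm = c(8, 8),
                         seed = 1L, slide_id = "slide",
                         tissue_frac = 0.92, pixel_budget = 2.5e7) {
  stopifnot(inherits(stain, "stain_model_params"))
  if (prod(canvas_mm) < 1) stop("canvas area must be at least 1 mm^2")
  s <- stain$mpp / 1000
  nc <- round(canvas_mm[1L] / s); nr <- round(canvas_mm[2L] / s)
  if (as.numeric(nr) * nc > pixel_budget)
    stop(sprintf(
      "raster %d x %d exceeds the pixel budget (%g); increase mpp above %.2f um/px",
      nr, nc, pixel_budget, 1000 * sqrt(prod(canvas_mm) / pixel_budget)))

  tissue_ring <- ellipse_ring(canvas_mm[1L] / 2, canvas_mm[2L] / 2,
                              tissue_frac * canvas_mm[1L] / 2,
                              tissue_frac * canvas_mm[2L] / 2, n = 96L)
  tissue_mask <- rasterize_rings(list(tissue_ring), c(nr, nc), stain$mpp)

  painted <- matrix(FALSE, nr, nc)
  od_map <- matrix(0, nr, nc)
  object_polygons <- list()
  cell_centroids <- list()

  paint <- function(rings, od) {
    bb <- rings_bbox(rings)
    c0 <- max(1L, floor(bb[1L] / s - 1)); c1 <- min(nc, ceiling(bb[3L] / s + 1))
    r0 <- max(1L, floor(bb[2L] / s - 1)); r1 <- min(nr, ceiling(bb[4L] / s + 1))
    if (c0 > c1 || r0 > r1) return(invisible())
    sub <- rasterize_rings(rings, c(r1 - r0 + 1L, c1 - c0 + 1L), stain$mpp,
                           origin = c((c0 - 1L) * s, (r0 - 1L) * s))
    if (!any(sub)) return(invisible())
    rows <- r0:r1; cols <- c0:c1
    blk_p <- painted[rows, cols, drop = FALSE]
    blk_o <- od_map[rows, cols, drop = FALSE]
    blk_p[sub] <- TRUE
    blk_o[sub] <- pmax(blk_o[sub], od)
    painted[rows, cols] <<- blk_p
    od_map[rows, cols] <<- blk_o
    invisible()
  }

  markers <- names(cell_patterns)
  if (length(cell_patterns) && is.null(markers))
    stop("cell_patterns must be a named list")

  with_seed(derive_seed(seed, 1L), {
    if (!is.null(vessel_pattern)) {
      stopifnot(vessel_pattern$object_kind == "vessel")
      centers <- sample_point_pattern(vessel_pattern, tissue_ring,
                                      seed = derive_seed(seed, 2L))
      nv <- nrow(centers)
      r_o <- stats::runif(nv, vessel_pattern$vessel_radius_range[1L],
                          vessel_pattern$vessel_radius_range[2L])
      elong <- stats::runif(nv, vessel_pattern$vessel_elongation_range[1L],
                            vessel_pattern$vessel_elongation_range[2L])
      theta <- stats::runif(nv, 0, 2 * pi)
      has_gap <- stats::runif(nv) < vessel_pattern$gap_prob
      g0 <- stats::runif(nv, 0, 2 * pi)
      glen <- 2 * pi * stats::runif(nv, vessel_pattern$gap_frac_range[1L],
                                    vessel_pattern$gap_frac_range[2L])
      ods <- stats::runif(nv, stain$chromogen_od_range[1L],
                          stain$chromogen_od_range[2L])
      # hard-core thinning by arrival order: vessel cross-sections are
      # disjoint structures, so later vessels too close to an accepted one
      # are dropped
      keep <- rep(TRUE, nv)
      hc <- vessel_pattern$hard_core_factor
      if (!is.null(hc) && hc > 0 && nv > 1L) {
        acc <- integer(0)
        for (i in seq_len(nv)) {
          if (length(acc)) {
            d <- sqrt((centers[acc, 1L] - centers[i, 1L])^2 +
                        (centers[acc, 2L] - centers[i, 2L])^2)
            if (any(d < hc * (r_o[acc] + r_o[i]))) {
              keep[i] <- FALSE
              next
            }
          }
          acc <- c(acc, i)
        }
      }
      for (i in which(keep)) {
        gap <- if (has_gap[i]) c(g0[i], g0[i] + glen[i]) else NULL
        rings <- annulus_rings(centers[i, 1L], centers[i, 2L],
                               a = r_o[i] * sqrt(elong[i]),
                               b = r_o[i] / sqrt(elong[i]),
                               wall_frac = vessel_pattern$wall_frac,
                               theta = theta[i], gap_arc = gap)
        paint(rings, ods[i])
        object_polygons[[length(object_polygons) + 1L]] <-
          list(rings = rings, kind = "vessel", marker = "vessel", od = ods[i])
      }
    }
    for (m in markers) {
      p <- cell_patterns[[m]]
      stopifnot(p$object_kind == "cell")
      centers <- sample_point_pattern(p, tissue_ring,
                                      seed = derive_seed(seed, 2L + match(m, markers)))
      cell_centroids[[m]] <- centers
      for (i in seq_len(nrow(centers))) {
        od <- stats::runif(1L, stain$chromogen_od_range[1L],
                           stain$chromogen_od_range[2L])
        rings <- list(disk_ring(centers[i, 1L], centers[i, 2L], p$cell_radius))
        paint(rings, od)
        object_polygons[[length(object_polygons) + 1L]] <-
          list(rings = rings, kind = "cell", marker = m, od = od)
      }
    }
  })

  painted <- painted & tissue_mask
  od_map[!painted] <- 0

  # Beer-Lambert composition + scanner noise
  pixels <- with_seed(derive_seed(seed, 1000L), {
    n <- nr * nc
    od_h <- numeric(n)
    idx <- which(tissue_mask)
    od_h[idx] <- pmax(0, stain$counterstain_od +
                        stats::rnorm(length(idx), 0, stain$counterstain_od_sd))
    v <- stain$vectors
    out <- array(0L, c(nr, nc, 3L))
    for (ch in 1:3) {
      od <- od_h * v["counterstain", ch] + as.vector(od_map) * v["chromogen", ch]
      i <- stain$background_rgb[ch] * 10^(-od) + stats::rnorm(n, 0, stain$noise_sd)
      out[, , ch] <- matrix(as.integer(pmax(pmin(round(i), 255), 0)), nr, nc)
    }
    out
  })

  pattern_kind <- if (!is.null(vessel_pattern)) vessel_pattern$pattern_kind
                  else if (length(cell_patterns)) cell_patterns[[1L]]$pattern_kind
                  else "homogeneous"
  taf <- if (sum(tissue_mask) > 0) 100 * sum(painted) / sum(tissue_mask) else 0

  slide <- structure(list(pixels = pixels, mpp = stain$mpp,
                          tissue_mask = tissue_mask, slide_id = slide_id),
                     class = "slide_image")
  truth <- structure(list(object_polygons = object_polygons,
                          cell_centroids = cell_centroids,
                          true_area_fraction = taf,
                          pattern_kind = pattern_kind, seed = seed,
                          painted_mask = painted,
                          tissue_px = sum(tissue_mask)),
                     class = "ground_truth")
  list(slide = slide, truth = truth)
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s: %d x %d px @ %.2f um/px (%.1f x %.1f mm), tissue %.1f mm^2\n",
              x$slide_id, d[1L], d[2L], x$mpp,
              d[2L] * x$mpp / 1000, d[1L] * x$mpp / 1000,
              sum(x$tissue_mask) * (x$mpp / 1000)^2))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d objects, %s pattern, true area fraction %.3f%% (seed %d)\n",
              length(x$object_polygons), x$pattern_kind,
              x$true_area_fraction, x$seed))
  invisible(x)
}
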