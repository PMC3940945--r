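# Per-slide threshold optimization and the immunoreactive mask.

#' Estimate a per-slide chromogen threshold (Otsu with an OD floor)
#'
#' Maximizes the between-class variance of the chromogen OD histogram over
#' tissue pixels (Otsu's criterion), then applies a configured OD floor: the
#' returned threshold is never below the floor, and a degenerate
#' (effectively constant, or unimodal below the floor) histogram returns the
#' floor itself. This is the per-section color-threshold optimization step:
#' every slide gets its own threshold, but by a reproducible rule.
#'
#' @param chromogen_map chromogen OD matrix from [deconvolve_stains()].
#' @param tissue_mask logical matrix of evaluable tissue.
#' @param od_floor minimum admissible threshold (OD units).
#' @param n_bins histogram resolution.
#' @return Threshold in OD units.
#' @export
estimate_threshold <- function(chromogen_map, tissue_mask,
                               od_floor = 0.15, n_bins = 256L) {
  stopifnot(identical(dim(chromogen_map), dim(tissue_mask)))
  vals <- chromogen_map[tissue_mask]
  if (!length(vals)) stop("tissue mask is empty; no pixels to threshold")
  lo <- min(vals); hi <- max(vals)
  if (hi - lo < 1e-8) return(od_floor)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(as.numeric(h))
  mu <- cumsum(h * mids)
  n <- w[n_bins]; mu_t <- mu[n_bins]
  w1 <- w[-n_bins]; mu1 <- mu[-n_bins]
  bcv <- ifelse(w1 == 0 | w1 == n, 0,
                (mu_t * w1 - mu1 * n)^2 / (w1 * (n - w1)))
  k <- which.max(bcv) # ties -> lowest bin
  max(breaks[k + 1L], od_floor)
}

#' Binary immunoreactive mask from a chromogen map
#'
#' Thresholds the chromogen OD map within tissue and removes connected
#' components (8-connectivity) smaller than `min_object_px` - sub-capillary
#' debris at the default calibration.
#'
#' @param chromogen_map chromogen OD matrix.
#' @param tissue_mask logical matrix of evaluable tissue.
#' @param threshold OD threshold (>= 0), e.g. from [estimate_threshold()].
#' @param min_object_px minimum surviving component size, pixels.
#' @param mpp microns per pixel (carried on the result).
#' @return Object of class `ihc_mask`: list with logical `mask`,
#'   `threshold_used`, `min_object_px`, `mpp`.
#' @export
immunoreactive_mask <- function(chromogen_map, tissue_mask, threshold,
                                min_object_px = 8L, mpp = NA_real_) {
  stopifnot(identical(dim(chromogen_map), dim(tissue_mask)), threshold >= 0)
  m <- (chromogen_map >= threshold) & tissue_mask
  m <- filter_small_components(m, as.integer(min_object_px))
  structure(list(mask = m, threshold_used = threshold,
                 min_object_px = as.integer(min_object_px), mpp = mpp),
            class = "ihc_mask")
}

#' @export
print.ihc_mask <- function(x, ...) {
  cat(sprintf("<ihc_mask> %d x %d px, %d positive (%.3f%%), threshold %.3f OD, min object %d px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold_used, x$min_object_px))
  invisible(x)
}

# Accept either an ihc_mask or a plain logical matrix.
as_mask_matrix <- function(mask) {
  if (inherits(mask, "ihc_mask")) mask$mask else mask
}
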