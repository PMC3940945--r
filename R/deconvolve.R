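# Color deconvolution: unmixing an RGB image into per-stain optical-density
# concentration maps by inverting the stain matrix in Beer-Lambert OD space.

# Per-channel optical density of 8-bit intensities against a 255 white point.
# The epsilon (1/255) keeps OD finite at intensity 0.
od_transform <- function(intensity) -log10((intensity + 1 / 255) / 255)

#' Deconvolve a slide into per-stain concentration maps
#'
#' Per-pixel optical density is computed per channel as
#' `-log10((I + 1/255)/255)` and projected onto the stain basis by inverting
#' the 3 x 3 stain matrix; negative concentrations (noise outside the stain
#' simplex) are clipped to zero.
#'
#' @param slide a `slide_image`, or an nr x nc x 3 array of 8-bit RGB values.
#' @param vectors a [stain_vectors()] object.
#' @param clip clip negative concentrations to zero (the default; set FALSE
#'   to keep the exact linear inversion, e.g. to verify that recomposition
#'   reproduces the OD image).
#' @return Object of class `stain_maps`: list with `counterstain`,
#'   `chromogen`, `residual` OD matrices, the `vectors`, and `mpp` when known.
#' @export
deconvolve_stains <- function(slide, vectors = stain_vectors(), clip = TRUE) {
  stopifnot(inherits(vectors, "stain_vectors"))
  pixels <- if (inherits(slide, "slide_image")) slide$pixels else slide
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L)
  nr <- dim(pixels)[1L]; nc <- dim(pixels)[2L]
  od <- od_transform(matrix(as.numeric(pixels), nr * nc, 3L))
  conc <- od %*% solve(unclass(vectors))
  if (clip) conc[conc < 0] <- 0
  structure(list(counterstain = matrix(conc[, 1L], nr, nc),
                 chromogen = matrix(conc[, 2L], nr, nc),
                 residual = matrix(conc[, 3L], nr, nc),
                 vectors = vectors,
                 mpp = if (inherits(slide, "slide_image")) slide$mpp else NA_real_),
            class = "stain_maps")
}

#' Recompose an OD image from deconvolved stain maps
#'
#' Inverse of [deconvolve_stains()] up to the negative-concentration clip;
#' used to verify that unmixing preserves the OD image.
#'
#' @param maps a `stain_maps` object.
#' @return nr x nc x 3 array of per-channel optical densities.
#' @export
recompose_od <- function(maps) {
  stopifnot(inherits(maps, "stain_maps"))
  nr <- nrow(maps$chromogen); nc <- ncol(maps$chromogen)
  conc <- cbind(as.vector(maps$counterstain), as.vector(maps$chromogen),
                as.vector(maps$residual))
  od <- conc %*% unclass(maps$vectors)
  array(od, c(nr, nc, 3L))
}

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf("<stain_maps> %d x %d px; chromogen OD range [%.3f, %.3f]\n",
              nrow(x$chromogen), ncol(x$chromogen),
              min(x$chromogen), max(x$chromogen)))
  invisible(x)
}
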