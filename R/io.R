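# File interfaces: RGB TIFF/PNG slides, single-channel mask PNGs, GeoJSON
# ground truth and hot spots (coordinates in mm), CSV manifests, and the
# green mark-up overlay of detected immunoreactive area.

#' Write a slide image to TIFF or PNG
#'
#' @param slide a `slide_image`.
#' @param path output path ending in .tif/.tiff or .png.
#' @return The path, invisibly.
#' @export
write_slide_image <- function(slide, path) {
  img <- slide$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path)
  else if (ext == "png") png::writePNG(img, path)
  else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a slide image from TIFF or PNG
#'
#' @param path RGB image path.
#' @param mpp microns per pixel of the raster.
#' @param mask_path optional single-channel PNG tissue mask; defaults to the
#'   whole raster.
#' @param slide_id identifier.
#' @return A `slide_image`.
#' @export
read_slide_image <- function(path, mpp, mask_path = NULL,
                             slide_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1:3, drop = FALSE]
  pixels <- array(as.integer(round(img * 255)), dim = c(dim(img)[1:2], 3L))
  tissue <- if (is.null(mask_path)) matrix(TRUE, dim(img)[1L], dim(img)[2L])
            else png::readPNG(mask_path) > 0.5
  if (length(dim(tissue)) == 3L) tissue <- tissue[, , 1L]
  structure(list(pixels = pixels, mpp = mpp, tissue_mask = tissue,
                 slide_id = slide_id), class = "slide_image")
}

#' Write a binary mask as a single-channel PNG
#' @param mask logical matrix or `ihc_mask`.
#' @param path output .png path.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Write a mark-up overlay of detected immunoreactive area
#'
#' Detected pixels are tinted green over the original image, the standard
#' visual check that the mask follows the chromogen.
#'
#' @param slide a `slide_image`.
#' @param mask an `ihc_mask` or logical matrix.
#' @param path output .png path.
#' @param alpha tint opacity.
#' @export
write_markup_png <- function(slide, mask, path, alpha = 0.6) {
  m <- as_mask_matrix(mask)
  img <- slide$pixels / 255
  tint <- c(0.1, 0.85, 0.1)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m] <- (1 - alpha) * plane[m] + alpha * tint[ch]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}

# One GeoJSON polygon geometry from a list of rings (mm coordinates).
geojson_polygon <- function(rings) {
  list(type = "Polygon", coordinates = lapply(rings, function(r)
    lapply(seq_len(nrow(r) + 1L), function(i) {
      j <- if (i > nrow(r)) 1L else i
      c(r[j, 1L], r[j, 2L])
    })))
}

#' Write generator ground truth as GeoJSON
#'
#' Object polygons and cell centroids in mm coordinates; feature-collection
#' properties carry `pattern_kind`, `seed`, and `true_area_fraction`.
#'
#' @param truth a `ground_truth`.
#' @param path output .geojson path.
#' @export
write_ground_truth_geojson <- function(truth, path) {
  feats <- lapply(truth$object_polygons, function(ob)
    list(type = "Feature",
         properties = list(kind = ob$kind, marker = ob$marker, od = ob$od),
         geometry = geojson_polygon(ob$rings)))
  for (m in names(truth$cell_centroids)) {
    cm <- truth$cell_centroids[[m]]
    for (i in seq_len(nrow(cm)))
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(kind = "cell_centroid", marker = m),
        geometry = list(type = "Point", coordinates = c(cm[i, 1L], cm[i, 2L])))
  }
  obj <- list(type = "FeatureCollection",
              properties = list(pattern_kind = truth$pattern_kind,
                                seed = truth$seed,
                                true_area_fraction = truth$true_area_fraction,
                                units = "mm"),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write selected hot spots as GeoJSON
#'
#' @param hotspot_set a [select_hotspots()] result.
#' @param path output .geojson path.
#' @export
write_hotspots_geojson <- function(hotspot_set, path) {
  feats <- lapply(seq_len(hotspot_set$k), function(j) {
    h <- hotspot_set$hotspots[[j]]
    list(type = "Feature",
         properties = list(rank = j, radius_mm = h$radius_mm,
                           area_mm2 = h$area_mm2,
                           density_px = hotspot_set$density[j],
                           area_fraction_pct = hotspot_set$area_fraction[j]),
         geometry = list(type = "Point", coordinates = c(h$center[1L], h$center[2L])))
  })
  obj <- list(type = "FeatureCollection",
              properties = list(units = "mm"), features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write a cohort manifest as CSV
#' @param plan a [cohort_plan()].
#' @param path output .csv path.
#' @export
write_cohort_manifest <- function(plan, path) {
  utils::write.csv(plan, path, row.names = FALSE)
  invisible(path)
}

#' Write per-slide quantification records as CSV
#'
#' Per-hot-spot list columns are flattened to semicolon-separated strings;
#' density column names carry the cells/0.1 mm^2 unit to avoid unit drift.
#'
#' @param records data.frame from [quantify_cohort()].
#' @param path output .csv path.
#' @export
write_quantification_csv <- function(records, path) {
  out <- records
  for (col in c("hotspot_area_fractions", "mvd", "mvd_per_mm2", "chalkley",
                "hotspot_cell_densities")) {
    if (col %in% names(out))
      out[[col]] <- vapply(out[[col]], function(v)
        paste(signif(as.numeric(v), 6), collapse = ";"), character(1L))
  }
  nm <- names(out)
  nm[nm == "whole_slide_cell_density"] <- "whole_slide_cell_density_per_0.1mm2"
  nm[nm == "hotspot_mean_cell_density"] <- "hotspot_mean_cell_density_per_0.1mm2"
  names(out) <- nm
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
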