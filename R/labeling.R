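# 8-connected component labeling. EBImage::bwlabel provides the fast
# first pass but joins pixels by edge adjacency only, so labels touching
# diagonally are merged afterwards with a vectorized union-find.

#' Label connected components of a binary mask (8-connectivity)
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background), numbered
#'   consecutively from 1 in first-pixel scan order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal adjacencies between distinct labels
  a <- c(lab[-nr, -nc], lab[-nr, -1L])
  b <- c(lab[-1L, -1L], lab[-1L, -nc])
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) {
    pairs <- unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1L))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # renumber consecutively
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Sizes and centroids of labelled components
#'
#' @param lab integer label matrix from [label_components()].
#' @return data.frame with `label`, `size` (pixels), `row`, `col` centroids
#'   (pixel units, 1-based).
#' @export
component_stats <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx))
    return(data.frame(label = integer(0), size = integer(0),
                      row = numeric(0), col = numeric(0)))
  l <- lab[idx]
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  size <- tabulate(l)
  data.frame(label = seq_along(size), size = size,
             row = rowsum(as.numeric(r), l)[, 1L] / size,
             col = rowsum(as.numeric(cc), l)[, 1L] / size)
}

# Remove components smaller than min_px (8-connectivity).
filter_small_components <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
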