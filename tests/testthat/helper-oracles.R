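# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops and direct formulas only.

# 8-connected component count by breadth-first flood fill.
oracle_label_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; cc <- p[2L] + dc
        if (r >= 1L && r <= nr && cc >= 1L && cc <= nc &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  count
}

# Otsu's threshold by exhaustive search over the observed values.
oracle_otsu <- function(v) {
  cand <- sort(unique(v))
  n <- length(v)
  best <- -Inf; bt <- cand[1L]
  for (t in cand[-1L]) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    b <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (b > best) { best <- b; bt <- t }
  }
  bt
}

# Area fraction by explicit per-pixel counting.
oracle_area_fraction <- function(mask, roi_px, evaluable) {
  num <- 0L; den <- 0L
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (roi_px[r, cc] && evaluable[r, cc]) {
      den <- den + 1L
      if (mask[r, cc]) num <- num + 1L
    }
  }
  100 * num / den
}

# Chalkley count by explicit search over the same rotation/offset grid.
oracle_chalkley <- function(mask, center, radius_mm, dots, mpp,
                            n_rotations, n_offsets, jitter_frac) {
  s <- mpp / 1000
  best <- 0L
  offsets <- list(c(0, 0))
  if (n_offsets > 1L)
    for (j in seq_len(n_offsets - 1L)) {
      a <- 2 * pi * (j - 1L) / (n_offsets - 1L)
      offsets[[j + 1L]] <- jitter_frac * radius_mm * c(cos(a), sin(a))
    }
  for (k in seq_len(n_rotations)) {
    ang <- 2 * pi * (k - 1L) / n_rotations
    for (off in offsets) {
      hits <- 0L
      for (d in seq_len(nrow(dots))) {
        x <- center[1L] + radius_mm * (dots[d, 1L] * cos(ang) - dots[d, 2L] * sin(ang)) + off[1L]
        y <- center[2L] + radius_mm * (dots[d, 1L] * sin(ang) + dots[d, 2L] * cos(ang)) + off[2L]
        cc <- min(max(ceiling(x / s), 1L), ncol(mask))
        rr <- min(max(ceiling(y / s), 1L), nrow(mask))
        if (mask[rr, cc]) hits <- hits + 1L
      }
      if (hits > best) best <- hits
    }
  }
  best
}

# Even-odd point-in-polygon by angle-free crossing count, one point at a time
# (independent of the package's vectorized version and of its scanline fill).
oracle_point_in_rings <- function(x, y, rings) {
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    for (e in seq_len(n)) {
      x1 <- ring[e, 1L]; y1 <- ring[e, 2L]
      j <- if (e == n) 1L else e + 1L
      x2 <- ring[j, 1L]; y2 <- ring[j, 2L]
      if ((y1 <= y) != (y2 <= y)) {
        xc <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xc) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

# Densest non-overlapping circle pair by exhaustive search over a candidate
# grid (counts computed by direct distance test).
oracle_best_pair <- function(mask, evaluable, r_px, stride, min_inside = 0.9) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- ceiling(r_px)
  rows <- seq(kr + 1L, nr - kr, by = stride)
  cols <- seq(kr + 1L, nc - kr, by = stride)
  cand <- NULL
  # kernel pixel count for the validity rule
  ksum <- 0L
  for (i in -kr:kr) for (j in -kr:kr) if (i^2 + j^2 <= r_px^2) ksum <- ksum + 1L
  for (r in rows) for (cc in cols) {
    m_ct <- 0L; e_ct <- 0L
    for (i in -kr:kr) for (j in -kr:kr) {
      if (i^2 + j^2 > r_px^2) next
      if (evaluable[r + i, cc + j]) e_ct <- e_ct + 1L
      if (mask[r + i, cc + j]) m_ct <- m_ct + 1L
    }
    if (e_ct >= min_inside * ksum)
      cand <- rbind(cand, c(r, cc, m_ct))
  }
  best <- -1L; pick <- NULL
  for (a in seq_len(nrow(cand))) for (b in seq_len(nrow(cand))) {
    if (a == b) next
    d2 <- (cand[a, 1L] - cand[b, 1L])^2 + (cand[a, 2L] - cand[b, 2L])^2
    if (d2 < (2 * r_px)^2) next
    tot <- cand[a, 3L] + cand[b, 3L]
    if (tot > best) { best <- tot; pick <- rbind(cand[a, ], cand[b, ]) }
  }
  list(total = best, centers = pick)
}

# Greedy nearest matching of detections to ground-truth centroids.
match_detections <- function(detected, truth, radius_mm) {
  if (!length(detected)) detected <- matrix(numeric(0), 0L, 2L)
  if (!length(truth)) truth <- matrix(numeric(0), 0L, 2L)
  matched <- 0L
  used <- rep(FALSE, nrow(truth))
  if (nrow(detected) && nrow(truth)) {
    for (j in seq_len(nrow(detected))) {
      d <- sqrt((truth[, 1L] - detected[j, 1L])^2 +
                  (truth[, 2L] - detected[j, 2L])^2)
      d[used] <- Inf
      k <- which.min(d)
      if (d[k] <= radius_mm) { matched <- matched + 1L; used[k] <- TRUE }
    }
  }
  list(matched = matched, n_detected = nrow(detected), n_truth = nrow(truth))
}
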