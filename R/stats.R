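# Cohort-level statistics: exclusion filtering, Pearson correlations between
# quantification methods and between hot-spot and whole-slide analyses, and
# the interobserver-variability statistic.

#' Mark slides below the evaluable-area exclusion threshold
#'
#' Sections with too little evaluable tissue are excluded from cohort
#' statistics (strictly below the threshold; the default 5 mm^2 is the
#' conventional cut for decalcified bone sections). Records are marked, never
#' deleted.
#'
#' @param records data.frame with an `evaluable_area_mm2` column (e.g. from
#'   [quantify_cohort()]).
#' @param min_area_mm2 exclusion threshold, mm^2.
#' @return The same data.frame with its `excluded` column set.
#' @export
apply_exclusion_filter <- function(records, min_area_mm2 = 5) {
  stopifnot(min_area_mm2 > 0)
  if (!nrow(records)) {
    records$excluded <- logical(0)
    return(records)
  }
  records$excluded <- records$evaluable_area_mm2 < min_area_mm2
  records
}

#' Pearson correlation with a two-sided test
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t-transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @param pair optional c(label_x, label_y).
#' @return Object of class `ihc_correlation`: list with `r`, `p`, `n`, `pair`.
#' @export
pearson_correlation <- function(x, y, pair = c(deparse(substitute(x)),
                                               deparse(substitute(y)))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop(sprintf("'%s' has zero variance", pair[1L]))
  if (stats::var(y) == 0) stop(sprintf("'%s' has zero variance", pair[2L]))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 pair = pair), class = "ihc_correlation")
}

#' @export
print.ihc_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("%s ~ %s: r = %.*f, p = %.3g, n = %d%s\n",
              x$pair[1L], x$pair[2L], digits, x$r, x$p, x$n,
              if (x$p < 0.05) " *" else " (n.s.)"))
  invisible(x)
}

#' Interobserver variability
#'
#' Per-slide absolute disagreement between two observers, expressed as a
#' percentage of the cohort mean (default) or of the per-slide mean; a slide
#' is acceptable when its variability is strictly below the limit.
#'
#' @param obs1,obs2 numeric vectors of per-slide measurements by the two
#'   observers.
#' @param mean_mode "cohort" (normalize by the mean of all observations) or
#'   "per_slide" (normalize each slide by its own two-observer mean).
#' @param limit_pct acceptability bound, percent (strict).
#' @return Object of class `ihc_interobserver`: list with
#'   `per_slide_variability` (%), `acceptable`, `cohort_mean`, `limit_pct`.
#' @export
interobserver_variability <- function(obs1, obs2,
                                      mean_mode = c("cohort", "per_slide"),
                                      limit_pct = 10) {
  mean_mode <- match.arg(mean_mode)
  if (length(obs1) != length(obs2)) stop("observer vectors must match in length")
  cohort_mean <- mean(c(obs1, obs2))
  if (!is.finite(cohort_mean) || cohort_mean <= 0)
    stop("cohort mean must be positive to normalize interobserver differences")
  denom <- if (mean_mode == "cohort") cohort_mean else (obs1 + obs2) / 2
  v <- abs(obs1 - obs2) / denom * 100
  structure(list(per_slide_variability = v, acceptable = v < limit_pct,
                 cohort_mean = cohort_mean, limit_pct = limit_pct,
                 mean_mode = mean_mode), class = "ihc_interobserver")
}

#' @export
print.ihc_interobserver <- function(x, ...) {
  cat(sprintf("<ihc_interobserver> cohort mean %.3f (%s mode); %d/%d slides acceptable (< %g%%)\n",
              x$cohort_mean, x$mean_mode, sum(x$acceptable),
              length(x$acceptable), x$limit_pct))
  invisible(x)
}

#' Compare whole-slide and hot-spot quantification across a cohort
#'
#' The cohort-level analysis: (a) correlations between the three vessel
#' quantification methods over pooled hot spots (area fraction vs micro-vessel
#' density and vs Chalkley count), (b) hot-spot vs whole-slide correlation per
#' marker (area fractions for vessel markers, cell densities for cell
#' markers), (c) per-slide hot-spot/whole-slide enrichment ratios, and (d) the
#' hot-spot vs whole-slide correlations stratified by the generator's spatial
#' pattern when ground truth is available. Excluded slides never enter the
#' statistics; analyses with too few slides are flagged rather than computed.
#'
#' @param records data.frame from [quantify_cohort()] (or rbind-ed
#'   [as.data.frame.slide_quantification()] rows).
#' @param min_n minimum non-excluded slides for cohort-level correlations.
#' @return Object of class `ihc_comparison`.
#' @export
compare_methods <- function(records, min_n = 10L) {
  records <- apply_exclusion_filter(records,
                                    min_area_mm2 = attr(records, "min_area_mm2") %||% 5)
  kept <- records[!records$excluded, , drop = FALSE]
  flags <- character(0)
  method_correlations <- list()
  marker_correlations <- list()
  stratified <- list()

  vess <- kept[kept$marker_kind == "vessel", , drop = FALSE]
  if (nrow(vess)) {
    af <- unlist(vess$hotspot_area_fractions)
    mvd <- unlist(vess$mvd)
    ck <- unlist(vess$chalkley)
    if (length(af) >= 3L && stats::var(af) > 0 && stats::var(mvd) > 0)
      method_correlations$area_fraction_vs_mvd <-
        pearson_correlation(af, mvd, pair = c("hotspot_area_fraction", "mvd"))
    else flags <- c(flags, "area_fraction_vs_mvd: insufficient or degenerate hot-spot data")
    if (length(af) >= 3L && stats::var(af) > 0 && stats::var(ck) > 0)
      method_correlations$area_fraction_vs_chalkley <-
        pearson_correlation(af, ck, pair = c("hotspot_area_fraction", "chalkley"))
    else flags <- c(flags, "area_fraction_vs_chalkley: insufficient or degenerate hot-spot data")
  }

  ratios <- NULL
  for (m in unique(kept$marker)) {
    sub <- kept[kept$marker == m, , drop = FALSE]
    if (sub$marker_kind[1L] == "vessel") {
      x <- sub$hotspot_mean_area_fraction; y <- sub$whole_slide_area_fraction
    } else {
      x <- sub$hotspot_mean_cell_density; y <- sub$whole_slide_cell_density
    }
    ratios <- rbind(ratios, data.frame(
      slide_id = sub$slide_id, marker = m,
      hotspot = x, whole_slide = y,
      ratio = ifelse(y > 0, x / y, NA_real_),
      pattern_kind = sub$pattern_kind, stringsAsFactors = FALSE))
    if (nrow(sub) < max(min_n, 3L)) {
      flags <- c(flags, sprintf(
        "%s: only %d non-excluded slides (< %d); hot-spot vs whole-slide correlation not computed",
        m, nrow(sub), max(min_n, 3L)))
    } else if (stats::var(x) == 0 || stats::var(y) == 0) {
      flags <- c(flags, sprintf(
        "%s: degenerate (zero-variance) quantification; correlation not computed", m))
    } else {
      marker_correlations[[m]] <-
        pearson_correlation(x, y, pair = c(paste0(m, "_hotspot"),
                                           paste0(m, "_whole_slide")))
      if (!all(is.na(sub$pattern_kind))) {
        for (pk in unique(sub$pattern_kind)) {
          sel <- sub$pattern_kind == pk
          if (sum(sel) >= 3L && stats::var(x[sel]) > 0 && stats::var(y[sel]) > 0)
            stratified[[paste(m, pk, sep = "_")]] <-
              pearson_correlation(x[sel], y[sel],
                                  pair = c(paste(m, pk, "hotspot", sep = "_"),
                                           paste(m, pk, "whole_slide", sep = "_")))
        }
      }
    }
  }

  structure(list(method_correlations = method_correlations,
                 marker_correlations = marker_correlations,
                 stratified = stratified, ratios = ratios,
                 n_total = nrow(records), n_kept = nrow(kept),
                 n_excluded = sum(records$excluded), flags = flags),
            class = "ihc_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ihc_comparison <- function(x, ...) {
  cat(sprintf("<ihc_comparison> %d slides (%d excluded)\n",
              x$n_total, x$n_excluded))
  if (length(x$method_correlations)) {
    cat("Method correlations over pooled hot spots:\n")
    for (cc in x$method_correlations) { cat("  "); print(cc) }
  }
  if (length(x$marker_correlations)) {
    cat("Hot-spot vs whole-slide correlations:\n")
    for (cc in x$marker_correlations) { cat("  "); print(cc) }
  }
  if (length(x$stratified)) {
    cat("Stratified by spatial pattern:\n")
    for (cc in x$stratified) { cat("  "); print(cc) }
  }
  if (length(x$flags)) cat("Flags:\n", paste0("  ", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.ihc_comparison <- function(object, ...) {
  r <- object$ratios
  if (!is.null(r)) {
    agg <- stats::aggregate(ratio ~ marker, data = r, FUN = function(z)
      c(median = stats::median(z, na.rm = TRUE)))
    cat("Median hot-spot / whole-slide enrichment by marker:\n")
    print(agg)
  }
  print(object)
  invisible(object)
}

#' Scatter plots of hot-spot vs whole-slide quantification
#'
#' One panel per marker with the identity line; the visual analogue of the
#' cohort correlation analysis.
#'
#' @param x an `ihc_comparison`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ihc_comparison <- function(x, ...) {
  r <- x$ratios
  if (is.null(r) || !nrow(r)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  markers <- unique(r$marker)
  old <- graphics::par(mfrow = c(1, length(markers)))
  on.exit(graphics::par(old))
  for (m in markers) {
    sub <- r[r$marker == m, ]
    lim <- range(c(sub$hotspot, sub$whole_slide), finite = TRUE)
    graphics::plot(sub$whole_slide, sub$hotspot, xlim = lim, ylim = lim,
                   xlab = "whole slide", ylab = "hot spots", main = m,
                   pch = ifelse(sub$pattern_kind == "clustered", 17, 1), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
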