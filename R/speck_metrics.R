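# Per-speck morphometrics and the summary statistics used to tabulate them.

as_xy <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  points
}

#' 2D radius of gyration
#'
#' \eqn{R_g = \sqrt{Var(x) + Var(y)}} with population (divide-by-N)
#' variances: the root-mean-square distance of the localizations from their
#' centroid. Restricted to 2D even when z is available, since the lateral
#' precision of the data far exceeds the axial one.
#'
#' @param points A [loc_table] or two-column (x, y) matrix in nm.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration_2d <- function(points) {
  p <- as_xy(points)
  n <- nrow(p)
  if (n < 1L) stop("need at least one point")
  mx <- mean(p[, 1L]); my <- mean(p[, 2L])
  sqrt(sum((p[, 1L] - mx)^2 + (p[, 2L] - my)^2) / n)
}

#' 2D eccentricity of a point cloud
#'
#' Ratio of the major to the minor axis of the localization distribution:
#' \eqn{\sqrt{\lambda_{max} / \lambda_{min}}} of the eigenvalues of the 2x2
#' coordinate covariance matrix. Circular objects have eccentricity near 1.
#'
#' @param points A [loc_table] or two-column matrix; at least 3 non-collinear
#'   points.
#' @return Dimensionless eccentricity >= 1.
#' @export
eccentricity_2d <- function(points) {
  p <- as_xy(points)
  if (nrow(p) < 3L) stop("undefined eccentricity: need at least 3 points")
  cv <- stats::cov(p) * (nrow(p) - 1) / nrow(p)   # population covariance
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-12)
    stop("undefined eccentricity: points are collinear")
  sqrt(ev[1L] / ev[2L])
}

#' Per-speck metrics
#'
#' Computes localization count, 2D radius of gyration, eccentricity and
#' density (localizations per segmented speck area) for one speck.
#'
#' @param table [loc_table] of the localizations inside the speck segment
#'   (single channel).
#' @param speck_area_um2 Segmented speck area in square micrometres.
#' @param channel Channel identifier stored with the metrics.
#' @return Object of class `speck_metrics`: list with `n_locs`, `rg_nm`,
#'   `eccentricity` (NA when undefined), `speck_area_um2`,
#'   `density_per_um2`, `channel`.
#' @export
speck_metrics <- function(table, speck_area_um2, channel = NULL) {
  n <- nrow(table)
  ecc <- tryCatch(eccentricity_2d(table), error = function(e) NA_real_)
  structure(list(
    n_locs = n,
    rg_nm = if (n >= 1L) radius_of_gyration_2d(table) else NA_real_,
    eccentricity = ecc,
    speck_area_um2 = speck_area_um2,
    density_per_um2 = speck_density(n, speck_area_um2),
    channel = channel %||% (if (n) table$channel[[1L]] else NA_character_)),
    class = "speck_metrics")
}

#' Speck density
#'
#' Number of localizations per segmented speck area.
#'
#' @param n_locs Localization count (>= 0).
#' @param speck_area_um2 Speck area in square micrometres (> 0).
#' @return Density in 1/um^2.
#' @export
speck_density <- function(n_locs, speck_area_um2) {
  if (is.na(speck_area_um2)) return(NA_real_)
  if (speck_area_um2 <= 0) stop("speck area must be positive")
  n_locs / speck_area_um2
}

#' Mean / median / mode / MAD summary
#'
#' The summary block used to tabulate per-speck and per-cluster
#' distributions: mean, median, histogram-based mode, and the unscaled
#' median absolute deviation of the median, MAD = median(|v - median(v)|).
#' The mode is the center of the tallest histogram bin (leftmost on ties);
#' the bin rule is configurable and reported alongside, since a histogram
#' mode depends on it.
#'
#' @param values Numeric vector (n >= 1).
#' @param mode_bin_rule `"fd"` (Freedman--Diaconis, default), `"sturges"`,
#'   `"scott"`, or a numeric bin width.
#' @return Object of class `summary_stats`: list with `mean`, `median`,
#'   `mode`, `mad`, `n`, `mode_bin_rule`.
#' @export
summarize_values <- function(values, mode_bin_rule = "fd") {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least one value")
  med <- stats::median(values)
  if (length(unique(values)) == 1L) {
    mode <- values[[1L]]
  } else {
    breaks <- if (is.numeric(mode_bin_rule)) {
      w <- mode_bin_rule
      seq(min(values) - w / 2, max(values) + w, by = w)
    } else {
      switch(match.arg(mode_bin_rule, c("fd", "sturges", "scott")),
             fd = "FD", sturges = "Sturges", scott = "Scott")
    }
    h <- graphics::hist(values, breaks = breaks, plot = FALSE)
    mode <- h$mids[which.max(h$counts)]   # which.max takes the leftmost tie
  }
  structure(list(mean = mean(values), median = med, mode = mode,
                 mad = stats::median(abs(values - med)),
                 n = length(values), mode_bin_rule = mode_bin_rule),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> n = %d: mean %.4g, median %.4g, mode %.4g (%s bins), MAD %.4g\n",
    x$n, x$mean, x$median, x$mode,
    if (is.numeric(x$mode_bin_rule)) paste0(x$mode_bin_rule, "-nm") else
      x$mode_bin_rule, x$mad))
  invisible(x)
}

#' Two-sample distribution comparison
#'
#' Thin wrappers around the standard two-sided two-sample
#' Kolmogorov--Smirnov test and the one-sided Welch t-test, with the usual
#' star coding (0.05 / 0.01 / 0.001).
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param test `"ks"` (default) or `"t_one_sided"` (alternative: mean of `a`
#'   greater).
#' @return List with `statistic`, `p_value`, `stars`, `test`.
#' @export
compare_distributions <- function(a, b, test = c("ks", "t_one_sided")) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L) stop("both samples need n >= 2")
  res <- if (test == "ks") {
    suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  } else {
    stats::t.test(a, b, alternative = "greater")
  }
  p <- res$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(statistic = unname(res$statistic), p_value = p, stars = stars,
       test = test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
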