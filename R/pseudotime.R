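# Pseudo-time ordering of speck assembly: day-to-day calibration, cell-area
# normalization, binning, center-of-mass alignment and sum projections.

#' Pseudo-time of speck assembly
#'
#' The fraction of a cell's localizations located within the speck segment:
#' a per-cell proxy for the progression of ASC recruitment (0 = no
#' recruitment, 1 = fully recruited). Pseudo-time approximates ordering, not
#' physical time.
#'
#' @param in_speck,total Localization counts (vectorized); `total` > 0.
#' @return Fraction in `[0, 1]`.
#' @export
pseudo_time <- function(in_speck, total) {
  if (any(total <= 0)) stop("total localization count must be positive")
  if (any(in_speck > total)) stop("in-speck count exceeds total")
  in_speck / total
}

#' Day-to-day calibration of intensity and localization counts
#'
#' Corrects experimental day effects in two sequential steps, each rescaling
#' a per-day least-squares slope to the maximum slope over days: first the
#' widefield intensity per cell area, then the number of localizations per
#' (calibrated) widefield intensity. Only slopes are rescaled; intercepts
#' are untouched. Values are calibrated in place, so the operation is
#' idempotent. Days with fewer than 2 cells or a non-positive/undefined
#' slope are dropped with a warning.
#'
#' @param records Data frame with columns `day_id`, `cell_area_um2`,
#'   `wf_intensity`, plus the localization-count columns in `count_cols`.
#' @param count_cols Localization-count columns scaled by the second
#'   calibration step (those present are used).
#' @return `records` with calibrated `wf_intensity` and count columns, and
#'   added columns `day_scale_intensity`, `day_scale_locs`.
#' @export
day_calibrate <- function(records,
                          count_cols = c("n_locs_total", "n_locs_speck",
                                         "n_locs_cyto")) {
  stopifnot(all(c("day_id", "cell_area_um2", "wf_intensity") %in%
                  names(records)))
  count_cols <- intersect(count_cols, names(records))
  if (!length(count_cols)) stop("no localization-count columns found")
  day_slope <- function(xcol, ycol) {
    vapply(split(records, records$day_id), function(d) {
      if (nrow(d) < 2L) return(NA_real_)
      x <- d[[xcol]]
      if (stats::var(x) == 0) return(NA_real_)
      stats::cov(x, d[[ycol]]) / stats::var(x)
    }, numeric(1))
  }
  apply_step <- function(slopes, cols) {
    bad <- names(slopes)[!is.finite(slopes) | slopes <= 0]
    if (length(bad)) {
      warning("calibration failed for day(s) ", paste(bad, collapse = ", "),
              "; excluded")
      records <<- records[!records$day_id %in% bad, , drop = FALSE]
      slopes <- slopes[!names(slopes) %in% bad]
    }
    if (!length(slopes)) stop("no day with a valid calibration slope")
    scale <- max(slopes) / slopes
    sc <- scale[as.character(records$day_id)]
    for (col in cols) records[[col]] <<- records[[col]] * sc
    unname(sc)
  }
  sc1 <- apply_step(day_slope("cell_area_um2", "wf_intensity"),
                    "wf_intensity")
  sc2 <- apply_step(day_slope("wf_intensity", count_cols[[1L]]), count_cols)
  records$day_scale_intensity <- sc1
  records$day_scale_locs <- sc2
  records
}

#' Remove the cell-area dependence of a per-cell quantity
#'
#' Fits a least-squares line of the values against cell area and subtracts
#' `slope * area` from each value, leaving the intercept plus residual; the
#' normalized values have zero least-squares slope against area.
#'
#' @param values Numeric per-cell values (e.g. speck Rg in nm).
#' @param cell_areas_um2 Positive cell areas; n >= 3.
#' @return Normalized values, with the removed `slope` as an attribute.
#' @export
normalize_by_cell_area <- function(values, cell_areas_um2) {
  if (length(values) < 3L) stop("need at least 3 cells")
  if (length(values) != length(cell_areas_um2))
    stop("values and areas differ in length")
  if (any(cell_areas_um2 <= 0)) stop("cell areas must be positive")
  slope <- stats::cov(cell_areas_um2, values) / stats::var(cell_areas_um2)
  out <- values - slope * cell_areas_um2
  attr(out, "slope") <- slope
  out
}

#' Correlation coefficient between per-cell quantities
#'
#' @param x,y Numeric vectors, n >= 3, non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y, method = method)
}

#' Align specks by center of mass, bin by pseudo-time, and sum
#'
#' Translates every speck so that the center of mass (unweighted mean x, y)
#' of its reference-channel localizations sits at the origin; in dual-color
#' data both channels are shifted by the reference-channel shift. Specks are
#' grouped into pseudo-time bins (equal-count tertiles by default), rendered
#' on a common centered grid, and summed per bin. Horizontal and vertical
#' cross-section profiles through the origin are averaged over a band
#' `band_px` rendered pixels wide (default 9).
#'
#' @param speck_tables List of [loc_table]s, one per speck (>= 1
#'   localization each; may contain several channels).
#' @param pseudo_times Numeric vector in `[0, 1]`, one per speck.
#' @param n_bins Number of pseudo-time bins (default 3).
#' @param pixel_size_nm,blur_sigma_px Rendering parameters (defaults 10.6
#'   nm, 1 px).
#' @param reference_channel Channel whose center of mass defines the shift;
#'   `NULL` uses all localizations of the speck.
#' @param half_size_nm Half-extent of the common render grid (default 1000).
#' @param binning `"equal_count"` (default) or `"equal_width"`.
#' @param band_px Cross-section band width in rendered pixels (default 9).
#' @return Object of class `aligned_stack`: list with `bins` (data.frame
#'   `bin`, `lo`, `hi`, `n`), `bin_of` (bin index per speck), `images`
#'   (per bin: named list of `rendered_image` per channel), `profiles`
#'   (per bin and channel: `horizontal` and `vertical` data.frames of band
#'   means), and `shifted` (the aligned localization tables).
#' @export
align_and_sum <- function(speck_tables, pseudo_times, n_bins = 3L,
                          pixel_size_nm = 10.6, blur_sigma_px = 1,
                          reference_channel = NULL, half_size_nm = 1000,
                          binning = c("equal_count", "equal_width"),
                          band_px = 9L) {
  binning <- match.arg(binning)
  stopifnot(length(speck_tables) == length(pseudo_times), n_bins >= 1L)
  if (any(pseudo_times < 0 | pseudo_times > 1))
    stop("pseudo-times must lie in [0, 1]")
  if (any(vapply(speck_tables, nrow, integer(1)) < 1L))
    stop("every speck needs at least one localization")
  shifted <- lapply(speck_tables, function(tb) {
    ref <- if (is.null(reference_channel)) tb else
      tb[tb$channel == reference_channel, , drop = FALSE]
    if (!nrow(ref)) ref <- tb
    tb$x <- tb$x - mean(ref$x)
    tb$y <- tb$y - mean(ref$y)
    tb
  })
  edges <- if (binning == "equal_width") {
    seq(0, 1, length.out = n_bins + 1L)
  } else {
    unique(stats::quantile(pseudo_times, seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE, type = 7))
  }
  edges[1L] <- 0; edges[length(edges)] <- 1
  edges <- unique(edges)
  if (length(edges) < 2L) edges <- c(0, 1)
  bin_of <- pmin(pmax(findInterval(pseudo_times, edges,
                                   rightmost.closed = TRUE), 1L),
                 length(edges) - 1L)
  bounds <- list(xlim = c(-half_size_nm, half_size_nm),
                 ylim = c(-half_size_nm, half_size_nm))
  channels <- unique(unlist(lapply(shifted, function(tb) unique(tb$channel))))
  images <- vector("list", length(edges) - 1L)
  profiles <- vector("list", length(edges) - 1L)
  for (b in seq_along(images)) {
    members <- shifted[bin_of == b]
    if (!length(members)) {
      warning("pseudo-time bin ", b, " is empty")
      members <- list(loc_table())
    }
    pooled <- do.call(rbind, members)
    images[[b]] <- lapply(stats::setNames(channels, channels), function(ch) {
      render(pooled[pooled$channel == ch, , drop = FALSE],
             pixel_size_nm, blur_sigma_px, bounds)
    })
    profiles[[b]] <- lapply(images[[b]], band_profiles, band_px = band_px)
  }
  structure(list(
    bins = data.frame(bin = seq_along(images),
                      lo = edges[-length(edges)], hi = edges[-1L],
                      n = tabulate(bin_of, length(images))),
    bin_of = bin_of, images = images, profiles = profiles,
    shifted = shifted, binning = binning,
    reference_channel = reference_channel),
    class = "aligned_stack")
}

# Mean horizontal/vertical cross-sections over a band of rows/columns
# centered on the origin pixel of a centered rendered image.
band_profiles <- function(image, band_px = 9L) {
  px <- image$pixels
  half <- (band_px - 1L) %/% 2L
  orow <- floor((0 - image$origin[2L]) / image$pixel_size_nm) + 1L
  ocol <- floor((0 - image$origin[1L]) / image$pixel_size_nm) + 1L
  rows <- pmin(pmax(orow + (-half:half), 1L), nrow(px))
  cols <- pmin(pmax(ocol + (-half:half), 1L), ncol(px))
  xs <- image$origin[1L] + (seq_len(ncol(px)) - 0.5) * image$pixel_size_nm
  ys <- image$origin[2L] + (seq_len(nrow(px)) - 0.5) * image$pixel_size_nm
  list(horizontal = data.frame(pos_nm = xs,
                               value = colMeans(px[rows, , drop = FALSE])),
       vertical = data.frame(pos_nm = ys,
                             value = rowMeans(px[, cols, drop = FALSE])))
}

#' @export
print.aligned_stack <- function(x, ...) {
  cat(sprintf("<aligned_stack> %d bins (%s): %s specks\n",
              nrow(x$bins), x$binning,
              paste(x$bins$n, collapse = " / ")))
  invisible(x)
}
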