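# Ripley's K / L(r) - r second-order statistics with a randomization control.

as_rect_roi <- function(roi) {
  if (is.list(roi) && !is.null(roi$xlim) && !is.null(roi$ylim)) {
    return(list(xlim = sort(as.numeric(roi$xlim)),
                ylim = sort(as.numeric(roi$ylim))))
  }
  if (inherits(roi, "region")) {
    v <- roi$vertices
    xl <- range(v[, 1L]); yl <- range(v[, 2L])
    a <- polygon_area_um2(v) * 1e6
    if (abs(a - diff(xl) * diff(yl)) > 1e-6 * diff(xl) * diff(yl))
      stop("Ripley ROI must be rectangular")
    return(list(xlim = xl, ylim = yl))
  }
  stop("roi must be a rectangular region or a list(xlim, ylim)")
}

#' Ripley's L(r) - r for a rectangular ROI
#'
#' Computes \eqn{K(r) = |A| / (n (n-1)) \sum_{i \ne j} w_{ij} 1[d_{ij} \le r]}
#' and reports \eqn{L(r) - r} with \eqn{L(r) = \sqrt{K(r)/\pi}}, which is 0
#' under complete spatial randomness and positive at scales of clustering.
#' `edge_mode = "none"` uses unit weights (the randomization control shares
#' any edge bias); `"translation"` applies the translation correction
#' \eqn{w_{ij} = ab / ((a - |dx|)(b - |dy|))}, which is unbiased for
#' rectangles.
#'
#' @param table A [loc_table] whose localizations lie in the ROI (points
#'   outside are discarded).
#' @param roi Rectangular ROI: `list(xlim, ylim)` in nm, or a rectangular
#'   `region`.
#' @param radii Increasing positive radii in nm; the largest must not exceed
#'   half the shorter ROI side.
#' @param edge_mode `"none"` (default) or `"translation"`.
#' @return Object of class `lr_curve`: data.frame columns `r`, `k`,
#'   `l_minus_r`; attributes `n`, `area_um2`, `max_l_minus_r`, `edge_mode`.
#' @export
ripley_l <- function(table, roi, radii, edge_mode = c("none", "translation")) {
  edge_mode <- match.arg(edge_mode)
  roi <- as_rect_roi(roi)
  radii <- as.numeric(radii)
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("radii must be positive and strictly increasing")
  a <- diff(roi$xlim); b <- diff(roi$ylim)
  if (max(radii) > min(a, b) / 2)
    stop("largest radius exceeds half the shorter ROI side")
  keep <- table$x >= roi$xlim[1L] & table$x <= roi$xlim[2L] &
    table$y >= roi$ylim[1L] & table$y <= roi$ylim[2L]
  x <- table$x[keep]; y <- table$y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 points in the ROI")
  A <- a * b
  ut <- upper.tri(matrix(0, n, n))
  dx <- abs(outer(x, x, `-`))[ut]
  dy <- abs(outer(y, y, `-`))[ut]
  d <- sqrt(dx^2 + dy^2)
  w <- if (edge_mode == "translation") A / ((a - dx) * (b - dy)) else
    rep(1, length(d))
  ord <- order(d)
  d <- d[ord]; w <- w[ord]
  cw <- cumsum(w)
  idx <- findInterval(radii, d)
  sums <- ifelse(idx > 0L, cw[pmax(idx, 1L)], 0)
  K <- A / (n * (n - 1)) * 2 * sums          # pairs counted once, doubled
  L <- sqrt(K / pi)
  out <- data.frame(r = radii, k = K, l_minus_r = L - radii)
  class(out) <- c("lr_curve", "data.frame")
  attr(out, "n") <- n
  attr(out, "area_um2") <- A / 1e6
  attr(out, "max_l_minus_r") <- max(out$l_minus_r)
  attr(out, "edge_mode") <- edge_mode
  out
}

#' Ripley randomization control
#'
#' Re-draws the same number of points uniformly in the ROI `n_rand` times
#' (complete spatial randomness at the observed density) and compares the
#' observed max of L(r) - r with the randomized ensemble, mirroring the
#' randomized-position control used for cytoplasmic ASC.
#'
#' @inheritParams ripley_l
#' @param n_rand Number of randomizations (>= 1).
#' @param seed Integer seed for the randomization draws.
#' @return List with `observed` (an `lr_curve`), `observed_max`,
#'   `randomized_max` (length `n_rand`), `randomized_mean_curve`
#'   (data.frame `r`, `l_minus_r`), and `exceeds` (fraction of
#'   randomizations whose max is below the observed max).
#' @export
ripley_randomization <- function(table, roi, radii, n_rand = 100L,
                                 seed = 1L,
                                 edge_mode = c("none", "translation")) {
  edge_mode <- match.arg(edge_mode)
  if (n_rand < 1L) stop("n_rand must be at least 1")
  roi <- as_rect_roi(roi)
  obs <- ripley_l(table, roi, radii, edge_mode)
  n <- attr(obs, "n")
  set.seed(as.integer(seed))
  rand_curves <- matrix(0, length(radii), n_rand)
  rand_max <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    tb <- loc_table(stats::runif(n, roi$xlim[1L], roi$xlim[2L]),
                    stats::runif(n, roi$ylim[1L], roi$ylim[2L]))
    cr <- ripley_l(tb, roi, radii, edge_mode)
    rand_curves[, i] <- cr$l_minus_r
    rand_max[i] <- attr(cr, "max_l_minus_r")
  }
  list(observed = obs,
       observed_max = attr(obs, "max_l_minus_r"),
       randomized_max = rand_max,
       randomized_mean_curve = data.frame(r = radii,
                                          l_minus_r = rowMeans(rand_curves)),
       exceeds = mean(rand_max < attr(obs, "max_l_minus_r")))
}

#' Tile square ROIs over the cytoplasm
#'
#' Draws square ROIs of a fixed size whose corners all lie inside the cell
#' polygon and outside every speck polygon, for multi-ROI Ripley analyses.
#'
#' @param cell_region Closed cell `region`.
#' @param speck_regions Optional `region_set` (or single region) to avoid.
#' @param size_nm ROI edge length in nm (default 2000).
#' @param n Number of ROIs requested (default 10 per cell).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget.
#' @return List of `list(xlim, ylim)` ROIs (possibly fewer than `n`).
#' @export
ripley_rois <- function(cell_region, speck_regions = NULL, size_nm = 2000,
                        n = 10L, seed = 1L, max_tries = 200L * n) {
  set.seed(as.integer(seed))
  v <- cell_region$vertices
  if (inherits(speck_regions, "region")) speck_regions <- region_set(list(speck_regions))
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  rois <- list()
  tries <- 0L
  while (length(rois) < n && tries < max_tries) {
    tries <- tries + 1L
    cx <- stats::runif(1, xr[1L], xr[2L] - size_nm)
    cy <- stats::runif(1, yr[1L], yr[2L] - size_nm)
    px <- c(cx, cx + size_nm, cx + size_nm, cx, cx + size_nm / 2)
    py <- c(cy, cy, cy + size_nm, cy + size_nm, cy + size_nm / 2)
    if (!all(point_in_polygon(px, py, v))) next
    bad <- FALSE
    if (!is.null(speck_regions)) {
      for (sp in speck_regions) {
        if (any(point_in_polygon(px, py, sp$vertices))) { bad <- TRUE; break }
      }
    }
    if (bad) next
    rois[[length(rois) + 1L]] <- list(xlim = c(cx, cx + size_nm),
                                      ylim = c(cy, cy + size_nm))
  }
  rois
}
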