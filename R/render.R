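#' Render localizations into a super-resolution image
#'
#' Builds a 2D histogram of localization positions at the requested pixel
#' size and convolves it with an isotropic Gaussian. The defaults (10.6 nm
#' pixels, 1 px blur) correspond to 10x-magnified reconstructions of data
#' acquired at a 106 nm camera pixel. Pixel (i, j) covers the half-open
#' interval [x0 + (j-1)*px, x0 + j*px) x [y0 + (i-1)*px, y0 + i*px); the
#' kernel is normalized so blur conserves total intensity up to boundary
#' truncation.
#'
#' @param table A [loc_table].
#' @param pixel_size_nm Pixel edge in nm (> 0, default 10.6).
#' @param blur_sigma_px Gaussian blur sigma in pixels (>= 0, default 1).
#' @param bounds List with `xlim`, `ylim` (nm). Defaults to the data range
#'   padded by 5 blurred pixels. Localizations outside the bounds are
#'   dropped.
#' @return Object of class `rendered_image`: list with `pixels` (matrix,
#'   rows = y), `pixel_size_nm`, `origin` (nm) and `n_rendered`.
#' @export
render <- function(table, pixel_size_nm = 10.6, blur_sigma_px = 1,
                   bounds = NULL) {
  stopifnot(pixel_size_nm > 0, blur_sigma_px >= 0)
  x <- table$x; y <- table$y
  if (is.null(bounds)) {
    if (!length(x)) stop("empty bounds: no localizations and no bounds given")
    pad <- (5 + blur_sigma_px) * pixel_size_nm
    bounds <- list(xlim = range(x) + c(-pad, pad),
                   ylim = range(y) + c(-pad, pad))
  }
  if (diff(bounds$xlim) <= 0 || diff(bounds$ylim) <= 0)
    stop("empty bounds")
  nx <- max(1L, ceiling(diff(bounds$xlim) / pixel_size_nm))
  ny <- max(1L, ceiling(diff(bounds$ylim) / pixel_size_nm))
  ix <- floor((x - bounds$xlim[1L]) / pixel_size_nm) + 1L
  iy <- floor((y - bounds$ylim[1L]) / pixel_size_nm) + 1L
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  ix <- ix[keep]; iy <- iy[keep]
  img <- matrix(0, ny, nx)
  if (length(ix)) {
    counts <- table(factor(iy + (ix - 1L) * ny, levels = seq_len(ny * nx)))
    img[] <- as.numeric(counts)
  }
  if (blur_sigma_px > 0) img <- gaussian_blur(img, blur_sigma_px)
  structure(list(pixels = img, pixel_size_nm = pixel_size_nm,
                 origin = c(bounds$xlim[1L], bounds$ylim[1L]),
                 n_rendered = sum(keep)),
            class = "rendered_image")
}

# Separable Gaussian convolution, zero padding, kernel normalized to sum 1.
gaussian_blur <- function(img, sigma_px) {
  r <- max(1L, ceiling(6 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(m, k) {
    # convolve each column of m with k (zero padded)
    n <- nrow(m); r <- (length(k) - 1L) / 2L
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      w <- k[o + r + 1L]
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img, k)), k))
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d px @ %.3g nm, sum = %.4g (%d rendered)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              sum(x$pixels), x$n_rendered))
  invisible(x)
}

#' Write a rendered image as 32-bit float TIFF
#' @param image A `rendered_image`.
#' @param path Output path.
#' @export
write_rendered_tiff <- function(image, path) {
  px <- image$pixels
  tiff::writeTIFF(px / max(max(px), .Machine$double.eps), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a (single-plane) widefield TIFF image as a count matrix
#' @param path TIFF path.
#' @return Numeric matrix of pixel values (as stored).
#' @export
read_widefield_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Background-corrected integrated widefield intensity
#'
#' Sums pixel counts over a cell region after subtracting the mean count of a
#' background region placed in an area free of cellular signal. Region
#' membership is evaluated at pixel centers.
#'
#' @param image Numeric matrix of pixel counts (rows = y).
#' @param cell_region,background_region Closed `region`s with vertices in nm.
#' @param pixel_size_nm Size of an image pixel in nm (default 106, the
#'   camera pixel of a 10x-reconstruction source image).
#' @return Background-corrected integrated intensity (counts). Negative
#'   totals are returned with a warning.
#' @export
widefield_intensity <- function(image, cell_region, background_region,
                                pixel_size_nm = 106) {
  stopifnot(is.matrix(image))
  mask <- function(reg) {
    v <- reg$vertices
    jx <- seq_len(ncol(image)); iy <- seq_len(nrow(image))
    cx <- (jx - 0.5) * pixel_size_nm
    cy <- (iy - 0.5) * pixel_size_nm
    xs <- rep(cx, each = length(cy)); ys <- rep(cy, times = length(cx))
    matrix(point_in_polygon(xs, ys, v), nrow(image), ncol(image))
  }
  bg <- mask(background_region)
  if (!any(bg)) stop("background region contains no pixels")
  cm <- mask(cell_region)
  if (!any(cm)) stop("cell region contains no pixels")
  bg_mean <- mean(image[bg])
  total <- sum(image[cm] - bg_mean)
  if (total < 0) warning("background-corrected intensity is negative")
  total
}
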