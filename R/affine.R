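#' 2D affine transform
#'
#' Maps a point p to `A %*% p + b`. Used for registering the second imaging
#' channel onto the reference channel via fiducial bead positions.
#'
#' @param linear 2x2 matrix (must be invertible, |det| > 1e-12).
#' @param offset Length-2 translation in nm.
#' @return Object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2L, 2L)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 2L)
  if (abs(det(linear)) <= 1e-12) stop("affine linear part is singular")
  structure(list(linear = linear, offset = offset), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>\n  linear:\n")
  print(x$linear)
  cat(sprintf("  offset: (%.6g, %.6g) nm\n", x$offset[1], x$offset[2]))
  invisible(x)
}

#' Least-squares affine transform from matched fiducial pairs
#'
#' Estimates the affine transform mapping source points (e.g. TetraSpeck bead
#' positions in the far-red channel) onto target points (reference channel)
#' by minimizing the sum of squared residuals.
#'
#' @param source_points,target_points Two-column (x, y) matrices of matched
#'   coordinates in nm; at least 3 non-collinear pairs.
#' @return An [affine2d]; attribute `rms_residual_nm` holds the fit residual.
#' @export
estimate_affine <- function(source_points, target_points) {
  S <- as.matrix(source_points); T <- as.matrix(target_points)
  if (nrow(S) != nrow(T)) stop("source and target must have equal length")
  if (nrow(S) < 3L) stop("degenerate geometry: need at least 3 point pairs")
  Sc <- sweep(S, 2L, colMeans(S))
  sv <- svd(Sc, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1))
    stop("degenerate geometry: source points are collinear")
  X <- cbind(1, S)
  beta <- qr.solve(X, T)                 # 3 x 2: offset row + linear rows
  tr <- affine2d(linear = t(beta[2:3, , drop = FALSE]), offset = beta[1L, ])
  fitted <- X %*% beta
  attr(tr, "rms_residual_nm") <- sqrt(mean((T - fitted)^2))
  tr
}

#' Apply an affine transform to a localization table or point matrix
#'
#' Only `x` and `y` are transformed; all other columns are untouched.
#'
#' @param transform An [affine2d].
#' @param table A [loc_table] or two-column matrix.
#' @return Same type as `table`, with mapped coordinates.
#' @export
apply_affine <- function(transform, table) {
  stopifnot(inherits(transform, "affine2d"))
  if (is.matrix(table)) {
    return(sweep(table %*% t(transform$linear), 2L, -transform$offset))
  }
  p <- cbind(table$x, table$y) %*% t(transform$linear)
  table$x <- p[, 1L] + transform$offset[1L]
  table$y <- p[, 2L] + transform$offset[2L]
  table
}

#' Invert an affine transform
#' @param transform An [affine2d].
#' @return The inverse [affine2d].
#' @export
affine_invert <- function(transform) {
  Ainv <- solve(transform$linear)
  affine2d(linear = Ainv, offset = -Ainv %*% transform$offset)
}
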