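# Independent oracles and shared fixtures for the test suite.

# Brute-force DBSCAN: full distance matrix, core points by neighbour count
# (self included), clusters = components grown from core points in index
# order, border points claimed by the first cluster reaching them.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (!n) return(integer(0))
  d <- as.matrix(stats::dist(cbind(x, y)))
  core <- rowSums(d <= eps) >= min_pts
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    q <- i
    while (length(q)) {
      p <- q[[1L]]; q <- q[-1L]
      nb <- which(d[p, ] <= eps & lab == 0L)
      lab[nb] <- cl
      q <- c(q, nb[core[nb]])
    }
  }
  lab
}

# Scalar crossing-number point-in-polygon (independent of the package's
# vectorized implementation). Boundary behaviour unspecified; callers use
# points off the edges.
brute_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((v[i, 2] > y) != (v[j, 2] > y)) {
        xint <- v[j, 1] + (y - v[j, 2]) * (v[i, 1] - v[j, 1]) /
          (v[i, 2] - v[j, 2])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Forward Monte-Carlo oracle for the filament transverse profile: direct 1D
# sampling of the same forward model (uniform cylinder cross-section +
# isotropic label displacement + Gaussian precision), histogram and a
# Gaussian-plus-baseline least-squares fit via optim (independent of the
# pipeline's geometry projection and nlsLM path).
oracle_filament_fwhm <- function(diameter_nm, label_size_nm, sigma_nm,
                                 n = 1e6, bin_width_nm = 5, seed = 1) {
  set.seed(seed)
  v <- (diameter_nm / 2) * sqrt(stats::runif(n)) *
    cos(stats::runif(n, 0, 2 * pi)) +
    label_size_nm * cos(stats::runif(n, 0, 2 * pi)) +
    stats::rnorm(n, 0, sigma_nm)
  lim <- max(abs(v)) + bin_width_nm
  h <- graphics::hist(v, breaks = seq(-lim, lim, by = bin_width_nm),
                      plot = FALSE)
  sse <- function(par) {
    sum((h$counts - (par[1] * exp(-(h$mids - par[2])^2 / (2 * par[3]^2)) +
                       par[4]))^2)
  }
  fit <- stats::optim(c(max(h$counts), 0, stats::sd(v), 0), sse,
                      method = "BFGS")
  2 * sqrt(2 * log(2)) * abs(fit$par[3])
}

# Shared 50-cell stimulated scene + per-cell records (generated once per
# test run; several test files reuse it).
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    .scene_cache$scene <- simulate_scene(scene_params(n_cells = 50), seed = 7)
  }
  .scene_cache$scene
}

cached_records <- function() {
  if (is.null(.scene_cache$records)) {
    sc <- cached_scene()
    .scene_cache$records <- cell_records(
      sc$locs, sc$regions, wf = sc$truth$cells[, c("cell_id", "wf_intensity")])
  }
  .scene_cache$records
}
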