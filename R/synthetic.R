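# Ground-truth scene generator: cells with cytosolic ASC oligomers/monomers,
# one perinuclear speck per stimulated cell (dense core + protruding
# filaments), two labeling probes with size, affinity and steric-exclusion
# effects, blinking, localization noise and multiplicative day effects.

#' Scene parameters for the synthetic localization generator
#'
#' Defaults encode the study conditions the analysis assumes: ASC surface
#' concentration constant across cells (content proportional to cell area),
#' a recruited fraction per stimulated cell of 0.2--0.95, a dense speck core
#' whose radius scales with the square root of the cell area, at most ~10
#' filaments of up to 500 nm length and 15 nm true diameter, ~12 nm
#' cytosolic oligomer disks, and three measurement days with multiplicative
#' intensity and localization-efficiency effects. The core radial density
#' follows \eqn{\rho(r) \propto (1 + r/r_0)^{-\alpha}} truncated at the core
#' radius; the default \eqn{\alpha = 2} gives the dense-core /
#' less-dense-periphery contrast that keeps both probes' density gates
#' strictly inside the core across the whole recruited-fraction range.
#'
#' @param n_cells Number of cells.
#' @param cell_radius_nm `c(mean, sd)` of the Gaussian cell radius (nm),
#'   truncated at 3000 nm.
#' @param concentration_per_um2 Ground-truth emitter concentration
#'   (emitters per um^2 of cell area), constant across cells.
#' @param f_range Recruited-fraction range; `c(0, 0)` simulates
#'   unstimulated cells (no speck).
#' @param core_radius_coef Core radius = coef * sqrt(cell area in nm^2).
#' @param core_profile_alpha,core_profile_r0_nm Core radial profile
#'   exponent and scale.
#' @param n_filaments_range Integer range of filaments per speck.
#' @param filament_length_range_nm Uniform filament length range.
#' @param filament_diameter_nm True filament diameter (default 15).
#' @param filament_linear_density_per_nm Emitters per nm of filament length.
#' @param filament_max_share Cap on the fraction of speck emitters placed in
#'   filaments.
#' @param filament_local_density_per_um2,oligomer_local_density_per_um2,monomer_local_density_per_um2
#'   Coarse-grained local ground-truth densities assigned to these
#'   structural roles for the probes' density gates.
#' @param oligomer_diameter_nm Cytosolic oligomer disk diameter (default 12).
#' @param oligomer_count_range Oligomers per cell (uniform integer range).
#' @param oligomer_size_mean Mean oligomer emitter count (1 + Poisson).
#' @param blink_mean Mean localizations per label (geometric, support >= 1).
#' @param days Data frame `day_id`, `intensity_scale`, `loc_efficiency`
#'   describing multiplicative day effects; cells are assigned cyclically.
#' @param wf_counts_per_emitter,wf_noise_cv Widefield intensity per emitter
#'   and its lognormal noise CV.
#' @return List of class `scene_params`.
#' @export
scene_params <- function(n_cells = 50L,
                         cell_radius_nm = c(7000, 700),
                         concentration_per_um2 = 25,
                         f_range = c(0.2, 0.95),
                         core_radius_coef = 0.032,
                         core_profile_alpha = 2,
                         core_profile_r0_nm = 150,
                         n_filaments_range = c(0L, 10L),
                         filament_length_range_nm = c(100, 500),
                         filament_diameter_nm = 15,
                         filament_linear_density_per_nm = 0.3,
                         filament_max_share = 0.3,
                         filament_local_density_per_um2 = 2000,
                         oligomer_diameter_nm = 12,
                         oligomer_count_range = c(30L, 90L),
                         oligomer_size_mean = 4,
                         oligomer_local_density_per_um2 = 600,
                         monomer_local_density_per_um2 = 10,
                         blink_mean = 5,
                         days = data.frame(
                           day_id = 1:3,
                           intensity_scale = c(1, 0.8, 0.65),
                           loc_efficiency = c(1, 0.85, 0.7)),
                         wf_counts_per_emitter = 50,
                         wf_noise_cv = 0.05) {
  p <- as.list(environment())
  stopifnot(n_cells >= 1L, all(cell_radius_nm > 0),
            concentration_per_um2 > 0,
            f_range[1L] >= 0, f_range[2L] <= 1, f_range[1L] <= f_range[2L],
            core_radius_coef > 0, core_profile_r0_nm > 0,
            filament_diameter_nm > 0, filament_length_range_nm[1L] > 0,
            oligomer_diameter_nm > 0, blink_mean >= 1,
            all(days$loc_efficiency > 0), all(days$intensity_scale > 0))
  class(p) <- "scene_params"
  p
}

#' Labeling-probe model
#'
#' A probe is characterized by its physical size (label displacement
#' epsilon), a two-level binding-probability gate on the local ground-truth
#' emitter density (steric exclusion / affinity wash-out), a geometric blink
#' count, and the channel localization precision.
#'
#' @param name Probe name.
#' @param channel Channel identifier written into the localization table.
#' @param label_size_nm Label displacement epsilon >= 0 (nm); the label
#'   binds at the emitter plus a uniformly random 2D direction times epsilon.
#' @param p_low,p_high Binding probabilities below / at-or-above the density
#'   threshold.
#' @param density_threshold_per_um2 Local-density threshold separating the
#'   two regimes.
#' @param sigma_xy_nm Lateral localization precision (> 0).
#' @param blink_mean Mean localizations per bound label (geometric,
#'   support >= 1).
#' @return List of class `probe_model`.
#' @export
probe_model <- function(name, channel, label_size_nm, p_low, p_high,
                        density_threshold_per_um2, sigma_xy_nm,
                        blink_mean = 5) {
  stopifnot(label_size_nm >= 0, sigma_xy_nm >= 0, blink_mean >= 1,
            p_low >= 0, p_low <= 1, p_high >= 0, p_high <= 1,
            density_threshold_per_um2 > 0)
  structure(list(name = name, channel = channel,
                 label_size_nm = label_size_nm,
                 p_low = p_low, p_high = p_high,
                 density_threshold_per_um2 = density_threshold_per_um2,
                 sigma_xy_nm = sigma_xy_nm, blink_mean = blink_mean),
            class = "probe_model")
}

#' @describeIn probe_model Primary antibody + secondary F(ab')2 preset:
#'   large label (11 nm), good affinity in low-density regions but sterically
#'   excluded from the dense speck core (`p_high < p_low`), 12 nm precision
#'   (Alexa Fluor 647 channel).
#' @export
probe_antibody <- function() {
  probe_model("antibody", channel = "AF647", label_size_nm = 11,
              p_low = 0.8, p_high = 0.25,
              density_threshold_per_um2 = 12000, sigma_xy_nm = 12)
}

#' @describeIn probe_model Nanobody preset: small label (2 nm) that
#'   penetrates the dense core, but low affinity so it is washed from
#'   low-density regions (`p_low < p_high`), 21 nm precision (DyLight755
#'   channel).
#' @export
probe_nanobody <- function() {
  probe_model("nanobody", channel = "DL755", label_size_nm = 2,
              p_low = 0.2, p_high = 0.9,
              density_threshold_per_um2 = 4000, sigma_xy_nm = 21)
}

# Inverse-CDF sampler for the core radial profile r * (1 + r/r0)^(-alpha)
# on [0, R], on a fixed 2048-point grid (deterministic given the draws).
sample_core_radii <- function(n, R, r0, alpha) {
  if (!n) return(numeric(0))
  grid <- seq(0, R, length.out = 2048L)
  pdf <- grid * (1 + grid / r0)^(-alpha)
  cdf <- cumsum(pdf); cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(cdf, grid, xout = u, yleft = 0, yright = R, ties = "ordered")$y
}

# Normalization of the core profile: amplitude rho0 (emitters / um^2) such
# that the truncated profile integrates to n_core emitters.
core_profile_amplitude <- function(n_core, R, r0, alpha) {
  grid <- seq(0, R, length.out = 2048L)
  integral <- sum(2 * pi * grid * (1 + grid / r0)^(-alpha)) * (grid[2L] - grid[1L])
  n_core / integral * 1e6
}

unit_dirs <- function(n) {
  th <- stats::runif(n, 0, 2 * pi)
  cbind(cos(th), sin(th))
}

# Uniform points in the cytoplasm (inside cell polygon, outside speck disk).
sample_cytoplasm <- function(n, cell_poly, cell_center, bound_radius,
                             speck_center = NULL, speck_radius = 0) {
  out <- matrix(numeric(0), 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    r <- bound_radius * sqrt(stats::runif(m))
    d <- unit_dirs(m)
    pts <- cbind(cell_center[1L] + r * d[, 1L], cell_center[2L] + r * d[, 2L])
    ok <- point_in_polygon(pts[, 1L], pts[, 2L], cell_poly)
    if (!is.null(speck_center)) {
      ok <- ok & ((pts[, 1L] - speck_center[1L])^2 +
                    (pts[, 2L] - speck_center[2L])^2 > speck_radius^2)
    }
    out <- rbind(out, pts[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a full cellular scene with ground truth
#'
#' Generates `n_cells` cells, places ground-truth emitters (speck core,
#' filaments, cytosolic oligomer disks and monomers), labels each emitter
#' per probe with a Bernoulli probability gated on the local ground-truth
#' density, emits a geometric number of localizations per bound label
#' displaced by the label size and blurred by the channel's localization
#' precision, thins localizations by the day's efficiency, and returns the
#' localization table together with matching cell/speck segmentations and
#' the full ground truth. Deterministic given `seed`.
#'
#' @param params A [scene_params].
#' @param probes List of [probe_model]s (default antibody + nanobody).
#' @param seed Integer seed.
#' @return Object of class `smlm_scene`: list with `locs` (a [loc_table]
#'   with `cell_id` column, all channels), `regions` (a [region_set] of cell
#'   and speck polygons), `truth` (list: `cells` data.frame, `emitters`
#'   data.frame, `labels` per-probe per-cell counts), `params`, `probes`,
#'   `seed`.
#' @export
simulate_scene <- function(params = scene_params(),
                           probes = list(probe_antibody(), probe_nanobody()),
                           seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (inherits(probes, "probe_model")) probes <- list(probes)
  set.seed(as.integer(seed))
  p <- params
  n <- p$n_cells
  day_ids <- p$days$day_id[(seq_len(n) - 1L) %% nrow(p$days) + 1L]
  grid_step <- 4 * (p$cell_radius_nm[1L] + 4 * p$cell_radius_nm[2L])
  ncol_grid <- ceiling(sqrt(n))
  cells <- vector("list", n)
  emitters <- vector("list", n)
  regions <- list()
  loc_parts <- list()
  label_counts <- list()
  for (i in seq_len(n)) {
    day <- p$days[p$days$day_id == day_ids[i], ]
    cc <- c(((i - 1L) %% ncol_grid) * grid_step,
            ((i - 1L) %/% ncol_grid) * grid_step) + grid_step / 2
    radius <- max(stats::rnorm(1, p$cell_radius_nm[1L], p$cell_radius_nm[2L]),
                  3000)
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    phase <- stats::runif(1, 0, 2 * pi)
    rr <- radius * (1 + 0.05 * cos(3 * th + phase))
    cell_poly <- cbind(cc[1L] + rr * cos(th), cc[2L] + rr * sin(th))
    area_um2 <- polygon_area_um2(cell_poly)
    E <- stats::rpois(1, p$concentration_per_um2 * area_um2)
    f <- if (p$f_range[2L] > 0)
      stats::runif(1, p$f_range[1L], p$f_range[2L]) else 0
    n_speck <- if (f > 0 && E > 0) stats::rbinom(1, E, f) else 0L
    # --- speck geometry and emitters -----------------------------------
    R_core <- p$core_radius_coef * sqrt(area_um2 * 1e6)
    sp_dir <- unit_dirs(1)
    sp_c <- cc + 0.25 * radius * as.numeric(sp_dir)
    em <- list()
    n_fil <- 0L; fil_lengths <- numeric(0); fil_counts <- integer(0)
    if (n_speck > 0L) {
      n_fil <- sample(seq(p$n_filaments_range[1L], p$n_filaments_range[2L]),
                      1L)
      if (n_fil > 0L) {
        fil_lengths <- stats::runif(n_fil, p$filament_length_range_nm[1L],
                                    p$filament_length_range_nm[2L])
        fil_counts <- round(fil_lengths * p$filament_linear_density_per_nm)
        cap <- floor(p$filament_max_share * n_speck)
        if (sum(fil_counts) > cap && sum(fil_counts) > 0) {
          fil_counts <- floor(fil_counts * cap / sum(fil_counts))
        }
      }
      n_core <- n_speck - sum(fil_counts)
      r_core <- sample_core_radii(n_core, R_core, p$core_profile_r0_nm,
                                  p$core_profile_alpha)
      d_core <- unit_dirs(n_core)
      rho0 <- core_profile_amplitude(n_core, R_core, p$core_profile_r0_nm,
                                     p$core_profile_alpha)
      em$core <- data.frame(
        x = sp_c[1L] + r_core * d_core[, 1L],
        y = sp_c[2L] + r_core * d_core[, 2L],
        role = "core",
        density = rho0 * (1 + r_core / p$core_profile_r0_nm)^(-p$core_profile_alpha))
      fil_geom <- NULL
      if (n_fil > 0L && sum(fil_counts) > 0) {
        ang0 <- stats::runif(n_fil, 0, 2 * pi)
        ang <- ang0 + stats::runif(n_fil, -25, 25) * pi / 180
        fil_geom <- data.frame(
          sx = sp_c[1L] + R_core * cos(ang0),
          sy = sp_c[2L] + R_core * sin(ang0),
          dx = cos(ang), dy = sin(ang), len = fil_lengths)
        fil <- lapply(seq_len(n_fil), function(k) {
          m <- fil_counts[k]
          if (!m) return(NULL)
          g <- fil_geom[k, ]
          nrm <- c(-g$dy, g$dx)
          tt <- stats::runif(m, 0, g$len)
          off <- (p$filament_diameter_nm / 2) * sqrt(stats::runif(m)) *
            cos(stats::runif(m, 0, 2 * pi))
          data.frame(x = g$sx + tt * g$dx + off * nrm[1L],
                     y = g$sy + tt * g$dy + off * nrm[2L],
                     role = "filament",
                     density = p$filament_local_density_per_um2)
        })
        em$filament <- do.call(rbind, fil)
      }
    }
    # --- cytosol -------------------------------------------------------
    C <- E - n_speck
    roi_radius <- R_core +
      (if (length(fil_lengths)) max(fil_lengths) else 0) + 100
    sp_center_arg <- if (n_speck > 0L) sp_c else NULL
    if (C > 0L) {
      n_olig <- sample(seq(p$oligomer_count_range[1L],
                           p$oligomer_count_range[2L]), 1L)
      sizes <- 1L + stats::rpois(n_olig, p$oligomer_size_mean - 1)
      keep <- cumsum(sizes) <= C
      sizes <- sizes[keep]
      if (length(sizes)) {
        centers <- sample_cytoplasm(length(sizes), cell_poly, cc,
                                    1.1 * radius, sp_center_arg, roi_radius)
        rdisk <- (p$oligomer_diameter_nm / 2) * sqrt(stats::runif(sum(sizes)))
        ddisk <- unit_dirs(sum(sizes))
        idx <- rep(seq_along(sizes), sizes)
        em$oligomer <- data.frame(
          x = centers[idx, 1L] + rdisk * ddisk[, 1L],
          y = centers[idx, 2L] + rdisk * ddisk[, 2L],
          role = "oligomer", density = p$oligomer_local_density_per_um2)
      }
      M <- C - sum(sizes)
      if (M > 0L) {
        mono <- sample_cytoplasm(M, cell_poly, cc, 1.1 * radius,
                                 sp_center_arg, roi_radius)
        em$monomer <- data.frame(x = mono[, 1L], y = mono[, 2L],
                                 role = "monomer",
                                 density = p$monomer_local_density_per_um2)
      }
    }
    em_df <- do.call(rbind, em)
    if (is.null(em_df))
      em_df <- data.frame(x = numeric(), y = numeric(),
                          role = character(), density = numeric())
    em_df$cell_id <- i
    emitters[[i]] <- em_df
    # --- labeling, blinking, localization noise per probe --------------
    for (pr in probes) {
      ne <- nrow(em_df)
      if (ne) {
        pbind <- ifelse(em_df$density >= pr$density_threshold_per_um2,
                        pr$p_high, pr$p_low)
        lab <- stats::runif(ne) < pbind
        nl <- sum(lab)
      } else nl <- 0L
      if (nl) {
        dirs <- unit_dirs(nl)
        lx <- em_df$x[lab] + pr$label_size_nm * dirs[, 1L]
        ly <- em_df$y[lab] + pr$label_size_nm * dirs[, 2L]
        blinks <- stats::rgeom(nl, 1 / pr$blink_mean) + 1L
        li <- rep(seq_len(nl), blinks)
        nb <- length(li)
        locx <- lx[li] + stats::rnorm(nb, 0, pr$sigma_xy_nm)
        locy <- ly[li] + stats::rnorm(nb, 0, pr$sigma_xy_nm)
        keep <- stats::runif(nb) < day$loc_efficiency
        tb <- loc_table(locx[keep], locy[keep],
                        frame = seq_len(sum(keep)) - 1L,
                        channel = pr$channel)
        tb$cell_id <- i
        loc_parts[[length(loc_parts) + 1L]] <- tb
        label_counts[[length(label_counts) + 1L]] <-
          data.frame(cell_id = i, channel = pr$channel, probe = pr$name,
                     n_labels = nl, n_locs = sum(keep))
      } else {
        label_counts[[length(label_counts) + 1L]] <-
          data.frame(cell_id = i, channel = pr$channel, probe = pr$name,
                     n_labels = 0L, n_locs = 0L)
      }
    }
    wf <- p$wf_counts_per_emitter * E * day$intensity_scale *
      exp(stats::rnorm(1, 0, p$wf_noise_cv))
    regions[[length(regions) + 1L]] <-
      region("cell", cell_poly, cell_id = i, day_id = day_ids[i])
    if (n_speck > 0L) {
      # tight "manual" segmentation: convex hull of the core disk plus the
      # filament tips (100 nm margin), not a bounding circle
      margin <- 100
      th32 <- seq(0, 2 * pi, length.out = 33L)[-33L]
      hull_pts <- cbind(sp_c[1L] + (R_core + margin) * cos(th32),
                        sp_c[2L] + (R_core + margin) * sin(th32))
      if (!is.null(fil_geom)) {
        half_w <- p$filament_diameter_nm / 2 + margin
        ex <- fil_geom$sx + (fil_geom$len + margin) * fil_geom$dx
        ey <- fil_geom$sy + (fil_geom$len + margin) * fil_geom$dy
        hull_pts <- rbind(hull_pts,
                          cbind(ex - fil_geom$dy * half_w,
                                ey + fil_geom$dx * half_w),
                          cbind(ex + fil_geom$dy * half_w,
                                ey - fil_geom$dx * half_w))
      }
      hull <- grDevices::chull(hull_pts)
      regions[[length(regions) + 1L]] <-
        region("speck", hull_pts[hull, , drop = FALSE],
               cell_id = i, day_id = day_ids[i])
    }
    cells[[i]] <- data.frame(
      cell_id = i, day_id = day_ids[i], cell_area_um2 = area_um2,
      cell_radius_nm = radius, cell_cx = cc[1L], cell_cy = cc[2L],
      f = f, n_emitters = E, n_speck_emitters = n_speck,
      n_filaments = n_fil, n_filament_emitters = sum(fil_counts),
      core_radius_nm = R_core, speck_cx = sp_c[1L], speck_cy = sp_c[2L],
      speck_roi_radius_nm = roi_radius, wf_intensity = wf)
  }
  locs <- do.call(rbind, loc_parts)
  if (is.null(locs)) locs <- { t0 <- loc_table(); t0$cell_id <- integer(0); t0 }
  class(locs) <- c("loc_table", "data.frame")
  structure(list(
    locs = locs,
    regions = region_set(regions),
    truth = list(cells = do.call(rbind, cells),
                 emitters = do.call(rbind, emitters),
                 labels = do.call(rbind, label_counts)),
    params = p, probes = probes, seed = seed),
    class = "smlm_scene")
}

#' @export
print.smlm_scene <- function(x, ...) {
  cat(sprintf("<smlm_scene> %d cells, %d localizations (%s), seed %s\n",
              nrow(x$truth$cells), nrow(x$locs),
              paste(unique(x$locs$channel), collapse = " + "),
              format(x$seed)))
  invisible(x)
}

#' Simulate an isolated filament phantom
#'
#' Labels are bound to emitter positions drawn uniformly in a cylinder of
#' the stated diameter and length (axis along x, starting at the origin),
#' displaced by the label size in a uniformly random 2D direction, and each
#' produces one localization blurred by the localization precision.
#' Deterministic given `seed`.
#'
#' @param true_diameter_nm Cylinder diameter (>= 0; 0 collapses to a line).
#' @param length_nm Cylinder length (> 0).
#' @param label_size_nm Label displacement epsilon (>= 0).
#' @param sigma_nm Localization precision (>= 0).
#' @param n_labels Number of labels (> 0).
#' @param seed Integer seed.
#' @return A [loc_table]; attribute `backbone` holds the true axis
#'   polyline.
#' @export
simulate_filament_phantom <- function(true_diameter_nm, length_nm,
                                      label_size_nm, sigma_nm, n_labels,
                                      seed) {
  stopifnot(true_diameter_nm >= 0, length_nm > 0, label_size_nm >= 0,
            sigma_nm >= 0, n_labels > 0)
  set.seed(as.integer(seed))
  tt <- stats::runif(n_labels, 0, length_nm)
  off <- (true_diameter_nm / 2) * sqrt(stats::runif(n_labels)) *
    cos(stats::runif(n_labels, 0, 2 * pi))
  dirs <- unit_dirs(n_labels)
  x <- tt + label_size_nm * dirs[, 1L] + stats::rnorm(n_labels, 0, sigma_nm)
  y <- off + label_size_nm * dirs[, 2L] + stats::rnorm(n_labels, 0, sigma_nm)
  tb <- loc_table(x, y, frame = seq_len(n_labels) - 1L, channel = "AF647")
  attr(tb, "backbone") <- rbind(c(0, 0), c(length_nm, 0))
  tb
}
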