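# Whole-scene pipeline: assemble per-cell records from a localization table
# and segmentations, the way the per-cell quantities feeding the pseudo-time
# analysis are tabulated.

#' Build per-cell records from localizations and segmentations
#'
#' For every `cell` region: counts reference-channel localizations in the
#' cell and in its speck segment, derives the pseudo-time (in-speck /
#' total), computes speck morphometrics on the in-speck localizations, and
#' (optionally) runs the DBSCAN cluster analysis on the cytoplasm (cell
#' minus speck).
#'
#' @param locs A [loc_table] covering all cells (any number of channels).
#' @param regions A [region_set] with `cell` polygons (carrying `cell_id`,
#'   `day_id`) and optional matching `speck` polygons.
#' @param wf Optional data.frame `cell_id`, `wf_intensity` of
#'   background-corrected widefield intensities.
#' @param channel Reference channel used for counts and metrics (default
#'   `"AF647"`).
#' @param cluster Run [dbscan_clusters] on each cytoplasm (default TRUE).
#' @param eps_nm,min_pts,max_cluster_size DBSCAN parameters.
#' @return Data frame of class `cell_records`, one row per cell: `cell_id`,
#'   `day_id`, `cell_area_um2`, `wf_intensity`, `n_locs_total`,
#'   `n_locs_speck`, `n_locs_cyto`, `pseudo_time`, `speck_area_um2`,
#'   `speck_rg_nm`, `speck_eccentricity`, `speck_density_per_um2`,
#'   `cyto_area_um2`, `clusters_per_um2`, `n_clusters`. Attribute
#'   `cluster_results` keeps the per-cell `cluster_result` objects.
#' @export
cell_records <- function(locs, regions, wf = NULL, channel = "AF647",
                         cluster = TRUE, eps_nm = 70, min_pts = 10L,
                         max_cluster_size = 300L) {
  is_cell <- vapply(regions, function(r) r$label == "cell", logical(1))
  cell_regs <- unclass(regions)[is_cell]
  if (!length(cell_regs)) stop("no cell regions found")
  ch <- locs[locs$channel == channel, , drop = FALSE]
  cres <- list()
  rows <- lapply(cell_regs, function(cr) {
    cid <- cr$cell_id
    speck <- Filter(function(r) r$label == "speck" &&
                      identical(r$cell_id, cid), unclass(regions))
    in_cell <- select_in_region(ch, cr)
    in_speck <- if (length(speck))
      select_in_region(in_cell, speck[[1L]]) else ch[0L, , drop = FALSE]
    cyto <- select_cytoplasm(in_cell, cr,
                             if (length(speck)) speck[[1L]] else NULL)
    n_tot <- nrow(in_cell); n_sp <- nrow(in_speck)
    pt <- if (n_tot > 0) pseudo_time(n_sp, n_tot) else NA_real_
    sp_area <- if (length(speck)) region_area_um2(speck[[1L]]) else NA_real_
    sm <- if (length(speck) && n_sp > 0) speck_metrics(in_speck, sp_area,
                                                      channel) else NULL
    clus <- NULL
    if (cluster) {
      clus <- dbscan_clusters(cyto$table, cyto$area_um2, eps_nm, min_pts,
                              max_cluster_size)
      cres[[length(cres) + 1L]] <<- clus
    }
    data.frame(
      cell_id = cid, day_id = cr$day_id,
      cell_area_um2 = region_area_um2(cr),
      wf_intensity = if (!is.null(wf) && cid %in% wf$cell_id)
        wf$wf_intensity[match(cid, wf$cell_id)] else NA_real_,
      n_locs_total = n_tot, n_locs_speck = n_sp,
      n_locs_cyto = nrow(cyto$table),
      pseudo_time = pt,
      speck_area_um2 = sp_area,
      speck_rg_nm = if (!is.null(sm)) sm$rg_nm else NA_real_,
      speck_eccentricity = if (!is.null(sm)) sm$eccentricity else NA_real_,
      speck_density_per_um2 = if (!is.null(sm)) sm$density_per_um2 else
        NA_real_,
      cyto_area_um2 = cyto$area_um2,
      clusters_per_um2 = if (!is.null(clus)) clus$clusters_per_um2 else
        NA_real_,
      n_clusters = if (!is.null(clus)) nrow(clus$clusters) else NA_integer_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cell_records", "data.frame")
  attr(out, "cluster_results") <- cres
  attr(out, "channel") <- channel
  out
}

#' Extract per-speck localization tables
#'
#' @param locs A [loc_table] (all channels).
#' @param regions A [region_set] containing `speck` polygons.
#' @param channels Optional channel subset.
#' @return Named list (by `cell_id`) of [loc_table]s, the localizations
#'   inside each speck segment.
#' @export
speck_tables <- function(locs, regions, channels = NULL) {
  if (!is.null(channels))
    locs <- locs[locs$channel %in% channels, , drop = FALSE]
  specks <- Filter(function(r) r$label == "speck", unclass(regions))
  out <- lapply(specks, function(sp) select_in_region(locs, sp))
  names(out) <- vapply(specks, function(sp) as.character(sp$cell_id),
                       character(1))
  out
}

#' Center-to-periphery density ratio of a speck
#'
#' Ratio of the localization density inside the central disk
#' (r < `inner_frac * radius`) to the density in the peripheral annulus
#' (`annulus_frac[1] * radius` < r < `annulus_frac[2] * radius`). Sterical
#' exclusion of a bulky label from the dense core lowers this ratio; a
#' core-penetrating label raises it.
#'
#' @param table [loc_table] of one speck, one channel.
#' @param center Speck center `c(x, y)` in nm.
#' @param radius_nm Reference (core) radius in nm.
#' @param inner_frac Central disk radius as a fraction of `radius_nm`
#'   (default 0.3).
#' @param annulus_frac Annulus fractions (default `c(0.7, 1)`).
#' @return Density ratio (dimensionless); `NA` if the annulus is empty.
#' @export
core_periphery_ratio <- function(table, center, radius_nm,
                                 inner_frac = 0.3, annulus_frac = c(0.7, 1)) {
  r <- sqrt((table$x - center[1L])^2 + (table$y - center[2L])^2)
  n_in <- sum(r < inner_frac * radius_nm)
  n_ann <- sum(r >= annulus_frac[1L] * radius_nm &
                 r < annulus_frac[2L] * radius_nm)
  if (!n_ann) return(NA_real_)
  a_in <- pi * (inner_frac * radius_nm)^2
  a_ann <- pi * ((annulus_frac[2L]^2 - annulus_frac[1L]^2) * radius_nm^2)
  (n_in / a_in) / (n_ann / a_ann)
}
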