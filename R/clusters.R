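# Cytoplasmic cluster statistics: DBSCAN with a cluster-size filter, and
# per-cell / per-condition summaries.

# Grid-accelerated eps-neighbourhoods (each point's list includes itself).
# Candidate pairs are built wholesale from the 3x3 grid-cell offsets and
# filtered by distance, which keeps everything vectorized.
eps_neighbours <- function(x, y, eps) {
  n <- length(x)
  nbrs <- vector("list", n)
  if (!n) return(nbrs)
  gx <- as.integer(floor(x / eps)); gy <- as.integer(floor(y / eps))
  gx <- gx - min(gx); gy <- gy - min(gy)
  ngy <- max(gy) + 2L                      # +2: offset keys never collide
  key <- as.double(gx) * ngy + gy
  cells <- split(seq_len(n), key)
  ckeys <- as.double(names(cells))
  counts <- lengths(cells)
  eps2 <- eps * eps
  ei <- vector("list", 9L); ej <- vector("list", 9L)
  s <- 0L
  for (dx in -1L:1L) {
    for (dy in -1L:1L) {
      s <- s + 1L
      nb <- match(ckeys + as.double(dx) * ngy + dy, ckeys)
      sel <- which(!is.na(nb))
      if (!length(sel)) next
      na <- counts[sel]; bcells <- nb[sel]; nbcnt <- counts[bcells]
      i_idx <- rep(unlist(cells[sel], use.names = FALSE),
                   times = rep(nbcnt, na))
      j_idx <- unlist(rep(cells[bcells], times = na), use.names = FALSE)
      ok <- (x[i_idx] - x[j_idx])^2 + (y[i_idx] - y[j_idx])^2 <= eps2
      ei[[s]] <- i_idx[ok]; ej[[s]] <- j_idx[ok]
    }
  }
  i_all <- unlist(ei, use.names = FALSE)
  j_all <- unlist(ej, use.names = FALSE)
  ord <- order(i_all, j_all)
  adj <- split(j_all[ord], factor(i_all[ord], levels = seq_len(n)))
  nbrs[] <- adj
  nbrs
}

# Deterministic DBSCAN: a point is core if its eps-neighbourhood (self
# included) holds >= min_pts points; clusters are grown from core points in
# index order (BFS), so a border point joins the first cluster that reaches
# it, i.e. the one containing the lowest-index core point.
dbscan_labels <- function(x, y, eps, min_pts) {
  n <- length(x)
  labels <- integer(n)
  if (!n) return(labels)
  nbrs <- eps_neighbours(x, y, eps)
  core <- lengths(nbrs) >= min_pts
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      nb <- nbrs[[p]]
      fresh <- nb[labels[nb] == 0L]
      if (length(fresh)) {
        labels[fresh] <- cl
        queue <- c(queue, fresh[core[fresh]])
      }
    }
  }
  labels
}

#' DBSCAN clustering of cytoplasmic localizations
#'
#' Clusters 2D localization positions with DBSCAN and then discards clusters
#' larger than `max_cluster_size` localizations, so a retained cluster is a
#' group of `min_pts`--`max_cluster_size` localizations within the `eps_nm`
#' search radius (defaults 10--300 within 70 nm). A point is a core point if
#' its eps-neighbourhood, itself included, holds at least `min_pts` points;
#' border points join the cluster of the lowest-index core point that reaches
#' them (deterministic tie-break). Noise carries label 0; clusters are
#' numbered 1..k in order of appearance.
#'
#' @param table A [loc_table] (typically cytoplasmic localizations, see
#'   [select_cytoplasm]).
#' @param area_um2 Analysed region area in square micrometres (cell minus
#'   speck), used for the cluster density. May be `NA`.
#' @param eps_nm Search radius in nm (default 70).
#' @param min_pts Minimum localizations per cluster (default 10).
#' @param max_cluster_size Maximum localizations per cluster (default 300);
#'   larger clusters are reassigned to noise.
#' @return Object of class `cluster_result`: list with `labels`
#'   (per-localization integer, 0 = noise), `clusters` (data.frame with
#'   `cluster`, `n_locs`, `cx`, `cy`, `rg_nm`), `area_um2`,
#'   `clusters_per_um2` and the parameters used.
#' @export
dbscan_clusters <- function(table, area_um2 = NA_real_, eps_nm = 70,
                            min_pts = 10L, max_cluster_size = 300L) {
  stopifnot(eps_nm > 0, min_pts > 0, min_pts <= max_cluster_size)
  labels <- dbscan_labels(table$x, table$y, eps_nm, min_pts)
  if (any(labels > 0L)) {
    sizes <- tabulate(labels)
    big <- which(sizes > max_cluster_size)
    labels[labels %in% big] <- 0L
    kept <- sort(unique(labels[labels > 0L]))
    labels <- match(labels, kept, nomatch = 0L)
  }
  ks <- sort(unique(labels[labels > 0L]))
  clusters <- do.call(rbind, lapply(ks, function(k) {
    px <- table$x[labels == k]; py <- table$y[labels == k]
    data.frame(cluster = k, n_locs = length(px),
               cx = mean(px), cy = mean(py),
               rg_nm = radius_of_gyration_2d(cbind(px, py)))
  }))
  if (is.null(clusters))
    clusters <- data.frame(cluster = integer(), n_locs = integer(),
                           cx = numeric(), cy = numeric(), rg_nm = numeric())
  structure(list(labels = labels, clusters = clusters, area_um2 = area_um2,
                 clusters_per_um2 = if (is.na(area_um2)) NA_real_ else
                   nrow(clusters) / area_um2,
                 eps_nm = eps_nm, min_pts = min_pts,
                 max_cluster_size = max_cluster_size),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d clusters from %d localizations (%.3g / um^2)\n",
    nrow(x$clusters), length(x$labels), x$clusters_per_um2))
  invisible(x)
}

#' Summarize cluster results over cells
#'
#' Aggregates per-cell [dbscan_clusters] results into the per-condition
#' summary reported for cytoplasmic ASC: mean cluster density over cells,
#' mean localizations per cluster (pooled), and median/mode of the pooled
#' per-cluster radius of gyration.
#'
#' @param results List of `cluster_result` objects (one per cell).
#' @param mode_bin_rule Histogram bin rule for the Rg mode, see
#'   [summarize_values].
#' @return List with `n_cells`, `n_clusters`, `mean_clusters_per_um2`,
#'   `mean_locs_per_cluster`, `rg_summary` (a `summary_stats`), and
#'   `cluster_table` (pooled per-cluster statistics for distribution plots).
#' @export
cluster_summary <- function(results, mode_bin_rule = "fd") {
  stopifnot(length(results) >= 1L)
  dens <- vapply(results, `[[`, numeric(1), "clusters_per_um2")
  pooled <- do.call(rbind, lapply(seq_along(results), function(i) {
    cl <- results[[i]]$clusters
    if (nrow(cl)) cl$cell <- i
    cl
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(list(n_cells = length(results), n_clusters = 0L,
                mean_clusters_per_um2 = mean(dens),
                mean_locs_per_cluster = NA_real_, rg_summary = NULL,
                cluster_table = pooled))
  }
  list(n_cells = length(results),
       n_clusters = nrow(pooled),
       mean_clusters_per_um2 = mean(dens),
       mean_locs_per_cluster = mean(pooled$n_locs),
       rg_summary = summarize_values(pooled$rg_nm, mode_bin_rule = mode_bin_rule),
       cluster_table = pooled)
}
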