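# DBSCAN cluster statistics and Ripley's L(r) - r.

test_that("DBSCAN honours min_pts and the cluster-size filter", {
  # 9 coincident points: below min_pts = 10, all noise
  nine <- loc_table(rep(0, 9), rep(0, 9))
  expect_equal(nrow(dbscan_clusters(nine)$clusters), 0L)

  # two tight blobs 1 um apart: two clusters, labels equal to the oracle
  set.seed(41)
  blob <- function(cx, cy) cbind(cx + runif(20, 0, 30), cy + runif(20, 0, 30))
  pts <- rbind(blob(0, 0), blob(1000, 0))
  res <- dbscan_clusters(loc_table(pts[, 1], pts[, 2]))
  expect_equal(nrow(res$clusters), 2L)
  expect_identical(as.integer(res$labels),
                   as.integer(brute_dbscan(pts[, 1], pts[, 2], 70, 10)))

  # one 400-point mutually linked blob: removed by the size filter
  set.seed(42)
  big <- loc_table(runif(400, 0, 50), runif(400, 0, 50))
  res2 <- dbscan_clusters(big)
  expect_equal(nrow(res2$clusters), 0L)
  expect_true(all(res2$labels == 0L))

  # empty input: empty result, not an error
  expect_equal(nrow(dbscan_clusters(loc_table())$clusters), 0L)
})

test_that("DBSCAN equals the brute-force oracle on random instances", {
  for (k in 1:25) {
    set.seed(2000 + k)
    n <- sample(20:200, 1)
    # mixture of clutter and a few planted blobs
    nb <- sample(0:3, 1)
    x <- runif(n, 0, 2000); y <- runif(n, 0, 2000)
    if (nb > 0) {
      for (b in seq_len(nb)) {
        m <- sample(5:30, 1)
        cx <- runif(1, 0, 2000); cy <- runif(1, 0, 2000)
        x <- c(x, cx + rnorm(m, 0, 25)); y <- c(y, cy + rnorm(m, 0, 25))
      }
    }
    eps <- runif(1, 40, 120); mp <- sample(3:12, 1)
    got <- dbscan_clusters(loc_table(x, y), eps_nm = eps, min_pts = mp,
                           max_cluster_size = 10 * length(x))$labels
    expect_identical(as.integer(got),
                     as.integer(brute_dbscan(x, y, eps, mp)))
  }
})

test_that("cluster density is invariant under rigid motions", {
  set.seed(55)
  x <- runif(800, 0, 5000); y <- runif(800, 0, 5000)
  x <- c(x, 2500 + rnorm(40, 0, 20)); y <- c(y, 2500 + rnorm(40, 0, 20))
  base <- dbscan_clusters(loc_table(x, y), area_um2 = 25)
  th <- 0.7
  xr <- x * cos(th) - y * sin(th) + 1e5
  yr <- x * sin(th) + y * cos(th) - 3e4
  rot <- dbscan_clusters(loc_table(xr, yr), area_um2 = 25)
  expect_equal(rot$clusters_per_um2, base$clusters_per_um2)
  expect_equal(sort(rot$clusters$n_locs), sort(base$clusters$n_locs))
})

test_that("cluster summaries aggregate density and size", {
  mk <- function(n_clusters, area) {
    # n_clusters tight planted blobs of 15 points each
    set.seed(n_clusters * 7 + area)
    xs <- ys <- numeric(0)
    for (b in seq_len(n_clusters)) {
      xs <- c(xs, b * 2000 + rnorm(15, 0, 15))
      ys <- c(ys, rnorm(15, 0, 15))
    }
    dbscan_clusters(loc_table(xs, ys), area_um2 = area)
  }
  one <- mk(4, 10)
  expect_equal(one$clusters_per_um2, 0.4)
  s <- cluster_summary(list(mk(1, 10), mk(3, 10)))
  expect_equal(s$mean_clusters_per_um2, 0.2)
  expect_equal(s$n_clusters, 4L)
  expect_equal(s$mean_locs_per_cluster, 15)
})

test_that("recovered oligomer cluster size matches the forward-model oracle", {
  # plant many 12 nm oligomer disks, label with the antibody model, and
  # compare the recovered median cluster Rg against a direct Monte-Carlo
  # draw of a single planted disk through the same forward model
  set.seed(61)
  n_disks <- 120
  cx <- runif(n_disks, 0, 2e4); cy <- runif(n_disks, 0, 2e4)
  xs <- ys <- numeric(0)
  for (k in seq_len(n_disks)) {
    n_em <- 4
    rd <- 6 * sqrt(runif(n_em)); th <- runif(n_em, 0, 2 * pi)
    ex <- cx[k] + rd * cos(th); ey <- cy[k] + rd * sin(th)
    dirs <- runif(n_em, 0, 2 * pi)
    lx <- ex + 2 * cos(dirs); ly <- ey + 2 * sin(dirs)
    blinks <- rgeom(n_em, 1 / 5) + 1L
    li <- rep(seq_len(n_em), blinks)
    xs <- c(xs, lx[li] + rnorm(length(li), 0, 10))
    ys <- c(ys, ly[li] + rnorm(length(li), 0, 10))
  }
  res <- dbscan_clusters(loc_table(xs, ys), area_um2 = 400)
  expect_gt(nrow(res$clusters), 40)
  # oracle: single disk, many emitters, same displacement chain
  m <- 2e5
  rd <- 6 * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
  ox <- rd * cos(th) + 2 * cos(runif(m, 0, 2 * pi)) + rnorm(m, 0, 10)
  oy <- rd * sin(th) + 2 * sin(runif(m, 0, 2 * pi)) + rnorm(m, 0, 10)
  oracle_rg <- radius_of_gyration_2d(cbind(ox, oy))
  expect_lt(abs(median(res$clusters$rg_nm) - oracle_rg) / oracle_rg, 0.20)
})

test_that("Ripley L(r) - r matches closed forms and contracts", {
  roi <- list(xlim = c(0, 2000), ylim = c(0, 2000))
  radii <- seq(50, 500, by = 50)
  # all points coincident: K(r) = |A|
  co <- loc_table(rep(1000, 6), rep(1000, 6))
  lr <- ripley_l(co, roi, radii)
  expect_equal(lr$l_minus_r, sqrt(4e6 / pi) - radii, tolerance = 1e-12)

  expect_error(ripley_l(loc_table(1, 1), roi, radii), "at least 2")
  expect_error(ripley_l(co, roi, c(100, 1500)), "exceeds half")
  expect_error(ripley_l(co, roi, c(200, 100)), "increasing")
  expect_error(ripley_randomization(co, roi, radii, n_rand = 0), "n_rand")
})

test_that("randomization control separates clustered from CSR data", {
  roi <- list(xlim = c(0, 2000), ylim = c(0, 2000))
  radii <- seq(25, 400, by = 25)
  hits <- 0L
  for (s in 1:5) {
    set.seed(700 + s)
    # planted 50 nm cluster over sparse background
    bg <- 80
    tb <- loc_table(c(runif(bg, 0, 2000), 1000 + rnorm(100, 0, 50)),
                    c(runif(bg, 0, 2000), 1000 + rnorm(100, 0, 50)))
    rr <- ripley_randomization(tb, roi, radii, n_rand = 20, seed = s)
    if (rr$observed_max > mean(rr$randomized_max)) hits <- hits + 1L
  }
  expect_equal(hits, 5L)

  # CSR observed data stays inside the randomized band most of the time
  inside <- 0L
  for (s in 1:10) {
    set.seed(800 + s)
    tb <- loc_table(runif(150, 0, 2000), runif(150, 0, 2000))
    rr <- ripley_randomization(tb, roi, radii, n_rand = 40, seed = s)
    if (rr$observed_max <= quantile(rr$randomized_max, 0.975)) inside <- inside + 1L
  }
  expect_gte(inside, 8L)
})

test_that("square ROIs tile the cytoplasm and avoid the speck", {
  cell <- circle_region("cell", 0, 0, 8000, cell_id = 1)
  speck <- circle_region("speck", 2000, 0, 900, cell_id = 1)
  rois <- ripley_rois(cell, speck, size_nm = 2000, n = 8, seed = 3)
  expect_gt(length(rois), 3)
  for (ro in rois) {
    corners_x <- c(ro$xlim, ro$xlim)
    corners_y <- rep(ro$ylim, each = 2)
    expect_true(all(point_in_polygon(corners_x, corners_y, cell$vertices)))
    expect_false(any(point_in_polygon(corners_x, corners_y, speck$vertices)))
  }
})
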