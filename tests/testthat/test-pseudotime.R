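# Pseudo-time, day calibration, cell-area normalization, aligned sums.

test_that("pseudo-time is the in-speck fraction of localizations", {
  expect_equal(pseudo_time(1000, 1000), 1)
  expect_equal(pseudo_time(0, 1000), 0)
  expect_equal(pseudo_time(300, 1000), 0.3)
  expect_error(pseudo_time(1, 0), "positive")
  expect_error(pseudo_time(11, 10), "exceeds")
})

mk_records <- function(days, slopes, n_per_day = 6, loc_slopes = NULL) {
  do.call(rbind, lapply(seq_along(days), function(k) {
    a <- seq(50, 150, length.out = n_per_day)
    wf <- slopes[k] * a
    nl <- if (is.null(loc_slopes)) 2 * wf else loc_slopes[k] * wf
    data.frame(cell_id = paste0(days[k], "_", seq_along(a)),
               day_id = days[k], cell_area_um2 = a, wf_intensity = wf,
               n_locs_total = nl, n_locs_speck = nl / 2)
  }))
}

test_that("day calibration rescales per-day slopes to the maximum", {
  one <- day_calibrate(mk_records("a", 2))
  expect_equal(one$day_scale_intensity, rep(1, 6))
  expect_equal(one$wf_intensity, mk_records("a", 2)$wf_intensity)

  two <- day_calibrate(mk_records(c("d1", "d2"), c(1, 2)))
  expect_equal(two$day_scale_intensity[two$day_id == "d1"], rep(2, 6))
  expect_equal(two$day_scale_intensity[two$day_id == "d2"], rep(1, 6))
  # recomputed slopes are equal after calibration
  s <- vapply(split(two, two$day_id),
              function(d) cov(d$cell_area_um2, d$wf_intensity) /
                var(d$cell_area_um2), numeric(1))
  expect_equal(unname(diff(s)), 0, tolerance = 1e-12)

  # localization counts calibrated against intensity in the second step
  lc <- day_calibrate(mk_records(c("d1", "d2"), c(1, 1),
                                 loc_slopes = c(1, 4)))
  expect_equal(unique(lc$day_scale_locs[lc$day_id == "d1"]), 4)
  expect_equal(lc$n_locs_speck, lc$n_locs_total / 2)  # ratios preserved
})

test_that("day calibration is idempotent and drops underpowered days", {
  rec <- mk_records(c("d1", "d2", "d3"), c(1, 1.6, 2.4))
  once <- day_calibrate(rec)
  twice <- day_calibrate(once)
  expect_equal(twice$wf_intensity, once$wf_intensity, tolerance = 1e-12)
  expect_equal(twice$n_locs_total, once$n_locs_total, tolerance = 1e-12)

  bad <- rbind(rec, data.frame(cell_id = "solo", day_id = "d4",
                               cell_area_um2 = 80, wf_intensity = 100,
                               n_locs_total = 200, n_locs_speck = 10))
  expect_warning(out <- day_calibrate(bad), "d4")
  expect_false("d4" %in% out$day_id)
})

test_that("cell-area normalization removes the fitted slope exactly", {
  a <- c(50, 80, 110, 140, 170)
  v <- 2 * a + 5
  norm <- normalize_by_cell_area(v, a)
  expect_equal(as.numeric(norm), rep(5, 5), tolerance = 1e-9)
  # residual least-squares slope is zero
  set.seed(121)
  v2 <- 3 * a + rnorm(5, 0, 4)
  n2 <- normalize_by_cell_area(v2, a)
  expect_lt(abs(cov(a, n2) / var(a)), 1e-9)
  # already-uncorrelated values are unchanged
  v3 <- c(1, -1, 0, 1, -1); v3 <- v3 - cov(a, v3) / var(a) * a
  expect_equal(as.numeric(normalize_by_cell_area(v3, a)), v3,
               tolerance = 1e-12)
  expect_error(normalize_by_cell_area(1:2, 1:2), "3 cells")
})

test_that("correlate wraps Pearson and Spearman with guard rails", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, x), 1)
  expect_equal(correlate(x, -x), -1)
  expect_error(correlate(x, rep(1, 4)), "constant")
  set.seed(122)
  expect_lt(abs(correlate(rnorm(1e4), rnorm(1e4))), 0.05)
})

test_that("aligned sums are translation invariant", {
  set.seed(131)
  sp <- loc_table(rnorm(400, 0, 80), rnorm(400, 0, 80))
  sp2 <- sp; sp2$x <- sp2$x + 3e3; sp2$y <- sp2$y - 3e3
  al <- align_and_sum(list(sp, sp2), c(0.2, 0.8), n_bins = 1,
                      half_size_nm = 600)
  # both shifted tables coincide after center-of-mass alignment
  expect_equal(al$shifted[[1]]$x, al$shifted[[2]]$x, tolerance = 1e-9)
  expect_equal(radius_of_gyration_2d(do.call(rbind, al$shifted)),
               radius_of_gyration_2d(al$shifted[[1]]), tolerance = 1e-9)
  # the summed image is twice the single-speck render
  single <- align_and_sum(list(sp), 0.5, n_bins = 1, half_size_nm = 600)
  expect_equal(al$images[[1]][[1]]$pixels,
               2 * single$images[[1]][[1]]$pixels, tolerance = 1e-9)
})

test_that("binning covers [0,1] and warns on empty bins", {
  set.seed(132)
  sps <- lapply(1:9, function(i) loc_table(rnorm(50), rnorm(50)))
  pt <- seq(0.05, 0.85, length.out = 9)
  al <- align_and_sum(sps, pt, n_bins = 3, half_size_nm = 300)
  expect_equal(al$bins$n, c(3L, 3L, 3L))
  expect_equal(al$bins$lo[1], 0)
  expect_equal(al$bins$hi[3], 1)
  aw <- align_and_sum(sps, pt, n_bins = 3, half_size_nm = 300,
                      binning = "equal_width")
  expect_equal(aw$bins$lo, c(0, 1, 2) / 3)
  w <- capture_warnings(align_and_sum(sps, rep(0.1, 9), n_bins = 3,
                                      half_size_nm = 300,
                                      binning = "equal_width"))
  expect_true(any(grepl("empty", w)))
})

test_that("late pseudo-time antibody stacks develop a central dip", {
  sc <- cached_scene()
  rec <- cached_records()
  st <- speck_tables(sc$locs, sc$regions, channels = "AF647")
  st <- st[match(as.character(rec$cell_id), names(st))]
  al <- align_and_sum(st, rec$pseudo_time, reference_channel = "AF647")
  dip <- vapply(1:3, function(b) {
    pr <- al$profiles[[b]][["AF647"]]$horizontal
    ctr <- pr$value[which.min(abs(pr$pos_nm))]
    ctr / max(pr$value)
  }, numeric(1))
  # center-to-peak ratio below 1 in the late bin (ring-like appearance),
  # and more pronounced than in the early bin
  expect_lt(dip[3], 1)
  expect_lt(dip[3], dip[1])
})
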