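# Localization/ROI I/O, affine registration, rendering, widefield intensity.

test_that("delimited localization files parse with the default dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x[nm],y[nm],frame", "10,20,1", "30.5,-2,2", "100,200,3"), f)
  tb <- read_localizations(f)
  expect_s3_class(tb, "loc_table")
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$x, c(10, 30.5, 100))
  expect_equal(tb$y, c(20, -2, 200))
  expect_equal(tb$frame, 1:3)

  # header-only file is an empty table, not an error
  writeLines("x[nm],y[nm],frame", f)
  expect_equal(nrow(read_localizations(f)), 0L)
})

test_that("reader rejects missing columns and non-numeric coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x[nm],frame", "10,1"), f)
  expect_error(read_localizations(f), "mandatory column: y")
  writeLines(c("x,y", "10,20", "oops,30"), f)
  expect_error(read_localizations(f), "row 2")
})

test_that("localization tables round-trip through text with extras intact", {
  tb <- loc_table(c(1.5, 2.5), c(3, 4), frame = c(7L, 8L),
                  channel = "DL755", photons = c(900, 1100))
  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tb, f)
  back <- read_localizations(f)
  expect_equal(back$x, tb$x)
  expect_equal(back$photons, tb$photons)
  expect_equal(back$channel, tb$channel)
})

test_that("affine estimation recovers exact transforms and flags degeneracy", {
  # identity on an exact triplet
  src <- rbind(c(0, 0), c(100, 0), c(0, 100))
  tr <- estimate_affine(src, src)
  expect_equal(tr$linear, diag(2), tolerance = 1e-12)
  expect_equal(tr$offset, c(0, 0), tolerance = 1e-12)

  # noiseless random sources under a known affine: exact recovery
  set.seed(11)
  A <- matrix(c(1.02, -0.03, 0.05, 0.98), 2, 2)
  b <- c(120, -45)
  S <- cbind(runif(10, 0, 5e4), runif(10, 0, 5e4))
  Tg <- t(A %*% t(S) + b)
  est <- estimate_affine(S, Tg)
  expect_lt(max(abs(est$linear - A)) / max(abs(A)), 1e-9)
  expect_lt(max(abs(est$offset - b)) / max(abs(b)), 1e-9)

  expect_error(estimate_affine(src[1:2, ], src[1:2, ]), "degenerate")
  line <- cbind(1:5 * 100, 1:5 * 200)
  expect_error(estimate_affine(line, line), "collinear")
})

test_that("applying an affine maps coordinates and nothing else", {
  tb <- loc_table(0, 0, frame = 3L, channel = "DL755", photons = 500)
  shift <- affine2d(offset = c(100, -50))
  out <- apply_affine(shift, tb)
  expect_equal(c(out$x, out$y), c(100, -50))
  expect_equal(out$photons, 500)
  expect_equal(out$frame, 3L)

  # round trip through the inverse restores coordinates
  set.seed(4)
  tb2 <- loc_table(runif(50, 0, 1e4), runif(50, 0, 1e4))
  A <- affine2d(matrix(c(0.9, 0.1, -0.2, 1.1), 2, 2), c(500, -200))
  back <- apply_affine(affine_invert(A), apply_affine(A, tb2))
  expect_lt(max(abs(back$x - tb2$x), abs(back$y - tb2$y)), 1e-9)
})

test_that("rendering histograms localizations and conserves mass", {
  b <- list(xlim = c(0, 106), ylim = c(0, 106))
  one <- render(loc_table(53, 53), 10.6, 0, b)
  expect_equal(sum(one$pixels), 1)
  expect_equal(sum(one$pixels > 0), 1L)

  # interior point: the truncated kernel support stays inside the image
  wide <- list(xlim = c(0, 318), ylim = c(0, 318))
  blurred <- render(loc_table(159, 159), 10.6, 1, wide)
  expect_equal(sum(blurred$pixels), 1, tolerance = 1e-6)

  two <- render(loc_table(c(53, 54), c(53, 53)), 10.6, 0, b)
  expect_equal(max(two$pixels), 2)

  # interior render of many points keeps the count
  set.seed(21)
  tb <- loc_table(runif(500, 200, 800), runif(500, 200, 800))
  img <- render(tb, 10.6, 1, list(xlim = c(0, 1000), ylim = c(0, 1000)))
  expect_equal(sum(img$pixels), 500, tolerance = 1e-6)
  expect_equal(img$n_rendered, 500L)

  expect_error(render(loc_table(), 10.6, 1, list(xlim = c(0, 0), ylim = c(0, 1))),
               "empty bounds")
})

test_that("widefield intensity subtracts the background mean", {
  sq <- function(x0, y0, w) region("roi", rbind(c(x0, y0), c(x0 + w, y0),
                                                c(x0 + w, y0 + w), c(x0, y0 + w)))
  px <- 10
  img <- matrix(5, 20, 20)
  expect_equal(widefield_intensity(img, sq(0, 0, 50), sq(100, 100, 50), px), 0)

  img2 <- matrix(2, 20, 20)
  img2[1:2, 1:5] <- 7                      # 10 px cell block at value 7
  cell <- sq(0, 0, 50)                     # covers exactly those 10 pixels
  bg <- sq(100, 100, 80)
  expect_equal(widefield_intensity(img2, cell, bg, px), 10 * (7 - 2))

  off_image <- sq(1e6, 1e6, 50)
  expect_error(widefield_intensity(img2, cell, off_image, px), "background")
})

test_that("region selection matches a brute-force oracle and conventions", {
  square <- region("roi", rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  expect_equal(nrow(select_in_region(loc_table(50, 50), square)), 1L)
  expect_equal(nrow(select_in_region(loc_table(500, 50), square)), 0L)
  # boundary counts as inside
  expect_equal(nrow(select_in_region(loc_table(0, 50), square)), 1L)
  bb <- region("filament_backbone", rbind(c(0, 0), c(100, 0)))
  expect_error(select_in_region(loc_table(1, 1), bb), "polyline")

  # left half of a uniform square: binomial count + exact oracle agreement
  set.seed(31)
  tb <- loc_table(runif(1000, 0, 1000), runif(1000, 0, 1000))
  left <- region("roi", rbind(c(0, 0), c(500, 0), c(500, 1000), c(0, 1000)))
  got <- nrow(select_in_region(tb, left))
  expect_lt(abs(got - 500), 4 * sqrt(1000 * 0.25))
  expect_equal(got, sum(brute_point_in_polygon(tb$x, tb$y, left$vertices)))

  # random simple polygons (convex, <= 12 vertices), random points
  for (k in 1:10) {
    set.seed(100 + k)
    m <- sample(3:12, 1)
    ang <- sort(runif(m, 0, 2 * pi))
    v <- cbind(500 + runif(1, 100, 400) * cos(ang),
               500 + runif(1, 100, 400) * sin(ang))
    pts <- loc_table(runif(300, 0, 1000), runif(300, 0, 1000))
    reg <- region("roi", v)
    mine <- point_in_polygon(pts$x, pts$y, v)
    oracle <- brute_point_in_polygon(pts$x, pts$y, v)
    expect_identical(mine, oracle)
  }
})

test_that("region sets round-trip through the JSON schema", {
  rs <- region_set(
    region("cell", rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)),
           cell_id = 1, day_id = 2),
    region("filament_backbone", rbind(c(10, 10), c(500, 400)), cell_id = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_regions(rs, f)
  back <- read_regions(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$label, "cell")
  expect_equal(back[[1]]$vertices, rs[[1]]$vertices)
  expect_equal(back[[1]]$day_id, 2)
  expect_equal(back[[2]]$closed, FALSE)
  expect_equal(region_area_um2(back[[1]]), 1)
})

test_that("rendered images write as TIFF", {
  img <- render(loc_table(c(50, 60), c(50, 60)), 10.6, 1,
                list(xlim = c(0, 110), ylim = c(0, 110)))
  f <- withr::local_tempfile(fileext = ".tif")
  write_rendered_tiff(img, f)
  back <- read_widefield_tiff(f)
  expect_equal(dim(back), dim(img$pixels))
  # 16-bit storage: agreement to the quantization step
  expect_lt(max(abs(back / max(back) - img$pixels / max(img$pixels))),
            2 / 65535)
})
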