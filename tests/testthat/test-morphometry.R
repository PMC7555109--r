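lab_from <- function(m) label_objects(m > 0)

test_that("shape descriptors are exact on analytic shapes", {
  # axis-aligned 4 x 5 rectangle
  rect <- matrix(0, 12, 12)
  rect[4:7, 3:7] <- 1
  f <- object_features(lab_from(rect))
  expect_equal(f$area, 20)
  expect_equal(f$extent, 1)
  expect_equal(f$solidity, 1)
  # filled disk: eccentricity ~ 0
  d <- 25
  xy <- expand.grid(1:d, 1:d)
  disk <- matrix(as.numeric((xy[, 1] - 13)^2 + (xy[, 2] - 13)^2 <= 10^2),
                 d, d)
  fd <- object_features(lab_from(disk))
  expect_lte(fd$eccentricity, 0.05)
  # orientation convention: horizontal 0, vertical 90
  hl <- matrix(0, 5, 12); hl[3, 2:10] <- 1
  vl <- matrix(0, 12, 5); vl[2:10, 3] <- 1
  expect_equal(object_features(lab_from(hl))$orientation, 0)
  expect_equal(object_features(lab_from(vl))$orientation, 90)
  # zero objects: empty table, not an error
  f0 <- object_features(lab_from(matrix(0, 5, 5)))
  expect_equal(nrow(f0), 0)
})

test_that("solidity equals area over the rasterized convex-hull area", {
  withr::local_seed(14)
  blob <- matrix(FALSE, 30, 30)
  for (k in 1:4)
    blob <- blob | (outer((1:30 - sample(8:22, 1))^2,
                          (1:30 - sample(8:22, 1))^2, "+") <=
                      sample(3:6, 1)^2)
  lab <- label_objects(blob)
  keep <- which(lab$labels > 0)
  f <- object_features(lab)
  f <- f[which.max(f$area), ]
  # brute-force oracle: hull of the largest object's pixels, rasterized by
  # an even-odd ray-crossing point-in-polygon test (boundary-inclusive via
  # a small tolerance)
  idx <- which(lab$labels == f$label)
  y <- (idx - 1) %% 30 + 1
  x <- (idx - 1) %/% 30 + 1
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  inside <- function(px, py) {
    n <- length(hx)
    cross <- 0
    on_edge <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      x1 <- hx[i]; y1 <- hy[i]; x2 <- hx[j]; y2 <- hy[j]
      d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) /
        sqrt((x2 - x1)^2 + (y2 - y1)^2)
      if (d < 1e-9 && px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
          py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9)
        on_edge <- TRUE
      if ((y1 > py) != (y2 > py) &&
          px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
        cross <- cross + 1
    }
    on_edge || (cross %% 2 == 1)
  }
  hull_area <- 0
  for (px in min(x):max(x)) for (py in min(y):max(y))
    if (inside(px, py)) hull_area <- hull_area + 1
  expect_equal(f$solidity, f$area / hull_area)
})

test_that("doubling the scale scales area, axes and perimeter correctly", {
  small <- matrix(0, 40, 40); small[5:16, 4:27] <- 1
  big <- matrix(0, 80, 80); big[9:32, 7:54] <- 1
  fs <- object_features(lab_from(small))
  fb <- object_features(lab_from(big))
  expect_equal(fb$area / fs$area, 4)
  expect_equal(fb$major_axis_length / fs$major_axis_length, 2,
               tolerance = 0.02)
  expect_equal(fb$minor_axis_length / fs$minor_axis_length, 2,
               tolerance = 0.02)
  expect_equal(fb$perimeter / fs$perimeter, 2, tolerance = 0.05)
})

test_that("features are invariant to object enumeration order", {
  withr::local_seed(6)
  m <- matrix(runif(40 * 40) > 0.8, 40, 40)
  f1 <- object_features(label_objects(m))
  # a 90-degree rotation re-orders objects in the label scan but preserves
  # every shape descriptor (orientations are remapped, sizes are not)
  f2 <- object_features(label_objects(t(m)[, 40:1]))
  for (col in c("area", "major_axis_length", "minor_axis_length",
                "eccentricity", "solidity", "extent", "perimeter"))
    expect_equal(sort(f1[[col]]), sort(f2[[col]]), tolerance = 1e-12)
})

test_that("histogram binning matches per-value assignment", {
  h <- feature_histogram(c(1, 2, 3, 4), 2, c(1, 4))
  expect_equal(h$counts, c(2, 2))
  # a value exactly at the upper bound falls in the (closed) last bin
  expect_equal(feature_histogram(4, 4, c(0, 4))$counts, c(0, 0, 0, 1))
  withr::local_seed(9)
  v <- runif(1000, -3, 7)
  hh <- feature_histogram(v, 100, c(-3, 7))
  oracle <- integer(100)
  w <- 10 / 100
  for (x in v) {
    k <- min(max(floor((x - (-3)) / w) + 1, 1), 100)
    oracle[k] <- oracle[k] + 1L
  }
  expect_equal(hh$counts, oracle)
  expect_equal(sum(hh$counts), 1000)
  # degenerate range: one occupied bin holding everything
  hd <- feature_histogram(rep(2, 7), 5, c(2, 2))
  expect_equal(hd$counts, c(7, 0, 0, 0, 0))
  expect_error(feature_histogram(1, 3, c(4, 2)), "range")
})

test_that("feature cubes assemble hand-checkable histograms", {
  df <- data.frame(
    sample_id = rep(1:2, each = 6),
    band_index = rep(rep(1:2, each = 3), 2),
    orientation = c(-80, 0, 40, -10, 10, 85,
                    -45, -40, 30, 0, 5, 88))
  cube <- assemble_feature_cube(df, "orientation", 10, 2)
  expect_identical(dim(cube), c(2L, 10L, 2L))
  # band 1 global range [-80, 40]: widths of 12 degrees
  expect_equal(cube[1, , 1], c(1, 0, 0, 0, 0, 0, 1, 0, 0, 1))
  expect_equal(cube[2, , 1], c(0, 0, 1, 1, 0, 0, 0, 0, 0, 1))
  # count conservation per sample/band slice
  expect_true(all(apply(cube, c(1, 3), sum) == 3))
  expect_error(assemble_feature_cube(df, "volume", 10, 2), "unknown feature")
  # sample with zero objects gives an all-zero slice
  cube3 <- assemble_feature_cube(df, "orientation", 10, 2,
                                 sample_ids = 1:3)
  expect_true(all(cube3[3, , ] == 0))
})
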