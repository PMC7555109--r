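test_that("contrast enhancement keeps range, fixes constants, adds entropy", {
  sp <- segmentation_params(clahe_tiles = c(4, 4))
  flat <- matrix(0.5, 64, 64)
  expect_identical(enhance_contrast(flat, sp), flat)
  two <- cbind(matrix(0.4, 64, 32), matrix(0.6, 64, 32))
  out <- enhance_contrast(two, sp)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  expect_gte(entropy256(out), entropy256(two))
  expect_error(enhance_contrast(matrix(0.5, 3, 3), sp), "tile")
  expect_error(enhance_contrast(matrix(2, 64, 64), sp), "\\[0, 1\\]")
})

test_that("Prewitt magnitudes match direct kernel convolution", {
  expect_equal(prewitt_gradient(matrix(0.3, 10, 10)), matrix(0, 10, 10))
  # vertical step: maximal response along the step columns
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  g <- prewitt_gradient(step)
  expect_true(all(g[, 4] == max(g)))
  expect_true(all(g[, c(1, 8)] == 0))
  # fixed 5x5 integer image vs hand convolution with replicated border
  img <- matrix(c(3, 1, 4, 1, 5,
                  9, 2, 6, 5, 3,
                  5, 8, 9, 7, 9,
                  3, 2, 3, 8, 4,
                  6, 2, 6, 4, 3) / 10, 5, 5, byrow = TRUE)
  kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)  # columns -1,0,1
  ky <- t(kx)
  pad <- img[c(1, 1:5, 5), c(1, 1:5, 5)]
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      v <- pad[i + 1 + a, j + 1 + b]
      gx <- gx + v * kx[a + 2, b + 2]
      gy <- gy + v * ky[a + 2, b + 2]
    }
    oracle[i, j] <- sqrt(gx^2 + gy^2)
  }
  expect_equal(prewitt_gradient(img), oracle)
  expect_error(prewitt_gradient(matrix(1, 2, 5)), "3 x 3")
})

test_that("Otsu binarization agrees with exhaustive threshold search", {
  sp <- segmentation_params()
  z <- matrix(0, 10, 10)
  expect_warning(m0 <- binarize_edges(z, sp), "all-zero")
  expect_false(any(m0))
  bim <- matrix(c(rep(0, 90), rep(10, 10)), 10, 10)
  expect_equal(sum(binarize_edges(bim, sp)), 10)
  # random gradient: exhaustive search over the same 256 candidate cuts,
  # between-class variance computed longhand from the histogram
  withr::local_seed(21)
  g <- matrix(c(abs(rnorm(300, 0, 0.3)), abs(rnorm(100, 3, 0.5))), 20, 20)
  lo <- min(g); hi <- max(g)
  w <- (hi - lo) / 256
  bin <- pmin(pmax(floor((g - lo) / w) + 1, 1), 256)
  cnt <- tabulate(bin, 256)
  mids <- lo + (seq_len(256) - 0.5) * w
  best_k <- NA; best_v <- -Inf
  for (k in 1:255) {
    n0 <- sum(cnt[1:k]); n1 <- sum(cnt) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / n0
    mu1 <- sum(cnt[(k + 1):256] * mids[(k + 1):256]) / n1
    v <- n0 / sum(cnt) * n1 / sum(cnt) * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  thr_oracle <- lo + best_k * w
  expect_equal(otsu_threshold(g), thr_oracle)
  expect_identical(binarize_edges(g, sp), g >= thr_oracle)
  # fixed threshold path
  spf <- segmentation_params(edge_threshold_method = "fixed",
                             edge_threshold_value = 1)
  expect_identical(binarize_edges(g, spf), g >= 1)
})

test_that("morphological cleaning closes gaps and removes small objects", {
  base <- segmentation_params(despeckle_area = 0, se_radius_dilate = 0,
                              se_radius_erode = 0, fill_holes = FALSE,
                              min_object_area = 2)
  empty <- matrix(FALSE, 12, 12)
  expect_identical(morphological_clean(empty, base), empty)
  single <- empty; single[5, 5] <- TRUE
  expect_false(any(morphological_clean(single, base)))
  # two parallel lines 3 px apart fuse under a radius-2 dilation
  lines <- matrix(FALSE, 12, 20)
  lines[4, 3:18] <- TRUE
  lines[8, 3:18] <- TRUE
  fused <- morphological_clean(lines, segmentation_params(
    despeckle_area = 0, se_radius_dilate = 2, se_radius_erode = 0,
    fill_holes = FALSE, min_object_area = 1))
  expect_equal(label_objects(fused)$n_objects, 1)
  # small enclosed holes are filled, large ones are kept
  ring <- matrix(FALSE, 40, 40)
  ring[10:30, 10:30] <- TRUE
  ring[13:27, 13:27] <- FALSE   # 225-px hole
  spl <- segmentation_params(despeckle_area = 0, se_radius_dilate = 0,
                             se_radius_erode = 0, fill_holes = TRUE,
                             max_hole_area = 500, min_object_area = 1)
  expect_true(all(morphological_clean(ring, spl)[13:27, 13:27]))
  sps <- segmentation_params(despeckle_area = 0, se_radius_dilate = 0,
                             se_radius_erode = 0, fill_holes = TRUE,
                             max_hole_area = 100, min_object_area = 1)
  expect_false(any(morphological_clean(ring, sps)[13:27, 13:27]))
})

test_that("labeling is 8-connected with consecutive labels", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE          # diagonal touch: one object
  m[5, 5] <- TRUE
  lab <- label_objects(m)
  expect_equal(lab$n_objects, 2)
  expect_identical(sort(unique(as.vector(lab$labels))), c(0L, 1L, 2L))
  expect_equal(lab$labels[1, 1], lab$labels[2, 2])
})

test_that("whole-cube segmentation is deterministic and recovers the network", {
  p <- scene_params(image_height = 240, image_width = 288, pixel_size = 200,
                    n_fibers = 46, seed = 11)
  sc <- generate_scene(p)
  labs <- segment_imct(sc$cube)
  labs2 <- segment_imct(sc$cube)
  expect_equal(length(labs), 19)
  expect_identical(lapply(labs, `[[`, "labels"),
                   lapply(labs2, `[[`, "labels"))
  union_fg <- Reduce(`|`, lapply(labs, function(l) l$labels > 0))
  truth <- sc$masks$perimysium | sc$masks$endomysium | sc$masks$fat
  expect_gte(dice(union_fg, truth), 0.6)
  # coarse area recovery: detected foreground fraction within a factor-2
  # bracket of the true structure fraction
  expect_lt(mean(union_fg), 2 * mean(truth))
  expect_gt(mean(union_fg), mean(truth) / 2)
})

test_that("a homogeneous lean scene yields no objects in any band", {
  p <- small_scene_params(seed = 1, perimysium_density = 0, fat_fraction = 0,
                          noise_sd = 0, illumination_amplitude = 0,
                          n_spots = 0, n_fibers = 1)
  sc <- generate_scene(p)
  labs <- segment_imct(sc$cube)
  expect_true(all(vapply(labs, `[[`, integer(1), "n_objects") == 0L))
})
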