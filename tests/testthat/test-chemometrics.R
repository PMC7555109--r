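# small synthetic feature cube with a band-profile signal
make_signal_cube <- function(n, n_bins = 6, n_bands = 3, seed = 1,
                             feature = "orientation") {
  withr::local_seed(seed)
  z <- runif(n)                       # latent signal
  cube <- array(0, c(n, n_bins, n_bands))
  for (i in seq_len(n))
    for (b in seq_len(n_bands))
      cube[i, , b] <- rpois(n_bins, lambda = 2 + 8 * z[i] * b / n_bands) + 1
  structure(cube, feature = feature, n_bins = as.integer(n_bins),
            class = c("feature_cube", "array"))
}

test_that("histogram normalization and centering follow the training set", {
  cube <- array(3, c(4, 5, 2))                      # equal counts
  nc <- normalize_and_center(cube, train = 1:2)
  expect_equal(nc$col_means, rep(1 / 10, 10))
  expect_true(all(abs(colMeans(nc$X[1:2, ])) < 1e-12))
  expect_equal(nc$X, matrix(0, 4, 10))              # identical samples
  # zero-object samples stay zero, with a warning
  cube[3, , ] <- 0
  expect_warning(nc2 <- normalize_and_center(cube), "no objects")
  expect_equal(rowSums(nc2$X[c(1, 2, 4), , drop = FALSE] +
                         rep(nc2$col_means, each = 3)),
               rep(1, 3))
  # band-major unfolding: entry (bin 2, band 2) lands at column 5 + 2
  cube4 <- array(0, c(2, 5, 2))
  cube4[1, 2, 2] <- 4
  cube4[2, 1, 1] <- 1
  X4 <- suppressWarnings(normalize_and_center(cube4))$X
  expect_equal(X4[1, 7] - X4[2, 7], 1)
})

test_that("70/15/15 splits have the documented sizes and partition property", {
  s <- split_data(240, seed = 1)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 168L, val = 36L, test = 36L))
  s10 <- split_data(10, seed = 2)
  expect_equal(lengths(s10[c("train", "val", "test")]),
               c(train = 7L, val = 2L, test = 1L))
  expect_identical(split_data(53, seed = 9), split_data(53, seed = 9))
  for (n in c(7, 20, 101)) for (seed in 1:3) {
    s <- split_data(n, seed)
    expect_identical(sort(c(s$train, s$val, s$test)), seq_len(n))
  }
  expect_error(split_data(4, 1), "empty")
})

test_that("PLS1 matches its algebraic contracts", {
  withr::local_seed(4)
  # exact rank-2 matrix: 2 LVs explain all X variance
  A <- matrix(rnorm(20 * 2), 20, 2)
  B <- matrix(rnorm(2 * 30), 2, 30)
  X <- A %*% B
  y <- rnorm(20)
  m2 <- fit_pls(X, y, 2)
  expect_equal(tail(m2$explained_x_variance, 1), 1, tolerance = 1e-10)
  expect_error(fit_pls(X, y, 5), "rank")
  # y exactly linear in X: regression of y on enough scores is exact
  Xf <- matrix(rnorm(30 * 8), 30, 8)
  beta <- rnorm(8)
  yl <- as.numeric(Xf %*% beta)
  mf <- fit_pls(Xf, yl, 8)
  S <- pls_scores(mf, Xf)
  fit <- lm(yl ~ S)
  r2_scores <- suppressWarnings(summary(fit)$r.squared)
  expect_equal(r2_scores, 1, tolerance = 1e-10)
  # first weight vector is the dominant eigenvector of X'yy'X
  Xr <- matrix(rnorm(20 * 50), 20, 50)
  yr <- rnorm(20)
  m1 <- fit_pls(Xr, yr, 3)
  Xc <- sweep(Xr, 2, colMeans(Xr))
  yc <- yr - mean(yr)
  M <- crossprod(Xc, yc) %*% crossprod(yc, Xc)
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  w1 <- m1$weights[, 1]
  expect_equal(abs(sum(w1 * ev)), 1, tolerance = 1e-8)
  # explained variance is nondecreasing
  expect_true(all(diff(m1$explained_x_variance) >= -1e-12))
})

test_that("the network reproduces constants and noiseless linear maps", {
  withr::local_seed(2)
  n <- 240
  S <- matrix(rnorm(n * 10), n, 10)
  sp <- split_data(n, 1)
  # constant target
  mc <- train_ann(S[sp$train, ], rep(5, 168), S[sp$val, ], rep(5, 36),
                  ann_config(3, 2, seed = 1))
  expect_lte(sqrt(mean((predict(mc, S[sp$train, ]) - 5)^2)), 1e-6)
  # noiseless linear target, 6-4 architecture
  y <- as.numeric(S %*% rnorm(10)) + 2
  ml <- train_ann(S[sp$train, ], y[sp$train], S[sp$val, ], y[sp$val],
                  ann_config(6, 4, seed = 1))
  r2 <- evaluate_predictions(y[sp$test], predict(ml, S[sp$test, ]))$r2
  expect_gte(r2, 0.999)
  # identical seeds give identical weights
  ml2 <- train_ann(S[sp$train, ], y[sp$train], S[sp$val, ], y[sp$val],
                   ann_config(6, 4, seed = 1))
  expect_identical(ml$weights, ml2$weights)
  expect_identical(ml$epoch_at_best, ml2$epoch_at_best)
})

test_that("determination coefficients and RMSE match hand computation", {
  e <- evaluate_predictions(1:3, 1:3)
  expect_equal(e$r2, 1)
  expect_equal(e$rmse, 0)
  e2 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(e2$rmse, sqrt(1 / 3))
  expect_equal(e2$r2, 1 - 1 / 2)
  e3 <- evaluate_predictions(c(1, 2, 3), rep(2, 3))
  expect_equal(e3$r2, 0)
  e4 <- evaluate_predictions(rep(2, 3), c(1, 2, 3))
  expect_true(is.na(e4$r2))
})

test_that("grid search selects the signal-bearing feature cube", {
  n <- 40
  cube_sig <- make_signal_cube(n, seed = 31, feature = "orientation")
  cube_noise <- make_signal_cube(n, seed = 99, feature = "area")
  # target driven by the signal cube's latent variable
  nc <- normalize_and_center(cube_sig)
  y <- 3 + 10 * rowSums(nc$X[, 13:18])
  split <- split_data(n, seed = 5)
  grid1 <- data.frame(n1l = 3, n2l = 2)
  rep1 <- grid_search_ann(list(cube_noise, cube_sig), y, split,
                          grid = grid1, n_lv = 4, seed = 8)
  expect_s3_class(rep1, "regression_report")
  expect_equal(rep1$feature_name, "orientation")
  gr <- attr(rep1, "grid_results")
  expect_equal(nrow(gr), 2)                 # one config x two cubes
  grid9 <- expand.grid(n1l = 2:4, n2l = 2:4)
  rep9 <- grid_search_ann(list(cube_sig), y, split, grid = grid9,
                          n_lv = 4, seed = 8)
  expect_equal(nrow(attr(rep9, "grid_results")), 9)
  expect_lte(rep9$rmsep, rep9$rmsec + rep9$rmsep)  # sanity: finite metrics
  expect_true(all(c(rep9$r2c, rep9$r2v, rep9$r2p) <= 1))
})

test_that("target summaries reproduce printed coefficient-of-variation rows", {
  df <- data.frame(a = c(1, 5), b = c(2, 2), c = c(-1, 1))
  s <- summarize_targets(df)
  expect_equal(s$cv_percent[s$name == "b"], 0)
  expect_true(is.na(s$cv_percent[s$name == "c"]))
  expect_equal(s$min[s$name == "a"], 1)
  expect_equal(s$mean[s$name == "a"], 3)
})
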