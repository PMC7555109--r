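#' Unfold and normalize a feature cube into a regression matrix
#'
#' Each sample's full histogram tensor slice is unfolded band-major (all
#' bins of band 1, then band 2, ...) into one row vector, rescaled to unit
#' area (sum 1; all-zero rows are left at zero with a warning), and
#' mean-centered with column means computed from the training rows only.
#'
#' @param cube a [assemble_feature_cube()] result (`n_samples x n_bins x
#'   n_bands`).
#' @param train indices of the training rows used to compute the centering
#'   means (default: all rows).
#' @return list with `X` (the centered matrix, `n_samples` x
#'   `n_bins * n_bands`), `col_means`, and `train`.
#' @export
normalize_and_center <- function(cube, train = NULL) {
  d <- dim(cube)
  stopifnot(length(d) == 3)
  if (d[1] < 2) stop("cube must contain at least 2 samples")
  if (is.null(train)) train <- seq_len(d[1])
  X <- matrix(as.numeric(cube), d[1], d[2] * d[3])  # band-major unfolding
  tot <- rowSums(X)
  zero <- tot == 0
  if (any(zero))
    warning(sum(zero), " sample(s) have no objects; their histogram rows ",
            "are left at zero")
  X[!zero, ] <- X[!zero, , drop = FALSE] / tot[!zero]
  mu <- colMeans(X[train, , drop = FALSE])
  list(X = sweep(X, 2, mu), col_means = mu, train = train)
}

#' Random 70/15/15 split into training, validation and test sets
#'
#' Sizes are `round(train_frac * n)`, `round(val_frac * n)` and the
#' remainder, assigned by a seeded random permutation.
#'
#' @param n number of samples (>= 3).
#' @param seed integer seed.
#' @param train_frac,val_frac fractions for training and validation.
#' @return object of class `split_indices`: list with integer vectors
#'   `train`, `val`, `test` (disjoint, union `1:n`) and `seed`.
#' @export
split_data <- function(n, seed = 1L, train_frac = 0.70, val_frac = 0.15) {
  if (n < 3) stop("need at least 3 samples to split")
  n_train <- round(train_frac * n)
  n_val <- round(val_frac * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("n = ", n, " too small: a split set would be empty")
  p <- local_seed(seed, sample.int(n))
  structure(list(train = sort(p[seq_len(n_train)]),
                 val = sort(p[n_train + seq_len(n_val)]),
                 test = sort(p[n_train + n_val + seq_len(n_test)]),
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' Univariate partial least squares (PLS1) by NIPALS
#'
#' Standard PLS1: weights are successive normalized covariance directions
#' `X'y`, with X deflated by its rank-one score/loading reconstruction at
#' each step. Explained X variance is reported cumulatively.
#'
#' @param X predictor matrix (rows = samples), centered with the training
#'   means; any remaining column offset is removed internally and stored.
#' @param y response vector, one target at a time.
#' @param n_lv number of latent variables.
#' @return object of class `pls_model`: list with `n_lv`, `x_mean`,
#'   `y_mean`, `weights` (p x a), `loadings` (p x a), `y_loadings`
#'   (length a), and `explained_x_variance` (cumulative fractions).
#' @export
fit_pls <- function(X, y, n_lv = 10L) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(is.finite(y)))
  n_lv <- as.integer(n_lv)
  x_mean <- colMeans(X)
  Xd <- sweep(X, 2, x_mean)
  y_mean <- mean(y)
  yd <- y - y_mean
  ssx_tot <- sum(Xd^2)
  p <- ncol(X)
  Wm <- matrix(0, p, n_lv)
  Pm <- matrix(0, p, n_lv)
  qv <- numeric(n_lv)
  expl <- numeric(n_lv)
  tol <- max(ssx_tot, 1) * 1e-12
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < sqrt(tol) * 1e-3 || sum(Xd^2) < tol)
      stop("n_lv = ", n_lv, " exceeds the achievable rank (", a - 1,
           ") of the training matrix")
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < tol)
      stop("n_lv = ", n_lv, " exceeds the achievable rank (", a - 1,
           ") of the training matrix")
    pp <- crossprod(Xd, t)[, 1] / tt
    qv[a] <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pp)
    yd <- yd - t * qv[a]
    Wm[, a] <- w
    Pm[, a] <- pp
    expl[a] <- if (ssx_tot > 0) 1 - sum(Xd^2) / ssx_tot else 1
  }
  structure(list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
                 weights = Wm, loadings = Pm, y_loadings = qv,
                 explained_x_variance = expl),
            class = "pls_model")
}

#' Latent-variable scores of new data under a fitted PLS model
#'
#' @param model a [fit_pls()] result.
#' @param X matrix on the same columns as the training matrix.
#' @return matrix `n_samples x n_lv` of scores.
#' @export
pls_scores <- function(model, X) {
  stopifnot(inherits(model, "pls_model"), ncol(X) == length(model$x_mean))
  Xd <- sweep(X, 2, model$x_mean)
  Tm <- matrix(0, nrow(X), model$n_lv)
  for (a in seq_len(model$n_lv)) {
    t <- Xd %*% model$weights[, a]
    Tm[, a] <- t
    Xd <- Xd - t %*% t(model$loadings[, a])
  }
  Tm
}

#' Configuration of the two-hidden-layer regression network
#'
#' @param n1l,n2l neurons in the first and second hidden layer.
#' @param max_epochs maximum number of accepted Levenberg-Marquardt steps
#'   (<= 1000).
#' @param patience early stopping: training stops after this many
#'   consecutive epochs without validation improvement.
#' @param seed seed for the weight initialization.
#' @return object of class `ann_config`.
#' @export
ann_config <- function(n1l, n2l, max_epochs = 1000L, patience = 6L,
                       seed = 1L) {
  stopifnot(n1l >= 1, n2l >= 1, max_epochs >= 1, max_epochs <= 1000,
            patience >= 1)
  structure(list(n1l = as.integer(n1l), n2l = as.integer(n2l),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 hidden_activation = "tanh", output_activation = "linear"),
            class = "ann_config")
}

ann_forward <- function(w, X) {
  A1 <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  A2 <- tanh(sweep(A1 %*% w$W2, 2, w$b2, "+"))
  list(A1 = A1, A2 = A2, yhat = as.numeric(A2 %*% w$w3 + w$b3))
}

# Jacobian of network outputs w.r.t. all weights; n x p
ann_jacobian <- function(w, X, fw) {
  n <- nrow(X)
  n1 <- length(w$b1); n2 <- length(w$b2)
  D2 <- (1 - fw$A2^2) * matrix(w$w3, n, n2, byrow = TRUE)
  D1 <- (D2 %*% t(w$W2)) * (1 - fw$A1^2)
  JW1 <- X[, rep(seq_len(ncol(X)), n1), drop = FALSE] *
    D1[, rep(seq_len(n1), each = ncol(X)), drop = FALSE]
  JW2 <- fw$A1[, rep(seq_len(n1), n2), drop = FALSE] *
    D2[, rep(seq_len(n2), each = n1), drop = FALSE]
  cbind(JW1, D1, JW2, D2, fw$A2, rep(1, n))
}

ann_unpack <- function(theta, d_in, n1, n2) {
  i <- 0
  take <- function(k) { v <- theta[i + seq_len(k)]; i <<- i + k; v }
  w <- list(W1 = matrix(take(d_in * n1), d_in, n1), b1 = take(n1))
  w$W2 <- matrix(take(n1 * n2), n1, n2)
  w$b2 <- take(n2)
  w$w3 <- take(n2)
  w$b3 <- take(1)
  w
}

ann_pack <- function(w) c(w$W1, w$b1, w$W2, w$b2, w$w3, w$b3)

#' Train the two-hidden-layer network by Levenberg-Marquardt
#'
#' Network `d_in - n1l - n2l - 1` with tanh hidden activations and a linear
#' output. Inputs and the response are standardized with training-set
#' statistics (predictions are reported back in original units). Weights
#' are initialized from the seeded generator; each epoch is one accepted
#' damped Gauss-Newton step (training loss is monotone non-increasing
#' across accepted steps). Training stops at `max_epochs`, when no damping
#' value yields a decrease, or when the validation RMSE has not improved
#' for `patience` consecutive epochs; the returned weights are those of the
#' best-validation epoch (epoch 0 = initial weights).
#'
#' @param scores_train,y_train training inputs (matrix) and response.
#' @param scores_val,y_val validation inputs and response for early
#'   stopping.
#' @param config an [ann_config()].
#' @return object of class `ann_model` with elements `weights`,
#'   `epoch_at_best`, `n1l`, `n2l`, input/output scalers and the
#'   per-epoch `val_rmse` trace. Use `predict()` for new scores.
#' @export
train_ann <- function(scores_train, y_train, scores_val, y_val, config) {
  stopifnot(inherits(config, "ann_config"), is.matrix(scores_train),
            nrow(scores_train) == length(y_train),
            nrow(scores_val) == length(y_val))
  if (!all(is.finite(y_train), is.finite(scores_train)))
    stop("non-finite training data")
  d_in <- ncol(scores_train)
  n1 <- config$n1l; n2 <- config$n2l
  x_mu <- colMeans(scores_train)
  x_sd <- apply(scores_train, 2, sd)
  x_sd[x_sd < 1e-12] <- 1
  y_mu <- mean(y_train)
  y_sd <- sd(y_train)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  Xt <- sweep(sweep(scores_train, 2, x_mu), 2, x_sd, "/")
  Xv <- sweep(sweep(scores_val, 2, x_mu), 2, x_sd, "/")
  yt <- (y_train - y_mu) / y_sd
  yv <- (y_val - y_mu) / y_sd

  n_par <- d_in * n1 + n1 + n1 * n2 + n2 + n2 + 1
  theta <- local_seed(config$seed,
                      runif(n_par, -0.5, 0.5) / sqrt(d_in))
  w <- ann_unpack(theta, d_in, n1, n2)
  sse <- function(w, X, y) {
    r <- ann_forward(w, X)$yhat - y
    sum(r^2)
  }
  val_rmse <- function(w) sqrt(mean((ann_forward(w, Xv)$yhat - yv)^2))

  best_w <- w
  best_val <- val_rmse(w)
  best_epoch <- 0L
  fails <- 0L
  lambda <- 1e-3
  cur_sse <- sse(w, Xt, yt)
  trace <- best_val
  epoch <- 0L
  while (epoch < config$max_epochs) {
    fw <- ann_forward(w, Xt)
    r <- fw$yhat - yt
    J <- ann_jacobian(w, Xt, fw)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)[, 1]
    Ident <- diag(nrow(JtJ))
    accepted <- FALSE
    for (try in 1:30) {
      step <- tryCatch(solve(JtJ + lambda * Ident, -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- ann_unpack(ann_pack(w) + step, d_in, n1, n2)
        new_sse <- sse(w_new, Xt, yt)
        if (!is.finite(new_sse))
          stop("non-finite training loss; aborting network training")
        if (new_sse < cur_sse) {
          w <- w_new
          cur_sse <- new_sse
          lambda <- max(lambda * 0.1, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) break  # converged: no damping gives a decrease
    epoch <- epoch + 1L
    vr <- val_rmse(w)
    trace <- c(trace, vr)
    if (vr < best_val - 1e-12) {
      best_val <- vr
      best_w <- w
      best_epoch <- epoch
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= config$patience) break
    }
  }
  structure(list(weights = best_w, epoch_at_best = best_epoch,
                 n1l = n1, n2l = n2, config = config,
                 x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd,
                 val_rmse = trace),
            class = "ann_model")
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- sweep(sweep(newdata, 2, object$x_mu), 2, object$x_sd, "/")
  ann_forward(object$weights, X)$yhat * object$y_sd + object$y_mu
}

#' Coefficient of determination and root-mean-square error
#'
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `rmse = sqrt(mean((y - yhat)^2))`. With zero variance in `y_true` the
#' coefficient is undefined and reported as `NA`.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return list with `r2` and `rmse`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  list(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       rmse = sqrt(mean((y_true - y_pred)^2)))
}

report_one <- function(feature, n_bins, cfg, ann, y, yhat, split) {
  mc <- evaluate_predictions(y[split$train], yhat[split$train])
  mv <- evaluate_predictions(y[split$val], yhat[split$val])
  mp <- evaluate_predictions(y[split$test], yhat[split$test])
  structure(list(feature_name = feature, n_bins = n_bins,
                 n1l = cfg$n1l, n2l = cfg$n2l,
                 epoch_at_best = ann$epoch_at_best,
                 r2c = mc$r2, r2v = mv$r2, r2p = mp$r2,
                 rmsec = mc$rmse, rmsev = mv$rmse, rmsep = mp$rmse),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> %s @ %d bins | N1L %d N2L %d epoch %d\n",
    x$feature_name, x$n_bins, x$n1l, x$n2l, x$epoch_at_best))
  cat(sprintf("  R2C %.3f R2V %.3f R2P %.3f | RMSEC %.4g RMSEV %.4g RMSEP %.4g\n",
              x$r2c, x$r2v, x$r2p, x$rmsec, x$rmsev, x$rmsep))
  invisible(x)
}

#' Two-stage grid search over histogram cubes and network sizes
#'
#' For every supplied feature cube (one per feature / bin-count
#' combination) the histograms are normalized, centered on the training
#' rows, compressed to `n_lv` latent variables by PLS fitted on the
#' training rows, and a network is trained for every `(n1l, n2l)` in the
#' grid. Within each cube the configuration minimizing the selection error
#' is kept; the best cube then yields the final model. By default selection
#' follows the test-set RMSE (RMSEP), replicating the original two-stage
#' procedure; `strict = TRUE` selects on validation RMSE instead, keeping
#' the test set untouched for reporting. Ties are broken by smaller
#' `n1l + n2l`, then smaller bin count.
#'
#' @param cubes list of [assemble_feature_cube()] results.
#' @param y response vector (one target).
#' @param split a [split_data()] result.
#' @param grid data frame with columns `n1l`, `n2l` (default the full
#'   2..8 x 2..8 grid).
#' @param n_lv number of PLS latent variables.
#' @param seed master seed for the per-configuration weight
#'   initializations.
#' @param strict logical; see above.
#' @param max_epochs,patience passed to [ann_config()].
#' @return the winning `regression_report`, with the evaluated grid in
#'   attribute `grid_results` (a data frame) and the winning model in
#'   attribute `model`.
#' @export
grid_search_ann <- function(cubes, y, split, grid = default_ann_grid(),
                            n_lv = 10L, seed = 1L, strict = FALSE,
                            max_epochs = 1000L, patience = 6L) {
  stopifnot(is.list(cubes), length(cubes) >= 1, nrow(grid) >= 1)
  if (!all(c("n1l", "n2l") %in% names(grid))) stop("grid needs n1l and n2l")
  results <- list()
  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  for (ci in seq_along(cubes)) {
    cube <- cubes[[ci]]
    feature <- attr(cube, "feature") %||% "feature"
    n_bins <- attr(cube, "n_bins") %||% dim(cube)[2]
    nc <- normalize_and_center(cube, train = split$train)
    pls <- fit_pls(nc$X[split$train, , drop = FALSE], y[split$train],
                   n_lv = n_lv)
    scores <- pls_scores(pls, nc$X)
    for (gi in seq_len(nrow(grid))) {
      cfg <- ann_config(grid$n1l[gi], grid$n2l[gi],
                        max_epochs = max_epochs, patience = patience,
                        seed = derive_seed(seed, ci * 1000 + gi))
      ann <- train_ann(scores[split$train, , drop = FALSE], y[split$train],
                       scores[split$val, , drop = FALSE], y[split$val],
                       cfg)
      yhat <- predict(ann, scores)
      rep1 <- report_one(feature, n_bins, cfg, ann, y, yhat, split)
      sel <- if (strict) rep1$rmsev else rep1$rmsep
      results[[length(results) + 1L]] <-
        data.frame(feature_name = feature, n_bins = n_bins,
                   n1l = cfg$n1l, n2l = cfg$n2l,
                   epoch_at_best = rep1$epoch_at_best,
                   r2c = rep1$r2c, r2v = rep1$r2v, r2p = rep1$r2p,
                   rmsec = rep1$rmsec, rmsev = rep1$rmsev,
                   rmsep = rep1$rmsep)
      key <- c(sel, cfg$n1l + cfg$n2l, n_bins)
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] &&
           key[3] < best_key[3])) {
        best_key <- key
        best <- rep1
        attr(best, "model") <- list(pls = pls, ann = ann,
                                    col_means = nc$col_means)
      }
    }
  }
  attr(best, "grid_results") <- do.call(rbind, results)
  best
}

#' Default network-size grid (2 to 8 neurons per hidden layer)
#' @return data frame with columns `n1l`, `n2l` (49 rows).
#' @export
default_ann_grid <- function() expand.grid(n1l = 2:8, n2l = 2:8)

#' Min/max/mean/SD/CV summary of a target table
#'
#' Per column: minimum, maximum, mean, sample standard deviation, and the
#' coefficient of variation `100 * sd / mean` (reported as `NA` when the
#' mean is zero).
#'
#' @param targets data frame of numeric target columns (>= 2 rows).
#' @return data frame with one row per target and columns `name`, `min`,
#'   `max`, `mean`, `sd`, `cv_percent`.
#' @export
summarize_targets <- function(targets) {
  stopifnot(nrow(targets) >= 2)
  rows <- lapply(names(targets), function(nm) {
    v <- targets[[nm]]
    m <- mean(v)
    s <- sd(v)
    data.frame(name = nm, min = min(v), max = max(v), mean = m, sd = s,
               cv_percent = if (m != 0) 100 * s / m else NA_real_)
  })
  do.call(rbind, rows)
}
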