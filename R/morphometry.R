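FEATURE_NAMES <- c("area", "major_axis_length", "minor_axis_length",
                   "eccentricity", "orientation", "solidity", "extent",
                   "perimeter")

#' The eight object shape descriptors
#' @return character vector of feature names.
#' @export
feature_names <- function() FEATURE_NAMES

# rasterized convex-hull area of one object's pixel coordinates:
# number of pixel centers inside or on the hull polygon
convex_hull_area <- function(r, c) {
  n <- length(r)
  if (n <= 2) return(n)
  h <- grDevices::chull(c, r)
  hx <- c[h]; hy <- r[h]
  rr <- min(r):max(r); cc <- min(c):max(c)
  gx <- rep(cc, each = length(rr)); gy <- rep(rr, length(cc))
  sum(pracma::inpolygon(gx, gy, hx, hy, boundary = TRUE))
}

#' Shape descriptors of every object in a labeled image
#'
#' Computes, per object: `area` (pixel count); `major_axis_length` /
#' `minor_axis_length` (axes of the ellipse with the same normalized second
#' central moments, including the 1/12 per-pixel variance term);
#' `eccentricity` (`sqrt(1 - (minor/major)^2)`); `orientation` (degrees in
#' `(-90, 90]`, positive counter-clockwise from the horizontal image axis);
#' `solidity` (area / rasterized convex-hull area); `extent` (area /
#' bounding-box area); `perimeter` (total length of the interpixel "crack"
#' boundary between object and background, i.e. `4 * area - 2 *` the number
#' of 4-adjacent same-object pixel pairs; exact and invariant under
#' rotation and reflection, though it overstates smooth contours by up to
#' ~27\% relative to a traced polygon — perimeter estimators differ, and
#' the convention is fixed here).
#'
#' @param labeled a [label_objects()] result (or a plain integer label
#'   matrix).
#' @param sample_id optional sample identifier stored in the table.
#' @param features subset of [feature_names()] to compute (all by default;
#'   restricting the set skips the more expensive descriptors).
#' @return data frame, one row per object, with the requested feature
#'   columns plus `label`, `sample_id`, `band_index`. Zero objects give an
#'   empty data frame.
#' @export
object_features <- function(labeled, sample_id = NA,
                            features = feature_names()) {
  features <- match.arg(features, FEATURE_NAMES, several.ok = TRUE)
  if (inherits(labeled, "labeled_image")) {
    lab <- labeled$labels
    band <- labeled$band_index
  } else {
    lab <- labeled
    band <- NA_integer_
  }
  n <- max(lab)
  base <- data.frame(label = seq_len(n),
                     sample_id = rep(sample_id, length.out = n),
                     band_index = rep(band, length.out = n))
  if (n == 0) {
    for (f in features) base[[f]] <- numeric(0)
    return(base)
  }
  fg <- which(lab > 0L)
  l <- lab[fg]
  y <- ((fg - 1L) %% nrow(lab)) + 1L   # row
  x <- ((fg - 1L) %/% nrow(lab)) + 1L  # col
  area <- tabulate(l, n)
  out <- base
  need_moments <- any(c("major_axis_length", "minor_axis_length",
                        "eccentricity", "orientation") %in% features)
  if ("area" %in% features) out$area <- area
  if (need_moments) {
    sx <- rowsum(as.numeric(x), l)[, 1]
    sy <- rowsum(as.numeric(y), l)[, 1]
    sxx <- rowsum(as.numeric(x)^2, l)[, 1]
    syy <- rowsum(as.numeric(y)^2, l)[, 1]
    sxy <- rowsum(as.numeric(x) * y, l)[, 1]
    mxx <- sxx / area - (sx / area)^2 + 1 / 12
    myy <- syy / area - (sy / area)^2 + 1 / 12
    mxy <- sxy / area - (sx / area) * (sy / area)
    common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    major <- 2 * sqrt(2) * sqrt(mxx + myy + common)
    minor <- 2 * sqrt(2) * sqrt(pmax(mxx + myy - common, 0))
    if ("major_axis_length" %in% features) out$major_axis_length <- major
    if ("minor_axis_length" %in% features) out$minor_axis_length <- minor
    if ("eccentricity" %in% features)
      out$eccentricity <- sqrt(pmax(1 - (minor / major)^2, 0))
    if ("orientation" %in% features) {
      # image rows grow downward; negate the cross moment so positive
      # angles are counter-clockwise from the horizontal axis
      ang <- 0.5 * atan2(-2 * mxy, mxx - myy) * 180 / pi
      ang[ang <= -90] <- ang[ang <= -90] + 180
      out$orientation <- ang
    }
  }
  if ("solidity" %in% features) {
    ys <- split(y, l)
    xs <- split(x, l)
    hull <- mapply(convex_hull_area, ys, xs)
    out$solidity <- as.numeric(area / pmax(hull, area))
  }
  if ("extent" %in% features) {
    xmin <- tapply(x, l, min); xmax <- tapply(x, l, max)
    ymin <- tapply(y, l, min); ymax <- tapply(y, l, max)
    out$extent <- as.numeric(area /
                               ((xmax - xmin + 1) * (ymax - ymin + 1)))
  }
  if ("perimeter" %in% features) {
    # interpixel (crack) boundary length: 4*area minus twice the number of
    # 4-adjacent same-object pixel pairs; exact, and invariant under
    # rotation and reflection
    H <- nrow(lab); W <- ncol(lab)
    hpair <- lab[, -W, drop = FALSE]
    hsame <- hpair > 0L & hpair == lab[, -1, drop = FALSE]
    vpair <- lab[-H, , drop = FALSE]
    vsame <- vpair > 0L & vpair == lab[-1, , drop = FALSE]
    adj <- tabulate(hpair[hsame], n) + tabulate(vpair[vsame], n)
    out$perimeter <- 4 * area - 2 * adj
  }
  out
}

#' Equal-width frequency histogram of feature values
#'
#' `n_bins` equal-width bins over `[lo, hi]`; bins are half-open
#' `[edge_i, edge_{i+1})` except the last, which is closed, and values
#' outside the range are clipped into the end bins. If `hi == lo` the
#' histogram degenerates to a single occupied bin holding all values.
#'
#' @param values numeric vector.
#' @param n_bins number of bins (>= 1).
#' @param range `c(lo, hi)` with `hi >= lo`.
#' @return list with integer `counts` (length `n_bins`, summing to
#'   `length(values)`) and `edges` (length `n_bins + 1`).
#' @export
feature_histogram <- function(values, n_bins, range) {
  stopifnot(n_bins >= 1, length(range) == 2)
  lo <- range[1]; hi <- range[2]
  if (hi < lo) stop("range upper bound below lower bound")
  n_bins <- as.integer(n_bins)
  if (hi == lo) {
    counts <- integer(n_bins)
    counts[1] <- length(values)
    return(list(counts = counts, edges = rep(lo, n_bins + 1)))
  }
  w <- (hi - lo) / n_bins
  bin <- pmin(pmax(floor((values - lo) / w) + 1L, 1L), n_bins)
  list(counts = tabulate(bin, n_bins), edges = lo + w * (0:n_bins))
}

#' Assemble a samples x bins x bands frequency-histogram cube
#'
#' Builds, for one feature and one bin count, the histogram tensor used as
#' regression input: dimension 1 indexes samples, dimension 2 the histogram
#' bins, dimension 3 the spectral bands. Under the default global range
#' policy the bin range for band `b` is the (min, max) of the feature over
#' all samples in that band, so bins are comparable across samples; the
#' per-sample alternative ranges each sample/band slice on its own.
#'
#' @param features_df data frame of object features as returned by
#'   [object_features()] (rows from all samples/bands bound together), with
#'   `sample_id` and `band_index` columns.
#' @param feature one of [feature_names()].
#' @param n_bins number of histogram bins (the "size classes").
#' @param n_bands number of spectral bands.
#' @param sample_ids sample identifiers defining row order (default: sorted
#'   unique `sample_id`).
#' @param range_policy `"global"` (default) or `"per_sample"`.
#' @return object of class `feature_cube`: numeric array
#'   `n_samples x n_bins x n_bands` of counts, with attributes
#'   `feature`, `n_bins`, `bin_edges` (list per band), `sample_ids`.
#' @export
assemble_feature_cube <- function(features_df, feature, n_bins, n_bands,
                                  sample_ids = NULL,
                                  range_policy = c("global", "per_sample")) {
  range_policy <- match.arg(range_policy)
  if (!feature %in% FEATURE_NAMES)
    stop("unknown feature '", feature, "'; must be one of: ",
         paste(FEATURE_NAMES, collapse = ", "))
  stopifnot(feature %in% names(features_df))
  if (is.null(sample_ids)) sample_ids <- sort(unique(features_df$sample_id))
  n_s <- length(sample_ids)
  cube <- array(0, c(n_s, n_bins, n_bands))
  edges <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    rows <- features_df$band_index == b
    vb <- features_df[[feature]][rows]
    sb <- features_df$sample_id[rows]
    rng <- if (length(vb)) range(vb) else c(0, 0)
    for (i in seq_len(n_s)) {
      vi <- vb[sb == sample_ids[i]]
      ri <- if (range_policy == "global") rng else
        if (length(vi)) range(vi) else c(0, 0)
      h <- feature_histogram(vi, n_bins, ri)
      cube[i, , b] <- h$counts
      if (i == 1 || range_policy == "global") edges[[b]] <- h$edges
    }
  }
  structure(cube, feature = feature, n_bins = as.integer(n_bins),
            bin_edges = edges, sample_ids = sample_ids,
            class = c("feature_cube", "array"))
}

#' @export
print.feature_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_cube> %s, %d samples x %d bins x %d bands\n",
              attr(x, "feature"), d[1], d[2], d[3]))
  invisible(x)
}
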