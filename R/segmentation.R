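#' Parameters of the connective-tissue segmentation pipeline
#'
#' Defaults: CLAHE clip limit 0.01 (fraction of tile pixel count) on an
#' 8 x 8 tile grid, Otsu thresholding of the Prewitt gradient magnitude,
#' morphological closing with disc radii 2 (dilate) / 1 (erode), and removal
#' of objects below 20 px.
#'
#' @param clahe_clip_limit contrast-limited equalization clip limit, as the
#'   fraction of the per-tile pixel count a histogram bin may hold.
#' @param clahe_tiles `c(ny, nx)` tile grid.
#' @param edge_threshold_method `"otsu"` (default) or `"fixed"`.
#' @param edge_threshold_value gradient-magnitude threshold when
#'   `edge_threshold_method = "fixed"`.
#' @param despeckle_area isolated edge specks of at most this many pixels
#'   are removed before the closing, so single-pixel noise responses cannot
#'   weld neighbouring structures together when dilated; 0 disables.
#' @param se_radius_dilate,se_radius_erode disc structuring-element radii in
#'   pixels for the closing (dilate, then erode); 0 skips the operation.
#' @param fill_holes fill enclosed background holes after the closing, so
#'   edge-outlined objects become solid regions.
#' @param max_hole_area only holes up to this many pixels are filled
#'   (`Inf` fills all); keeps large muscle regions enclosed by network
#'   loops from being swallowed.
#' @param min_object_area components smaller than this many pixels are
#'   removed.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(clahe_clip_limit = 0.01,
                                clahe_tiles = c(8, 8),
                                edge_threshold_method = c("otsu", "fixed"),
                                edge_threshold_value = NULL,
                                despeckle_area = 6,
                                se_radius_dilate = 2,
                                se_radius_erode = 2,
                                fill_holes = TRUE,
                                max_hole_area = 500,
                                min_object_area = 20) {
  edge_threshold_method <- match.arg(edge_threshold_method)
  stopifnot(clahe_clip_limit > 0, length(clahe_tiles) == 2,
            all(clahe_tiles >= 1), se_radius_dilate >= 0,
            se_radius_erode >= 0, min_object_area >= 1)
  if (edge_threshold_method == "fixed" && is.null(edge_threshold_value))
    stop("edge_threshold_value required when edge_threshold_method = 'fixed'")
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tiles = as.integer(clahe_tiles),
                 edge_threshold_method = edge_threshold_method,
                 edge_threshold_value = edge_threshold_value,
                 despeckle_area = despeckle_area,
                 se_radius_dilate = se_radius_dilate,
                 se_radius_erode = se_radius_erode,
                 fill_holes = isTRUE(fill_holes),
                 max_hole_area = max_hole_area,
                 min_object_area = min_object_area),
            class = "segmentation_params")
}

#' Contrast-limited adaptive histogram equalization of one band image
#'
#' Tile-wise clipped histogram equalization (CLAHE). The image is padded by
#' edge replication to a multiple of the tile grid, equalized, cropped back
#' and clamped to `[0, 1]`. Constant images are returned unchanged (there is
#' no contrast to enhance). Deterministic.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param params a [segmentation_params()] object.
#' @return numeric matrix in `[0, 1]`.
#' @export
enhance_contrast <- function(img, params = segmentation_params()) {
  stopifnot(is.matrix(img))
  if (min(img) < 0 || max(img) > 1)
    stop("image values must lie in [0, 1]")
  ny <- params$clahe_tiles[1]; nx <- params$clahe_tiles[2]
  H <- nrow(img); W <- ncol(img)
  if (H < ny || W < nx)
    stop("image (", H, " x ", W, ") smaller than one ", ny, " x ", nx,
         " tile grid cell")
  if (diff(range(img)) == 0) return(img)
  Hp <- ceiling(H / ny) * ny
  Wp <- ceiling(W / nx) * nx
  pad <- img[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W))]
  # EBImage's first dimension is x; tiles are (nx along dim1, ny along dim2)
  out <- EBImage::clahe(pad, nx = ny, ny = nx, bins = 256,
                        limit = params$clahe_clip_limit * 256)
  out <- out[seq_len(H), seq_len(W)]
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Prewitt gradient magnitude
#'
#' Convolves the image with the two 3 x 3 Prewitt kernels and returns
#' `sqrt(Gx^2 + Gy^2)`. Borders are handled by edge replication, so a
#' constant image has zero gradient everywhere including the frame.
#'
#' @param img numeric matrix, at least 3 x 3.
#' @return numeric matrix of gradient magnitudes, same size.
#' @export
prewitt_gradient <- function(img) {
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  if (H < 3 || W < 3) stop("image must be at least 3 x 3")
  P <- img[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  s <- function(i, j) P[i:(i + H - 1), j:(j + W - 1)]
  gx <- (s(1, 3) + s(2, 3) + s(3, 3)) - (s(1, 1) + s(2, 1) + s(3, 1))
  gy <- (s(3, 1) + s(3, 2) + s(3, 3)) - (s(1, 1) + s(1, 2) + s(1, 3))
  sqrt(gx^2 + gy^2)
}

#' Otsu threshold of a non-negative image
#'
#' Histogram-based Otsu threshold: values are binned into `n_bins`
#' equal-width bins over their range and the inter-bin cut maximizing the
#' between-class variance is returned (ties broken toward the lower
#' threshold).
#'
#' @param x numeric vector or matrix.
#' @param n_bins number of histogram bins.
#' @return the threshold value, on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(hi)
  w <- (hi - lo) / n_bins
  bin <- pmin(pmax(floor((v - lo) / w) + 1L, 1L), n_bins)
  cnt <- tabulate(bin, n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * w
  n <- length(v)
  w0 <- cumsum(cnt)[-n_bins] / n
  m0 <- cumsum(cnt * mids)[-n_bins] / n
  mu <- sum(cnt * mids) / n
  # between-class variance at each candidate cut (after bin k)
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  lo + k * w
}

#' Threshold a gradient image into a binary edge mask
#'
#' Pixels with gradient magnitude greater than or equal to the threshold
#' (Otsu by default, or a fixed value) are foreground. An all-zero gradient
#' yields an empty mask with a warning.
#'
#' @param gradient non-negative numeric matrix.
#' @param params a [segmentation_params()] object.
#' @return logical matrix.
#' @export
binarize_edges <- function(gradient, params = segmentation_params()) {
  stopifnot(is.matrix(gradient))
  if (any(gradient < 0)) stop("gradient must be non-negative")
  if (max(gradient) == 0) {
    warning("all-zero gradient; returning empty mask")
    return(matrix(FALSE, nrow(gradient), ncol(gradient)))
  }
  thr <- if (params$edge_threshold_method == "fixed")
    params$edge_threshold_value else otsu_threshold(gradient)
  gradient >= thr
}

#' Morphological cleaning of a binary edge mask
#'
#' Removal of sub-`despeckle_area` noise specks, then closing (dilation
#' with a disc of radius `se_radius_dilate`, then erosion
#' with a disc of radius `se_radius_erode`), optional filling of enclosed
#' holes (so edge-outlined regions become solid objects), and removal of
#' 8-connected components smaller than `min_object_area` pixels.
#'
#' @param mask logical matrix.
#' @param params a [segmentation_params()] object.
#' @return logical matrix.
#' @export
morphological_clean <- function(mask, params = segmentation_params()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (params$despeckle_area > 0 && any(mask)) {
    lab <- .label8_cpp(mask)
    sizes <- tabulate(lab[lab > 0L])
    mask <- mask & matrix(lab %in% which(sizes > params$despeckle_area),
                          nrow(mask), ncol(mask))
  }
  m <- mask * 1
  if (params$se_radius_dilate > 0)
    m <- EBImage::dilate(m, EBImage::makeBrush(
      2L * params$se_radius_dilate + 1L, "disc"))
  if (params$se_radius_erode > 0)
    m <- EBImage::erode(m, EBImage::makeBrush(
      2L * params$se_radius_erode + 1L, "disc"))
  m <- m > 0.5
  if (params$fill_holes && any(m)) m <- fill_small_holes(m, params$max_hole_area)
  if (!any(m)) return(m)
  lab <- .label8_cpp(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_object_area)
  m & matrix(lab %in% keep, nrow(m), ncol(m))
}

# fill background components that touch no image border and are at most
# max_area pixels (4-connected holes, complementary to 8-connected objects)
fill_small_holes <- function(mask, max_area) {
  if (!is.finite(max_area)) {
    filled <- EBImage::fillHull(mask * 1) > 0.5
    return(filled)
  }
  bg <- .label8_cpp(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0L])
  fillable <- setdiff(which(sizes <= max_area), border)
  if (length(fillable)) mask[bg %in% fillable] <- TRUE
  mask
}

#' 8-connected component labeling
#'
#' @param mask logical matrix.
#' @param band_index optional band index carried along for bookkeeping.
#' @return object of class `labeled_image`: list with the integer `labels`
#'   matrix (0 = background, objects numbered consecutively 1..n in
#'   column-major scan order), `n_objects`, and `band_index`.
#' @export
label_objects <- function(mask, band_index = NA_integer_) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- .label8_cpp(mask)
  structure(list(labels = lab, n_objects = max(lab),
                 band_index = band_index),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %d x %d, %d objects (band %s)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects,
              as.character(x$band_index)))
  invisible(x)
}

#' Segment intramuscular connective tissue in every band of a cube
#'
#' For each band independently: [enhance_contrast()], [prewitt_gradient()],
#' [binarize_edges()], [morphological_clean()], then 8-connected component
#' labeling. The whole chain is deterministic (no random state).
#'
#' @param cube a calibrated [msi_cube()].
#' @param params a [segmentation_params()] object.
#' @return list of [label_objects()] results, one per band.
#' @export
segment_imct <- function(cube, params = segmentation_params()) {
  stopifnot(inherits(cube, "msi_cube"))
  lapply(seq_len(dim(cube$pixels)[3]), function(b) {
    img <- enhance_contrast(cube$pixels[, , b], params)
    grad <- prewitt_gradient(img)
    mask <- suppressWarnings(binarize_edges(grad, params))
    mask <- morphological_clean(mask, params)
    label_objects(mask, band_index = b)
  })
}
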