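# Small scenes used across the suite: ~1 s to generate and segment.
small_scene_params <- function(seed = 1L, ...) {
  args <- list(image_height = 96, image_width = 120, pixel_size = 500,
               n_fibers = 12, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_params, args)
}

# mid-size scene matching the simulated-dataset defaults used for
# recovery runs (288 x 352 px at 167 um/px)
recovery_scene_size <- list(image_height = 288, image_width = 352,
                            pixel_size = 167)

# round doubles to the nearest IEEE single-precision value (independent of
# the package's internal helper)
snap32 <- function(x) {
  v <- readBin(writeBin(as.vector(as.double(x)), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  dim(v) <- dim(x)
  v
}

# Dice coefficient of two binary masks
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Shannon entropy of a [0,1] image over a fixed 256-bin histogram
entropy256 <- function(img) {
  cnt <- tabulate(pmin(floor(img * 256) + 1L, 256L), 256L)
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}
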