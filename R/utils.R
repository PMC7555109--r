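#' Derive a reproducible sub-seed from a master seed
#'
#' Fixed multiplicative hash mapping a `(master, index)` pair to an integer
#' in `[0, 2^31 - 2]`. Used everywhere a master seed has to spawn
#' independent per-sample or per-stage random streams, so that e.g. sample
#' `i` of a simulated dataset is reproducible on its own.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), length(master) == 1)
  # exact in doubles: |master| < 2^31, index < 2^21 keeps products < 2^53
  v <- (abs(as.double(master)) * 48271 + as.double(index) * 2654435761) %%
    2147483647
  as.integer(v)
}

# Run code under a fixed seed with pinned RNG kind, restoring global state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# Round doubles to the nearest IEEE single-precision value.
snap_float32 <- function(x) {
  d <- dim(x)
  v <- readBin(writeBin(as.vector(as.double(x)), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  if (!is.null(d)) dim(v) <- d
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
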