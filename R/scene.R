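#' Default band wavelengths (nm)
#'
#' Nineteen LED center wavelengths spanning 405-1050 nm, matching the
#' visible/near-infrared multispectral instruments this package targets.
#'
#' @return numeric vector of length 19, strictly increasing.
#' @export
default_wavelengths <- function() {
  c(405, 435, 450, 470, 505, 525, 570, 590, 630, 645,
    660, 700, 780, 850, 870, 890, 910, 940, 1050)
}

# anchor reflectance curves at the default wavelengths; interpolated for
# other band sets. Shapes: small local peak near 505 nm, shoulder near
# 645 nm, global maximum near 850 nm; fat shows the ~940 nm lipid dip.
.spectra_anchors <- list(
  lean = c(0.270, 0.295, 0.310, 0.330, 0.360, 0.345, 0.320, 0.315, 0.340,
           0.365, 0.385, 0.430, 0.520, 0.600, 0.595, 0.588, 0.575, 0.555,
           0.510),
  connective = c(0.470, 0.500, 0.515, 0.530, 0.550, 0.540, 0.525, 0.520,
                 0.540, 0.555, 0.570, 0.605, 0.670, 0.720, 0.715, 0.710,
                 0.700, 0.685, 0.650),
  fat = c(0.550, 0.580, 0.600, 0.620, 0.645, 0.640, 0.630, 0.628, 0.638,
          0.648, 0.660, 0.685, 0.720, 0.740, 0.735, 0.730, 0.710, 0.660,
          0.700))

#' Reference reflectance spectra of the three tissue classes
#'
#' Reflectance per band, in `[0, 1]`, for lean muscle, connective tissue and
#' marbling fat. Each curve has a small local maximum near 500 nm, a
#' shoulder near 645 nm and its global maximum near 850 nm; connective
#' tissue and fat are brighter than lean muscle across the visible range,
#' which is what makes the connective network segmentable.
#'
#' @param wavelengths band wavelengths in nm (default
#'   [default_wavelengths()]); curves are interpolated to these bands.
#' @return object of class `tissue_spectra`: list with numeric vectors
#'   `lean`, `connective`, `fat`.
#' @export
tissue_spectra <- function(wavelengths = default_wavelengths()) {
  stopifnot(all(diff(wavelengths) > 0))
  wl0 <- default_wavelengths()
  out <- lapply(.spectra_anchors, function(v)
    stats::approx(wl0, v, xout = wavelengths, rule = 2)$y)
  structure(out, class = "tissue_spectra")
}

#' Parameters of a synthetic multispectral meat scene
#'
#' Controls the simulated connective-tissue network (a branching perimysium
#' strand network dilated to a target width, and an endomysium drawn as the
#' boundaries of a seeded Voronoi fiber tessellation), the marbling fat
#' blobs placed along fixed marbling seams, the per-tissue spectra, a smooth
#' multiplicative illumination field, and additive Gaussian noise.
#'
#' @param image_height,image_width image size in pixels.
#' @param wavelengths band wavelengths in nm, strictly increasing.
#' @param pixel_size pixel edge in micrometers per pixel. The default 86
#'   corresponds to a ~6 cm x 5 cm field of view at 700 x 575 pixels.
#' @param perimysium_density dimensionless intensity of the strand network;
#'   the number of strands drawn is proportional to it (and to image size),
#'   with density 1 giving roughly a 10\% area fraction at the default
#'   strand width.
#' @param perimysium_width_px target strand width in pixels (realized as the
#'   nearest odd disc diameter).
#' @param n_fibers number of fiber cells in the endomysium tessellation.
#' @param fat_fraction target fraction of image area occupied by marbling,
#'   in `[0, 1)`.
#' @param noise_sd additive Gaussian noise standard deviation, reflectance
#'   units.
#' @param illumination_amplitude amplitude of the smooth multiplicative
#'   illumination field (0 disables it).
#' @param n_spots number of dark myoglobin-rich texture spots in the lean
#'   tissue; default (`NULL`) scales with image area (one per 300 px).
#'   Set 0 for perfectly homogeneous lean tissue.
#' @param spectra a [tissue_spectra()] object (default built for
#'   `wavelengths`).
#' @param seed integer seed; identical parameters (including seed) give
#'   bit-identical scenes.
#' @param noise_seed separate seed for the noise realization; defaults to
#'   `seed`, so a scene is fully determined by its parameters.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_height = 575, image_width = 700,
                         wavelengths = default_wavelengths(),
                         pixel_size = 86,
                         perimysium_density = 1.0,
                         perimysium_width_px = 4,
                         n_fibers = 250,
                         fat_fraction = 0.06,
                         noise_sd = 0.01,
                         illumination_amplitude = 0.05,
                         n_spots = NULL,
                         spectra = NULL,
                         seed = 1L,
                         noise_seed = NULL) {
  stopifnot(image_height > 0, image_width > 0, pixel_size > 0,
            n_fibers > 0, perimysium_density >= 0, perimysium_width_px >= 1,
            noise_sd >= 0, illumination_amplitude >= 0)
  if (fat_fraction < 0 || fat_fraction >= 1)
    stop("fat_fraction must be in [0, 1)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (image_height * image_width / n_fibers < 4)
    stop("n_fibers too large: mean fiber cell area below 4 pixels ",
         "(degenerate tessellation)")
  if (is.null(spectra)) spectra <- tissue_spectra(wavelengths)
  stopifnot(length(spectra$lean) == length(wavelengths))
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 wavelengths = wavelengths,
                 n_bands = length(wavelengths),
                 pixel_size = pixel_size,
                 perimysium_density = perimysium_density,
                 perimysium_width_px = perimysium_width_px,
                 n_fibers = as.integer(n_fibers),
                 fat_fraction = fat_fraction,
                 noise_sd = noise_sd,
                 illumination_amplitude = illumination_amplitude,
                 n_spots = if (is.null(n_spots)) NULL else as.integer(n_spots),
                 spectra = spectra,
                 seed = as.integer(seed),
                 noise_seed = as.integer(noise_seed %||% seed)),
            class = "scene_params")
}

# rasterize a polyline (matrix of row, col doubles) into linear indices.
# dash_pattern = c(on, off) renders broken streaks (connective seams at
# MSI resolution appear as discontinuous flecks, not solid lines).
rasterize_polyline <- function(pts, H, W, dash_pattern = NULL) {
  if (nrow(pts) < 2) return(integer(0))
  out <- vector("list", nrow(pts) - 1)
  arc0 <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2, ceiling(2 * max(abs(b - a))))
    t <- seq(0, 1, length.out = n)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]), arc0 + t * len)
    arc0 <- arc0 + len
    out[[i]] <- seg
  }
  xy <- do.call(rbind, out)
  if (!is.null(dash_pattern)) {
    period <- sum(dash_pattern)
    xy <- xy[xy[, 3] %% period < dash_pattern[1], , drop = FALSE]
  }
  xy <- round(xy[, 1:2, drop = FALSE])
  keep <- xy[, 1] >= 1 & xy[, 1] <= H & xy[, 2] >= 1 & xy[, 2] <= W
  xy <- xy[keep, , drop = FALSE]
  unique((xy[, 2] - 1) * H + xy[, 1])
}

# anatomical muscle-fiber axis (radians in walk space); perimysium seams
# run roughly parallel to it, as in a consistently oriented muscle cut
FIBER_AXIS <- 25 * pi / 180

# one perimysium seam under the current RNG; returns linear pixel indices.
# Seams follow the global fiber axis with small meander, so their flecks
# concentrate in a reproducible orientation band; occasional branches cross
# at wider angles.
draw_strand <- function(H, W) {
  dash <- c(runif(1, 9, 12), runif(1, 14, 16))
  axis <- FIBER_AXIS + rnorm(1, 0, 0.12)
  step <- 6
  nmax <- ceiling(1.3 * (H + W) / step)
  walk <- function(pos, ang, dir) {
    pts <- matrix(NA_real_, nmax + 1, 2)
    pts[1, ] <- pos
    used <- 1
    for (i in seq_len(nmax)) {
      ang <- ang + rnorm(1, 0, 0.06)
      pos <- pos + dir * step * c(sin(ang), cos(ang))
      used <- used + 1
      pts[used, ] <- pos
      if (pos[1] < -10 || pos[1] > H + 10 ||
          pos[2] < -10 || pos[2] > W + 10) break
    }
    pts[seq_len(used), , drop = FALSE]
  }
  # full image crossing: pick the seam by its perpendicular offset so every
  # strand spans the field of view and contributes a comparable fleck count
  D <- H * abs(cos(axis)) + W * abs(sin(axis))
  u <- runif(1, -D / 2, D / 2)
  c0 <- c(H / 2 + u * cos(axis), W / 2 - u * sin(axis))
  fwd <- walk(c0, axis, 1)
  bwd <- walk(c0, axis, -1)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               fwd[-1, , drop = FALSE])
  idx <- rasterize_polyline(pts, H, W, dash)
  # occasional crossing branch at a wider angle
  if (runif(1) < 0.25 && nrow(pts) > 4) {
    j <- sample.int(nrow(pts) - 2, 1) + 1
    bang <- axis + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1)
    bpts <- walk(pts[j, ], bang, 1)
    bn <- min(nrow(bpts), ceiling(nmax / 3))
    idx <- union(idx, rasterize_polyline(bpts[seq_len(bn), , drop = FALSE],
                                         H, W, dash))
  }
  idx
}

disc_brush <- function(width_px) {
  size <- 2L * floor(width_px / 2) + 1L
  if (size < 3L) return(NULL)
  EBImage::makeBrush(size, shape = "disc")
}

# stamp a rough disc of radius r at (r0, c0) into logical matrix m
stamp_blob <- function(m, r0, c0, r) {
  H <- nrow(m); W <- ncol(m)
  r1 <- max(1, floor(r0 - r)); r2 <- min(H, ceiling(r0 + r))
  c1 <- max(1, floor(c0 - r)); c2 <- min(W, ceiling(c0 + r))
  if (r1 > r2 || c1 > c2) return(m)
  rr <- r1:r2
  cc <- c1:c2
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  m[rr, cc] <- m[rr, cc] | (d2 <= r^2)
  m
}

# number of strand trajectories that host marbling, independent of
# perimysium_density so the fat mask does not move when the network grows
MARBLING_SEAMS <- 20L

#' Generate a synthetic multispectral meat scene with exact ground truth
#'
#' Draws a branching perimysium network (random polylines dilated to the
#' target width), an endomysium as the 1-2 px boundaries of a seeded
#' Voronoi fiber tessellation, and marbling fat blobs stamped along fixed
#' marbling seams until the target fat area is reached. The cube is the
#' linear mixture of the three tissue spectra over the masks, modulated by a
#' smooth illumination field, plus additive Gaussian noise, clipped to
#' `[0, 1]`. Ground truth is measured from the generated masks (see
#' [measure_network()]); the three biochemical targets are affine maps of
#' the realized fat-area fraction and perimysium area onto the reference
#' ranges in [biochemical_ranges()].
#'
#' Masks are mutually exclusive and exhaustive with priority
#' fat > perimysium > endomysium > lean.
#'
#' @param params a [scene_params()] object.
#' @return object of class `msi_scene`: list with `cube` ([msi_cube()]),
#'   `truth` ([scene_truth()]), and `masks` (logical matrices `lean`,
#'   `perimysium`, `endomysium`, `fat`, plus the integer `fiber_cells`
#'   tessellation label matrix).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$image_height; W <- params$image_width
  A <- H * W
  seed <- params$seed

  # perimysium centerline network: strand s has its own derived stream, so
  # raising the density adds strands without moving existing ones. Strand
  # count scales with A/(H+W) (strand length scales with H+W), keeping the
  # realized area fraction roughly independent of image size.
  n_strands <- max(0L, as.integer(round(
    params$perimysium_density * 0.08 * A / (H + W))))
  center <- matrix(FALSE, H, W)
  for (s in seq_len(n_strands))
    center[local_seed(derive_seed(seed, 1000 + s),
                      draw_strand(H, W))] <- TRUE
  # marbling seams: separate fiber-axis-parallel trajectories, independent
  # of the rendered perimysium so the fat mask is unaffected by density
  seam_idx <- vector("list", MARBLING_SEAMS)
  for (s in seq_len(MARBLING_SEAMS))
    seam_idx[[s]] <- local_seed(derive_seed(seed, 2000 + s),
                                draw_strand(H, W))
  brush <- disc_brush(params$perimysium_width_px)
  peri <- if (is.null(brush)) center else
    EBImage::dilate(center * 1, brush) > 0.5

  # endomysium: Voronoi cell boundaries
  cells <- local_seed(derive_seed(seed, 2), {
    sr <- runif(params$n_fibers, 1, H)
    sc <- runif(params$n_fibers, 1, W)
    .voronoi_cpp(H, W, as.integer(round(sr)), as.integer(round(sc)))
  })
  endo <- cells != cells[c(2:H, H), ] | cells != cells[, c(2:W, W)]

  # marbling fat: discrete non-overlapping flecks stamped along the fixed
  # seams (hard-core placement keeps flecks separate, so the number of fat
  # objects scales with the fat fraction instead of saturating by merging)
  fat <- matrix(FALSE, H, W)
  target_fat <- round(params$fat_fraction * A)
  if (target_fat > 0) {
    seam <- unique(unlist(seam_idx))
    # standoff from the rendered perimysium so flecks stay discrete
    peri_dist <- if (any(peri)) EBImage::distmap((!peri) * 1)
      else matrix(Inf, H, W)
    local_seed(derive_seed(seed, 3), {
      centers <- matrix(numeric(0), 0, 2)
      radii <- numeric(0)
      guard <- 0
      rejects <- 0
      covered <- 0
      while (covered < target_fat && guard < 50000) {
        guard <- guard + 1
        if (rejects < 300) {
          p <- seam[sample.int(length(seam), 1)]
          r0 <- ((p - 1) %% H) + 1 + rnorm(1, 0, 8)
          c0 <- ((p - 1) %/% H) + 1 + rnorm(1, 0, 8)
        } else {  # seams saturated: spill-over marbling anywhere
          r0 <- runif(1, 1, H)
          c0 <- runif(1, 1, W)
        }
        r <- runif(1, 2.2, 3.2)
        ri <- min(max(round(r0), 1), H)
        ci <- min(max(round(c0), 1), W)
        if (peri_dist[ri, ci] <= r + 8) {
          rejects <- rejects + 1
          next
        }
        if (nrow(centers) > 0 &&
            any((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2 <
                (radii + r + 6)^2)) {
          rejects <- rejects + 1
          next
        }
        rejects <- 0
        centers <- rbind(centers, c(r0, c0))
        radii <- c(radii, r)
        before <- fat
        fat <- stamp_blob(fat, r0, c0, r)
        covered <- covered + sum(fat) - sum(before)
      }
    })
  }

  # priority fat > perimysium > endomysium > lean
  peri <- peri & !fat
  endo <- endo & !fat & !peri
  lean <- !(fat | peri | endo)

  # dark myoglobin-rich texture spots within the lean tissue: a stable
  # population (count proportional to image area, independent of the other
  # parameters) of small spots that are dark in the visible range and fade
  # toward the lean reflectance in the NIR. They give every scene a
  # reference object population with a distinct spectral detection profile;
  # in the masks they remain lean tissue (reflectance variation, not a
  # tissue class)
  n_spots <- params$n_spots %||% round(A / 300)
  spot <- matrix(FALSE, H, W)
  if (n_spots > 0) {
    dist_free <- EBImage::distmap((!(peri | fat)) * 1)
    local_seed(derive_seed(seed, 6), {
      sc_centers <- matrix(numeric(0), 0, 2)
      placed <- 0
      guard <- 0
      while (placed < n_spots && guard < 30 * n_spots) {
        guard <- guard + 1
        r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
        r <- runif(1, 1.8, 2.8)
        if (dist_free[round(r0), round(c0)] <= r + 8) next
        if (nrow(sc_centers) > 0 &&
            any((sc_centers[, 1] - r0)^2 + (sc_centers[, 2] - c0)^2 <
                (r + 2.8 + 6)^2)) next
        sc_centers <- rbind(sc_centers, c(r0, c0))
        spot <- stamp_blob(spot, r0, c0, r)
        placed <- placed + 1
      }
    })
    spot <- spot & lean
  }

  # mix spectra over masks, illumination field, noise. Endomysium sheaths
  # are thinner than a pixel, so their pixels get a partial-volume blend of
  # the connective and lean spectra rather than pure connective reflectance.
  sp <- params$spectra
  endo_pv <- 0.08
  illum <- if (params$illumination_amplitude > 0) {
    local_seed(derive_seed(seed, 4), {
      cy <- runif(1, 0.3 * H, 0.7 * H); cx <- runif(1, 0.3 * W, 0.7 * W)
      sig <- 0.6 * min(H, W)
      f <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+")
      1 + params$illumination_amplitude * (exp(-f / (2 * sig^2)) - 0.5)
    })
  } else matrix(1, H, W)
  px <- array(0, c(H, W, params$n_bands))
  wl <- params$wavelengths
  spot_factor <- 0.40 + 0.55 * (wl - min(wl)) / max(max(wl) - min(wl), 1)
  for (b in seq_len(params$n_bands)) {
    econ <- sp$lean[b] + endo_pv * (sp$connective[b] - sp$lean[b])
    img <- lean * sp$lean[b] + peri * sp$connective[b] + endo * econ +
      fat * sp$fat[b]
    img <- img - spot * sp$lean[b] * (1 - spot_factor[b])
    px[, , b] <- img * illum
  }
  if (params$noise_sd > 0) {
    px <- px + local_seed(derive_seed(params$noise_seed, 5),
                          array(rnorm(A * params$n_bands, 0,
                                      params$noise_sd),
                                dim(px)))
  }
  px[px < 0] <- 0
  px[px > 1] <- 1

  masks <- list(lean = lean, perimysium = peri, endomysium = endo,
                fat = fat, fiber_cells = cells)
  truth <- scene_truth_from_masks(masks, params$pixel_size)
  structure(list(cube = msi_cube(px, params$wavelengths, params$pixel_size),
                 truth = truth, masks = masks, params = params),
            class = "msi_scene")
}

#' Measure a connective-tissue network mask
#'
#' Computes the three geometric descriptors used as ground truth: area
#' percentage (`100 * foreground / total pixels`), total skeleton length per
#' unit image area (skeleton pixel count times pixel size, in mm per mm^2 of
#' image), and mean width (twice the mean Euclidean distance-transform value
#' sampled along the skeleton, in micrometers).
#'
#' @param mask logical matrix of the network.
#' @param pixel_size pixel edge in micrometers.
#' @return list with `area_pct`, `length_mm_per_mm2`, `width_um`.
#' @export
measure_network <- function(mask, pixel_size) {
  stopifnot(is.logical(mask), is.matrix(mask), pixel_size > 0)
  A <- length(mask)
  area_pct <- 100 * sum(mask) / A
  skel <- skeletonize(mask)
  area_mm2 <- A * (pixel_size / 1000)^2
  len <- sum(skel) * pixel_size / 1000 / area_mm2
  width <- if (any(skel)) {
    dm <- EBImage::distmap(mask * 1)
    2 * mean(dm[skel]) * pixel_size
  } else 0
  list(area_pct = area_pct, length_mm_per_mm2 = len, width_um = width)
}

#' Reduce a binary mask to its 1-pixel skeleton
#'
#' Zhang-Suen iterative thinning, deterministic.
#'
#' @param mask logical matrix.
#' @return logical matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .thin_cpp(mask)
}

#' Reference ranges of the biochemical targets
#'
#' Min-max ranges (dry-matter basis) that the simulator's affine maps span:
#' intramuscular fat in g/100 g DM, total and insoluble collagen in mg
#' hydroxyproline per g DM. The driver scales are the realized fat-area
#' fraction (full scale at 0.15) and the perimysium area percentage (full
#' scale at 20%).
#'
#' @return named list of `c(min, max)` pairs plus the two driver scales.
#' @export
biochemical_ranges <- function() {
  list(imf = c(3.61, 22.82),
       total_collagen = c(2.94, 10.45),
       insoluble_collagen = c(2.01, 6.87),
       fat_fraction_scale = 0.15,
       perimysium_area_scale = 20)
}

#' Ground truth of a synthetic scene, measured from its masks
#'
#' @param masks list with logical `perimysium`, `endomysium`, `fat` masks
#'   and the integer `fiber_cells` tessellation labels.
#' @param pixel_size pixel edge in micrometers.
#' @return object of class `scene_truth`: named numeric vector with the ten
#'   target parameters (`perimysium_area` \%, `perimysium_length` mm/mm^2,
#'   `perimysium_width` um, the same three for the endomysium,
#'   `fiber_density` per mm^2, `imf` g/100g DM, `total_collagen` and
#'   `insoluble_collagen` mg OH-Prol/g DM).
#' @export
scene_truth_from_masks <- function(masks, pixel_size) {
  H <- nrow(masks$perimysium); W <- ncol(masks$perimysium)
  area_mm2 <- H * W * (pixel_size / 1000)^2
  p <- measure_network(masks$perimysium, pixel_size)
  e <- measure_network(masks$endomysium, pixel_size)
  n_cells <- length(unique(as.vector(masks$fiber_cells)))
  ff <- sum(masks$fat) / (H * W)
  rg <- biochemical_ranges()
  amap <- function(range, x, scale)
    range[1] + diff(range) * min(x / scale, 1)
  tr <- c(perimysium_area = p$area_pct,
          perimysium_length = p$length_mm_per_mm2,
          perimysium_width = p$width_um,
          endomysium_area = e$area_pct,
          endomysium_length = e$length_mm_per_mm2,
          endomysium_width = e$width_um,
          fiber_density = n_cells / area_mm2,
          imf = amap(rg$imf, ff, rg$fat_fraction_scale),
          total_collagen = amap(rg$total_collagen, p$area_pct,
                                rg$perimysium_area_scale),
          insoluble_collagen = amap(rg$insoluble_collagen, p$area_pct,
                                    rg$perimysium_area_scale))
  structure(tr, fat_area_fraction = ff, class = "scene_truth")
}

#' Names and units of the ten target parameters
#' @return data frame with columns `name` and `unit`.
#' @export
target_units <- function() {
  data.frame(
    name = c("perimysium_area", "perimysium_length", "perimysium_width",
             "endomysium_area", "endomysium_length", "endomysium_width",
             "fiber_density", "imf", "total_collagen", "insoluble_collagen"),
    unit = c("% of image area", "mm/mm2 of image", "um",
             "% of image area", "mm/mm2 of image", "um",
             "fibers/mm2", "g/100 g DM", "mg OH-Prol/g DM",
             "mg OH-Prol/g DM"))
}

#' Default per-sample parameter ranges for simulated datasets
#'
#' Uniform sampling ranges used by [generate_dataset()]: perimysium density
#' 0.3-1.7, strand width 3-6 px, fat fraction 0-0.15 (so the affine map
#' spans the full intramuscular-fat reference range), and a fiber count
#' giving mean cell areas between 500 and 900 px.
#'
#' @param image_height,image_width scene size in pixels.
#' @return named list of `c(min, max)` ranges.
#' @export
default_param_ranges <- function(image_height = 575, image_width = 700) {
  A <- image_height * image_width
  list(perimysium_density = c(0.3, 1.2),
       perimysium_width_px = c(3.5, 4.5),
       n_fibers = c(round(A / 2000), round(A / 1100)),
       fat_fraction = c(0, 0.15))
}

#' Draw per-sample scene parameters from ranges
#'
#' Sample `i` uses the derived seed `derive_seed(seed, i)`, so any sample is
#' reproducible in isolation. The geometry seed of each scene is a hash of
#' its drawn parameter values (so identical parameters give identical
#' geometry) while the noise realization is seeded per sample.
#'
#' @param n_samples number of samples (>= 2 in [generate_dataset()]).
#' @param param_ranges named list of `c(min, max)` ranges as in
#'   [default_param_ranges()].
#' @param seed master seed.
#' @param ... fixed arguments passed to every [scene_params()] call
#'   (e.g. `image_height`, `image_width`, `pixel_size`, `noise_sd`).
#' @return list of [scene_params()] objects.
#' @export
draw_scene_params <- function(n_samples, param_ranges = NULL, seed = 1L,
                              ...) {
  fixed <- list(...)
  hh <- fixed$image_height %||% 575
  ww <- fixed$image_width %||% 700
  if (is.null(param_ranges)) param_ranges <- default_param_ranges(hh, ww)
  for (nm in names(param_ranges)) {
    r <- param_ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("invalid range for '", nm, "': min must not exceed max")
  }
  lapply(seq_len(n_samples), function(i) {
    si <- derive_seed(seed, i)
    drawn <- local_seed(si, {
      d <- lapply(param_ranges, function(r) runif(1, r[1], r[2]))
      d$perimysium_width_px <- round(d$perimysium_width_px)
      d$n_fibers <- round(d$n_fibers)
      d
    })
    key <- 0
    for (v in unlist(drawn)) key <- (key * 31 + round(v * 1e7)) %% 2147483647
    do.call(scene_params,
            c(drawn, fixed,
              list(seed = derive_seed(seed, key %% 1048576),
                   noise_seed = si)))
  })
}

#' Generate a simulated multispectral dataset with ground-truth targets
#'
#' Draws per-sample scene parameters uniformly from `param_ranges`,
#' generates each scene, and collects the ten ground-truth target values
#' into one table (one row per sample).
#'
#' @inheritParams draw_scene_params
#' @param keep_cubes keep the generated cubes in the returned object
#'   (disable for large runs and stream through `scene_handler` instead).
#' @param scene_handler optional `function(i, scene)` called on each scene
#'   as it is generated.
#' @return object of class `msi_dataset`: list with `targets` (data frame,
#'   `n_samples` x 10), `params` (list of [scene_params()]), `scenes` (list
#'   of `msi_scene` or `NULL`), and `seed`.
#' @export
generate_dataset <- function(n_samples, param_ranges = NULL, seed = 1L,
                             keep_cubes = TRUE, scene_handler = NULL, ...) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  plist <- draw_scene_params(n_samples, param_ranges, seed, ...)
  targets <- matrix(NA_real_, n_samples, 10,
                    dimnames = list(NULL, target_units()$name))
  scenes <- if (keep_cubes) vector("list", n_samples) else NULL
  for (i in seq_len(n_samples)) {
    sc <- generate_scene(plist[[i]])
    targets[i, ] <- as.numeric(sc$truth)
    if (keep_cubes) scenes[[i]] <- sc
    if (!is.null(scene_handler)) scene_handler(i, sc)
  }
  structure(list(targets = as.data.frame(targets), params = plist,
                 scenes = scenes, seed = seed),
            class = "msi_dataset")
}

#' Write a target table as CSV with units in a header comment
#'
#' @param targets data frame of targets (as in [generate_dataset()]).
#' @param path output CSV path.
#' @export
write_targets <- function(targets, path) {
  tu <- target_units()
  hdr <- paste0("# ", paste(sprintf("%s [%s]", tu$name, tu$unit),
                            collapse = "; "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(targets, con, row.names = FALSE)
  invisible(path)
}

#' Acquisition bookkeeping for a multi-animal imaging study
#'
#' @param n_animals number of animals.
#' @param muscles_per_animal muscles sampled per animal.
#' @param sides_per_muscle acquisitions (cubes) per muscle.
#' @param n_bands spectral bands per cube.
#' @return list with `n_muscle_samples`, `n_cubes`, `n_band_images`.
#' @export
acquisition_plan <- function(n_animals, muscles_per_animal = 3,
                             sides_per_muscle = 2, n_bands = 19) {
  n_samples <- n_animals * muscles_per_animal
  n_cubes <- n_samples * sides_per_muscle
  list(n_muscle_samples = n_samples,
       n_cubes = n_cubes,
       n_band_images = n_cubes * n_bands)
}
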