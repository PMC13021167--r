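# Bidirectional modality conversion: synthetic DRAQ5&Eosin from H&E (the
# transfer-learning recipe) and synthetic H&E from DRAQ5&Eosin (Beer-Lambert
# recoloring with gamma > 1).

#' Parameters for H&E -> synthetic DRAQ5/Eosin conversion
#'
#' Defaults follow the published recipe: additive Gaussian noise of variance
#' 1e-4 on the unit scale, smoothing sigma 0.5, 12-bit scaling (4095),
#' 1-pixel disk erosion of the nuclei mask and 1-pixel disk dilation of the
#' intensity planes.
#' @param noise_variance variance of i.i.d. Gaussian noise on the `[0,1]` scale.
#' @param smoothing_sigma Gaussian filter sigma (pixels).
#' @param scale_max intensity scale factor, `2^bit_depth - 1` of the target.
#' @param erosion_radius_px,dilation_radius_px disk radii for nuclei-mask
#'   erosion and intensity dilation.
#' @param rng_seed integer seed; equal seeds give bit-identical outputs.
#' @return a `SyntheticDEParams` list.
#' @export
synthetic_de_params <- function(noise_variance = 1e-4, smoothing_sigma = 0.5,
                                scale_max = 4095L, erosion_radius_px = 1L,
                                dilation_radius_px = 1L, rng_seed = 1L) {
  stopifnot(noise_variance >= 0, smoothing_sigma >= 0, scale_max >= 1)
  structure(list(noise_variance = noise_variance, smoothing_sigma = smoothing_sigma,
                 scale_max = as.integer(scale_max),
                 erosion_radius_px = as.integer(erosion_radius_px),
                 dilation_radius_px = as.integer(dilation_radius_px),
                 rng_seed = as.integer(rng_seed)),
            class = "SyntheticDEParams")
}

#' Parameters for DRAQ5/Eosin -> synthetic H&E conversion
#'
#' Beer-Lambert recoloring with gamma exponents above 1, which darkens only
#' the strongest fluorescence signal and keeps faint cytoplasm pale — the
#' pipeline's departure from earlier virtual-H&E work that used gamma < 1.
#' Optical-density vectors default to conventional hematoxylin/eosin stain
#' directions scaled to unit maximum absorbance.
#' @param gamma_draq5,gamma_eosin gamma exponents, both > 1.
#' @param od_hematoxylin_rgb,od_eosin_rgb non-negative length-3 per-channel
#'   optical-density weights.
#' @param background_level 8-bit background (white) level.
#' @return a `SyntheticHEParams` list.
#' @export
synthetic_he_params <- function(gamma_draq5 = 1.5, gamma_eosin = 1.5,
                                od_hematoxylin_rgb = c(0.65, 0.70, 0.29) / 0.70,
                                od_eosin_rgb = c(0.07, 0.99, 0.11) / 0.99,
                                background_level = 255L) {
  stopifnot(gamma_draq5 > 1, gamma_eosin > 1,
            length(od_hematoxylin_rgb) == 3, length(od_eosin_rgb) == 3,
            all(od_hematoxylin_rgb >= 0), all(od_eosin_rgb >= 0))
  structure(list(gamma_draq5 = gamma_draq5, gamma_eosin = gamma_eosin,
                 od_hematoxylin_rgb = od_hematoxylin_rgb,
                 od_eosin_rgb = od_eosin_rgb,
                 background_level = as.integer(background_level)),
            class = "SyntheticHEParams")
}

#' Luma grayscale conversion
#'
#' Standard luma weights (0.299, 0.587, 0.114) on the 8-bit scale.
#' @param he an `RGBImage` or rows x cols x 3 array.
#' @return numeric matrix of grayscale intensities in `[0, 255]`.
#' @export
rgb_to_gray <- function(he) {
  d <- raster_of(he)
  0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
}

# flat disk structuring element of the given pixel radius
disk_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

# separable Gaussian blur with explicit finite support radius ceil(3*sigma);
# near the borders the kernel is renormalized by its in-bounds mass, so a
# constant image stays constant and no artificial dark rim appears
gauss_blur <- function(x, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0 || radius < 1) return(x)
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    mass <- matrix(0, nrow(m), ncol(m))
    n <- if (along_rows) nrow(m) else ncol(m)
    for (o in -radius:radius) {
      w <- k[o + radius + 1]
      src <- (1:n) + o
      ok <- src >= 1 & src <= n
      if (along_rows) {
        out[ok, ] <- out[ok, ] + w * m[src[ok], ]
        mass[ok, ] <- mass[ok, ] + w
      } else {
        out[, ok] <- out[, ok] + w * m[, src[ok]]
        mass[, ok] <- mass[, ok] + w
      }
    }
    out / mass
  }
  blur1(blur1(x, TRUE), FALSE)
}

# reversal that maps 0 to 0: background/masked pixels stay dark
invert_keep_zero <- function(g, maxval = 255) {
  ifelse(g == 0, 0, maxval - g)
}

#' Nuclei mask from an H&E image
#'
#' Grayscale conversion, multi-Otsu with two thresholds (three classes),
#' pixels strictly below the lower threshold marked as nuclei, then binary
#' erosion with a 1-pixel disk (configurable).
#' @param he an `RGBImage`.
#' @param erosion_radius_px disk radius for the final binary erosion.
#' @param n_bins histogram bins for multi-Otsu (default 255).
#' @return binary integer matrix (1 = nucleus).
#' @export
nuclei_mask_from_he <- function(he, erosion_radius_px = 1L, n_bins = 255) {
  g <- rgb_to_gray(he)
  if (min(g) == max(g)) {
    warning("constant image: returning empty nuclei mask")
    return(matrix(0L, nrow(g), ncol(g)))
  }
  t_low <- multi_otsu(g, n_classes = 3, n_bins = n_bins)[1]
  mask <- (g < t_low) * 1
  if (erosion_radius_px >= 1)
    mask <- EBImage::erode(mask, disk_brush(erosion_radius_px))
  m <- matrix(as.integer(round(mask)), nrow(g), ncol(g))
  m
}

# one channel of the synthetic-D&E chain: [0,255] grayscale already masked /
# zeroed as required -> reverse, noise, dilate, smooth, scale, z-normalize
synthesize_fluor_plane <- function(gray, params) {
  g <- invert_keep_zero(gray, 255) / 255
  if (params$noise_variance > 0)
    g <- g + matrix(rnorm(length(g), 0, sqrt(params$noise_variance)),
                    nrow(g), ncol(g))
  if (params$dilation_radius_px >= 1)
    g <- EBImage::dilate(g, disk_brush(params$dilation_radius_px))
  g <- gauss_blur(g, params$smoothing_sigma)
  g <- as.matrix(g) * params$scale_max
  znorm(g)
}

#' Convert an H&E image to a synthetic DRAQ5/Eosin pair
#'
#' The transfer-learning construction: the DRAQ5 plane keeps only (eroded)
#' nuclei, the Eosin plane everything but nuclei; both are
#' reversed-grayscale, noised, dilated, smoothed, scaled to 12-bit and
#' z-normalized. Deterministic for a fixed `params$rng_seed`.
#'
#' @param he an `RGBImage` (8-bit).
#' @param params a [synthetic_de_params()] object.
#' @return a `DEImage` whose planes are z-normalized float rasters
#'   (mean 0, sd 1), bit depth recorded as 12.
#' @export
he_to_synthetic_de <- function(he, params = synthetic_de_params()) {
  stopifnot(inherits(he, "RGBImage"))
  with_seed(params$rng_seed, {
    nmask <- nuclei_mask_from_he(he, params$erosion_radius_px)
    gray <- rgb_to_gray(he)
    draq5 <- synthesize_fluor_plane(gray * nmask, params)
    he0 <- he$data
    for (ch in 1:3) he0[, , ch] <- he0[, , ch] * (1 - nmask)
    eosin <- synthesize_fluor_plane(rgb_to_gray(rgb_image(he0, he$pixel_pitch_um)),
                                    params)
    de_image(
      image_plane_raw(draq5, 12L, he$pixel_pitch_um),
      image_plane_raw(eosin, 12L, he$pixel_pitch_um))
  })
}

# ImagePlane without the range invariant, for z-normalized float planes
image_plane_raw <- function(data, bit_depth, pixel_pitch_um) {
  structure(list(data = as.matrix(data), bit_depth = as.integer(bit_depth),
                 pixel_pitch_um = pixel_pitch_um),
            class = "ImagePlane")
}

#' Theoretical support mask of a synthetic DRAQ5 plane
#'
#' With noise off, nonzero synthetic-DRAQ5 values can only arise inside the
#' nuclei mask dilated by the intensity-dilation disk plus the finite
#' footprint of the Gaussian smoothing kernel. Useful for support-containment
#' checks.
#' @param nuclei_mask binary matrix from [nuclei_mask_from_he()].
#' @param params a [synthetic_de_params()] object.
#' @return binary matrix.
#' @export
synthetic_draq5_support <- function(nuclei_mask, params = synthetic_de_params()) {
  m <- nuclei_mask * 1
  if (params$dilation_radius_px >= 1)
    m <- EBImage::dilate(m, disk_brush(params$dilation_radius_px))
  rb <- ceiling(3 * params$smoothing_sigma)
  if (rb >= 1)  # separable smoothing spreads over a square footprint
    m <- EBImage::dilate(m, EBImage::makeBrush(2L * rb + 1L, shape = "box"))
  matrix(as.integer(as.matrix(m) > 0), nrow(nuclei_mask), ncol(nuclei_mask))
}

#' Convert a DRAQ5/Eosin pair to a synthetic H&E image
#'
#' Per-pixel Beer-Lambert recoloring: each plane is normalized to `[0,1]` by
#' its maximum, raised to its gamma (> 1), weighted by the per-channel
#' optical-density vectors and exponentiated:
#' `out_c = background * exp(-(odH_c * d^g_d + odE_c * e^g_e))`.
#' An all-zero plane contributes no absorbance.
#'
#' @param de a `DEImage` (planes need not be integer-valued).
#' @param params a [synthetic_he_params()] object.
#' @return an `RGBImage`.
#' @export
de_to_synthetic_he <- function(de, params = synthetic_he_params()) {
  stopifnot(inherits(de, "DEImage"))
  norm01 <- function(m) {
    m <- pmax(m, 0)
    mx <- max(m)
    if (mx <= 0) m else m / mx
  }
  d <- norm01(de$draq5$data)^params$gamma_draq5
  e <- norm01(de$eosin$data)^params$gamma_eosin
  out <- array(0, c(nrow(d), ncol(d), 3))
  for (ch in 1:3) {
    ab <- params$od_hematoxylin_rgb[ch] * d + params$od_eosin_rgb[ch] * e
    out[, , ch] <- pmin(pmax(params$background_level * exp(-ab), 0), 255)
  }
  rgb_image(round(out), pixel_pitch_um = de$draq5$pixel_pitch_um)
}
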