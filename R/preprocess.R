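# Deterministic image conditioning: rolling-ball background subtraction,
# CLAHE, tissue masking, z-normalization, physical-size cropping, resizing.

# 1-D grayscale erosion/dilation by a parabola p(k) = k^2/(2R) with finite
# support |k| <= half_width, via vectorized shift-and-extremum over offsets.
parabolic_pass <- function(m, half_width, curvature_div, dilate = FALSE,
                           along_rows = TRUE) {
  n <- if (along_rows) nrow(m) else ncol(m)
  hw <- min(half_width, n - 1)
  out <- m
  # erosion: E(x) = min_o I(x+o) - p(o); dilation: D(x) = max_o I(x+o) + p(o)
  # (symmetric support, so the dilation transpose convention collapses)
  for (o in setdiff(-hw:hw, 0)) {
    pen <- o^2 / curvature_div
    src <- (1:n) + o
    ok <- src >= 1 & src <= n
    if (along_rows) {
      cand <- m[src[ok], , drop = FALSE] + (if (dilate) pen else -pen)
      out[ok, ] <- if (dilate) pmax(out[ok, ], cand) else pmin(out[ok, ], cand)
    } else {
      cand <- m[, src[ok], drop = FALSE] + (if (dilate) pen else -pen)
      out[, ok] <- if (dilate) pmax(out[, ok], cand) else pmin(out[, ok], cand)
    }
  }
  out
}

#' Rolling-ball background subtraction (sliding paraboloid)
#'
#' Estimates the background as a grayscale opening with a paraboloid
#' structuring element `z = (dx^2 + dy^2) / (2 * radius)` — the local shape
#' of a ball of the given radius — and subtracts it. The paraboloid is
#' separable, so the opening runs as sequential 1-D parabolic erosions and
#' dilations along rows and columns. Support is truncated where the
#' paraboloid exceeds the dtype range (beyond that distance a farther pixel
#' can never determine the extremum), capped at `2 * radius`.
#'
#' @param plane an `ImagePlane` (or plain matrix, treated as 16-bit range).
#' @param radius_px ball radius in pixels (default 50, the pipeline value).
#' @return object of the same kind with background-subtracted, zero-clipped
#'   values.
#' @export
rolling_ball_subtract <- function(plane, radius_px = 50L) {
  stopifnot(radius_px >= 1)
  is_plane <- inherits(plane, "ImagePlane")
  m <- raster_of(plane)
  if (radius_px > max(dim(m)))
    stop("rolling-ball radius exceeds both image dimensions")
  maxv <- if (is_plane) 2^plane$bit_depth - 1 else 2^16 - 1
  # beyond hw, p(k) >= dynamic range so the offset can never win the min/max
  hw <- min(ceiling(sqrt(2 * radius_px * maxv)), 2L * radius_px)
  div <- 2 * radius_px
  bg <- parabolic_pass(m, hw, div, dilate = FALSE, along_rows = TRUE)
  bg <- parabolic_pass(bg, hw, div, dilate = FALSE, along_rows = FALSE)
  bg <- parabolic_pass(bg, hw, div, dilate = TRUE, along_rows = TRUE)
  bg <- parabolic_pass(bg, hw, div, dilate = TRUE, along_rows = FALSE)
  out <- pmax(m - bg, 0)
  if (is_plane) image_plane(out, plane$bit_depth, plane$pixel_pitch_um) else out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, on the unit scale.
#' Wraps the standard CLAHE implementation (EBImage); input intensities are
#' normalized by the plane's bit-depth maximum first.
#'
#' @param plane `ImagePlane` or numeric matrix (matrix assumed already on
#'   an arbitrary positive scale; normalized by its own max).
#' @param clip_limit clipping fraction of the per-tile histogram (default
#'   0.01); mapped onto the implementation's multiplicative limit as
#'   `clip_limit * n_bins`.
#' @param tile_grid integer pair: tiles along rows and columns (default 8x8).
#' @param n_bins histogram bins (default 256).
#' @return numeric matrix in `[0, 1]`.
#' @export
clahe <- function(plane, clip_limit = 0.01, tile_grid = c(8L, 8L), n_bins = 256L) {
  m <- raster_of(plane)
  stopifnot(length(m) > 0)
  maxv <- if (inherits(plane, "ImagePlane")) 2^plane$bit_depth - 1 else max(max(m), 1)
  x <- m / maxv
  if (min(x) == max(x)) return(x)
  # EBImage images are x-major (first dim = columns): transpose in and out
  y <- EBImage::clahe(t(x), nx = tile_grid[2], ny = tile_grid[1],
                      bins = n_bins, limit = max(clip_limit * n_bins, 1e-6),
                      keep.range = FALSE)
  out <- t(as.matrix(y))
  pmin(pmax(out, 0), 1)
}

#' Tissue mask from an H&E image
#'
#' Grayscale conversion, multi-Otsu with two thresholds; everything strictly
#' below the high threshold (i.e., darker than glass/background) is tissue.
#' @param he an `RGBImage`.
#' @param n_bins histogram bins for multi-Otsu (default 255).
#' @return binary integer matrix (1 = tissue).
#' @export
tissue_mask <- function(he, n_bins = 255) {
  g <- rgb_to_gray(he)
  if (min(g) == max(g)) {
    warning("constant image: returning empty tissue mask")
    return(matrix(0L, nrow(g), ncol(g)))
  }
  t_high <- multi_otsu(g, n_classes = 3, n_bins = n_bins)[2]
  matrix(as.integer(g < t_high), nrow(g), ncol(g))
}

#' Z-normalize a raster
#'
#' Subtracts the plane mean and divides by the plane standard deviation
#' (population form, denominator n). A constant plane yields all zeros with
#' a warning.
#' @param x `ImagePlane` or numeric matrix/array.
#' @return numeric raster of the same shape.
#' @export
znorm <- function(x) {
  m <- raster_of(x)
  mu <- mean(m)
  s <- sqrt(mean((m - mu)^2))
  if (s == 0) {
    warning("zero-variance raster: z-normalization returns zeros")
    return(m * 0)
  }
  (m - mu) / s
}

#' Tile an image into fixed physical-size crop boxes
#'
#' The crop edge in pixels is `round(crop_edge_um / pixel_pitch_um)`
#' (half-away-from-zero rounding). Boxes tile the raster on a regular grid
#' anchored at pixel (0,0); partial boxes at the right/bottom are discarded.
#'
#' @param shape integer pair (rows, cols).
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @param crop_edge_um physical crop edge (default 245.52, the pipeline's
#'   crop size).
#' @return list of half-open boxes `c(r0, r1, c0, c1)`; empty if no full
#'   tile fits.
#' @export
crop_boxes <- function(shape, pixel_pitch_um, crop_edge_um = 245.52) {
  stopifnot(pixel_pitch_um > 0, crop_edge_um > 0)
  edge <- floor(crop_edge_um / pixel_pitch_um + 0.5)
  if (edge < 1) stop("crop edge rounds to less than one pixel")
  nr <- shape[1] %/% edge
  nc <- shape[2] %/% edge
  if (nr < 1 || nc < 1) return(list())
  out <- vector("list", nr * nc)
  k <- 1
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[[k]] <- c((i - 1) * edge, i * edge, (j - 1) * edge, j * edge)
    k <- k + 1
  }
  out
}

#' Nearest-neighbour resize
#'
#' Index-arithmetic nearest resampling (pixel centers; no interpolation), so
#' label rasters keep their exact value set.
#' @param x matrix or rows x cols x channels array.
#' @param target_shape integer pair (rows, cols).
#' @return resized raster of the same type.
#' @export
resize_nearest <- function(x, target_shape) {
  stopifnot(all(target_shape >= 1))
  d <- if (is.matrix(x)) dim(x) else dim(x)[1:2]
  ri <- pmin(floor((seq_len(target_shape[1]) - 0.5) * d[1] / target_shape[1]) + 1, d[1])
  ci <- pmin(floor((seq_len(target_shape[2]) - 0.5) * d[2] / target_shape[2]) + 1, d[2])
  if (is.matrix(x)) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}
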