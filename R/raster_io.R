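#' @importFrom stats rnorm runif sd quantile cor fft median setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Shared pixel-coordinate convention for the whole package:
# rasters are base-R matrices (rows x cols), origin top-left; crop boxes are
# half-open, 0-based: c(r0, r1, c0, c1) selects rows r0..r1-1, cols c0..c1-1.

#' Construct an intensity plane
#'
#' An `ImagePlane` is a single-channel intensity raster plus the two pieces of
#' acquisition metadata every downstream step needs: nominal bit depth and
#' physical pixel pitch. Values are stored as plain numerics; invariants are
#' checked on construction.
#'
#' @param data numeric matrix (rows x cols), values in `[0, 2^bit_depth - 1]`.
#' @param bit_depth nominal bit depth, one of 8, 12, 16. 12-bit microscope
#'   data lives in 16-bit file containers; the flag records the nominal depth.
#' @param pixel_pitch_um physical edge length of one pixel in micrometres.
#' @return an object of class `ImagePlane`.
#' @export
image_plane <- function(data, bit_depth = 16, pixel_pitch_um = 0.52) {
  if (!is.matrix(data)) data <- as.matrix(data)
  stopifnot(bit_depth %in% c(8L, 12L, 16L), pixel_pitch_um > 0,
            nrow(data) >= 1, ncol(data) >= 1)
  storage.mode(data) <- "double"
  attributes(data) <- list(dim = dim(data))  # drop any file-reader metadata
  maxv <- 2^bit_depth - 1
  if (any(data < 0 | data > maxv, na.rm = TRUE))
    stop("plane values outside [0, ", maxv, "] for bit depth ", bit_depth)
  structure(list(data = data, bit_depth = as.integer(bit_depth),
                 pixel_pitch_um = pixel_pitch_um),
            class = "ImagePlane")
}

#' @export
print.ImagePlane <- function(x, ...) {
  cat(sprintf("ImagePlane %dx%d, %d-bit, %.4g um/px, range [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$bit_depth, x$pixel_pitch_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct an 8-bit RGB image
#'
#' @param data rows x cols x 3 numeric array with values in `[0, 255]`.
#'   White (255,255,255) is background by convention.
#' @param pixel_pitch_um physical pixel pitch in micrometres.
#' @return an object of class `RGBImage`.
#' @export
rgb_image <- function(data, pixel_pitch_um = 0.52) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 3, pixel_pitch_um > 0)
  if (any(data < 0 | data > 255)) stop("RGB values outside [0, 255]")
  structure(list(data = data, pixel_pitch_um = pixel_pitch_um),
            class = "RGBImage")
}

#' Construct a paired DRAQ5/Eosin image
#'
#' The pipeline's native sample: the DRAQ5 channel images nuclei, the Eosin
#' channel cytoplasm and stroma. Both planes must agree in shape, bit depth
#' and pitch.
#'
#' @param draq5,eosin `ImagePlane` objects of identical geometry.
#' @param core_id,patient_id opaque provenance strings.
#' @param acquisition optional [acquisition_config()].
#' @return an object of class `DEImage`.
#' @export
de_image <- function(draq5, eosin, core_id = "core", patient_id = "patient",
                     acquisition = NULL) {
  stopifnot(inherits(draq5, "ImagePlane"), inherits(eosin, "ImagePlane"))
  if (!identical(dim(draq5$data), dim(eosin$data)) ||
      draq5$bit_depth != eosin$bit_depth ||
      draq5$pixel_pitch_um != eosin$pixel_pitch_um)
    stop("draq5 and eosin planes must share shape, bit_depth and pixel pitch")
  structure(list(draq5 = draq5, eosin = eosin, core_id = core_id,
                 patient_id = patient_id, acquisition = acquisition),
            class = "DEImage")
}

#' The fixed annotation legend
#'
#' Six annotation categories plus background, with fixed integer codes used
#' by every `LabelMask` in the package.
#' @return named integer vector mapping class name to code.
#' @export
annotation_legend <- function() {
  c(background = 0L, Healthy = 1L, GP3 = 2L, GP4 = 3L,
    Cribriform = 4L, Glomeruloid = 5L, GP5 = 6L)
}

#' Construct a label mask over the annotation legend
#'
#' @param data integer matrix whose values are all legend codes.
#' @param legend named integer vector; defaults to [annotation_legend()].
#' @return an object of class `LabelMask`.
#' @export
label_mask <- function(data, legend = annotation_legend()) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), unname(legend))
  if (length(bad))
    stop("mask values not in legend: ", paste(sort(bad), collapse = ", "))
  structure(list(data = data, legend = legend), class = "LabelMask")
}

#' Construct a binary epithelial mask
#'
#' @param data matrix of 0 (non-epithelium) / 1 (epithelium).
#' @return an object of class `EpithelialMask`.
#' @export
epithelial_mask <- function(data) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) stop("epithelial mask values must be 0/1")
  structure(list(data = data), class = "EpithelialMask")
}

raster_of <- function(x) {
  if (inherits(x, c("ImagePlane", "LabelMask", "EpithelialMask", "RGBImage")))
    x$data else x
}

#' Read a grayscale plane from TIFF or PNG
#'
#' Supports 8- and 16-bit single-page grayscale files. 12-bit microscope data
#' is conventionally stored in a 16-bit container; pass `bit_depth = 12` to
#' record the nominal depth (values are never rescaled).
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param pixel_pitch_um physical pixel pitch to attach.
#' @param bit_depth nominal bit depth of the stored data (default 16 for
#'   16-bit containers, 8 for 8-bit files).
#' @return an `ImagePlane` with values exactly as stored.
#' @export
read_plane <- function(path, pixel_pitch_um = 0.52, bit_depth = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = FALSE, info = TRUE)
    stored_bits <- attr(img, "bits.per.sample")
    if (is.null(stored_bits)) stored_bits <- if (max(img) > 255) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    # png package returns [0,1]; recover integers from the 8/16-bit container
    stored_bits <- attr(img, "info")$bit.depth
    if (is.null(stored_bits)) stored_bits <- 8L
    img <- round(img * (2^stored_bits - 1))
    attributes(img) <- list(dim = dim(img))
  } else stop("unsupported raster format: ", path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1] else
      stop("expected grayscale raster, got multi-channel file: ", path)
  }
  if (is.null(bit_depth)) bit_depth <- as.integer(stored_bits)
  image_plane(img, bit_depth = bit_depth, pixel_pitch_um = pixel_pitch_um)
}

#' Write a grayscale plane losslessly
#'
#' 8-bit planes are written as 8-bit files; 12- and 16-bit planes go into
#' 16-bit containers with values unscaled, so `read_plane(write_plane(p))`
#' reproduces the data bit-exactly.
#'
#' @param plane an `ImagePlane`.
#' @param path destination .tif/.tiff/.png path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_plane <- function(plane, path) {
  stopifnot(inherits(plane, "ImagePlane"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  container <- if (plane$bit_depth == 8L) 8L else 16L
  scaled <- plane$data / (2^container - 1)
  ext <- tolower(tools::file_ext(path))
  ok <- if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = container)
  } else if (ext == "png") {
    # the png writer emits 8-bit containers only; deep planes go to TIFF
    if (container > 8L)
      stop("PNG output supports 8-bit planes only; use a .tif path for ",
           plane$bit_depth, "-bit data")
    png::writePNG(scaled, path)
    TRUE
  } else stop("unsupported raster format: ", path)
  if (isFALSE(ok)) stop("failed to write ", path)
  invisible(path)
}

#' Read a z-stack from a multi-page TIFF
#'
#' Page order is acquisition order (focus offsets -5, -2.5, 0, +2.5, +5 um in
#' the reference protocol).
#'
#' @inheritParams read_plane
#' @return list of `ImagePlane`, one per page.
#' @export
read_zstack <- function(path, pixel_pitch_um = 0.52, bit_depth = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE)
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(p) > 255) 16L else 8L
    image_plane(p, bit_depth = if (is.null(bit_depth)) as.integer(bits) else bit_depth,
                pixel_pitch_um = pixel_pitch_um)
  })
}

#' Write a z-stack as a multi-page TIFF
#' @param planes list of `ImagePlane` of identical geometry.
#' @param path destination .tif path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(planes, path) {
  container <- if (planes[[1]]$bit_depth == 8L) 8L else 16L
  imgs <- lapply(planes, function(p) p$data / (2^container - 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = container)
  invisible(path)
}

#' Read an 8-bit RGB image
#' @inheritParams read_plane
#' @return an `RGBImage`.
#' @export
read_rgb <- function(path, pixel_pitch_um = 0.52) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("expected RGB raster: ", path)
  rgb_image(round(img[, , 1:3] * 255), pixel_pitch_um = pixel_pitch_um)
}

#' Write an 8-bit RGB image
#' @param img an `RGBImage`.
#' @param path destination .png/.tif path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "RGBImage"))
  ext <- tolower(tools::file_ext(path))
  scaled <- img$data / 255
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  else png::writePNG(scaled, path)
  invisible(path)
}

#' Write a legend sidecar file
#'
#' The sidecar is a two-column CSV (`code`, `name`); mask rasters never rely
#' on palette inference.
#' @param legend named integer vector (name -> code).
#' @param path destination .csv path.
#' @return `path`, invisibly.
#' @export
write_legend <- function(legend, path) {
  write.csv(data.frame(code = unname(legend), name = names(legend)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a legend sidecar file
#' @param path legend CSV with columns `code`, `name`.
#' @return named integer vector.
#' @export
read_legend <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$code), df$name)
}

#' Read a label or epithelial mask with its legend
#'
#' Every raster value is validated against the legend; a purely binary legend
#' (codes 0/1) yields an `EpithelialMask`, anything else a `LabelMask`.
#'
#' @param raster_path single-channel PNG or TIFF of integer codes.
#' @param legend_path legend sidecar CSV.
#' @return `LabelMask` or `EpithelialMask`.
#' @export
read_mask <- function(raster_path, legend_path) {
  plane <- read_plane(raster_path, pixel_pitch_um = 1)
  legend <- read_legend(legend_path)
  vals <- unique(as.vector(plane$data))
  bad <- setdiff(vals, unname(legend))
  if (length(bad))
    stop("mask values absent from legend: ", paste(sort(bad), collapse = ", "))
  m <- plane$data
  storage.mode(m) <- "integer"
  if (setequal(unname(legend), c(0L, 1L))) epithelial_mask(m)
  else label_mask(m, legend = legend)
}

#' Write a mask raster plus legend sidecar
#' @param mask `LabelMask` or `EpithelialMask`.
#' @param raster_path destination raster path.
#' @param legend_path destination legend CSV path.
#' @return `raster_path`, invisibly.
#' @export
write_mask <- function(mask, raster_path, legend_path) {
  legend <- if (inherits(mask, "LabelMask")) mask$legend
            else c(background = 0L, epithelium = 1L)
  write_plane(image_plane(mask$data, bit_depth = 8L, pixel_pitch_um = 1), raster_path)
  write_legend(legend, legend_path)
  invisible(raster_path)
}

#' Read or write a core manifest
#'
#' The manifest is the package's CSV dialect tying cores to files:
#' columns `core_id, patient_id, path_draq5, path_eosin, path_mask,
#' pixel_pitch_um` (extra columns pass through untouched).
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "patient_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

# --- half-open box helpers -------------------------------------------------

#' Extract a half-open crop box from a raster
#'
#' Boxes are `c(r0, r1, c0, c1)`, 0-based, half-open: rows `r0..r1-1`,
#' columns `c0..c1-1` of the raster.
#' @param x matrix or 3-d array (rows x cols x channels).
#' @param box integer vector `c(r0, r1, c0, c1)`.
#' @return the cropped raster.
#' @export
crop_box <- function(x, box) {
  stopifnot(length(box) == 4, box[1] < box[2], box[3] < box[4], box[1] >= 0, box[3] >= 0)
  d <- if (is.matrix(x)) dim(x) else dim(x)[1:2]
  stopifnot(box[2] <= d[1], box[4] <= d[2])
  ri <- (box[1] + 1):box[2]; ci <- (box[3] + 1):box[4]
  if (is.matrix(x)) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Paste values back into a half-open crop box
#' @param x target raster; @param box half-open box; @param value replacement.
#' @return modified raster.
#' @export
uncrop_box <- function(x, box, value) {
  ri <- (box[1] + 1):box[2]; ci <- (box[3] + 1):box[4]
  if (is.matrix(x)) x[ri, ci] <- value else x[ri, ci, ] <- value
  x
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
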