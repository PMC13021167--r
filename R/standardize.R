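# Acquisition-robustness harness: sharpness scoring and focus ranking,
# acquisition perturbation simulation, hierarchical phase-correlation mask
# realignment, per-condition robustness reports.

#' One point on the standardization grid
#'
#' The acquisition grids of the reference protocol: focus offsets
#' -5..+5 um, confocal averaging 1/2/4/8 (noise std scales as
#' 1/sqrt(averaging)), pixel pitches 0.34/0.52/0.69 um (0.35 accepted as an
#' alias of 0.34), and two lenses (20x NA 0.8; 10x NA 0.45, which widens the
#' PSF by the NA ratio). Off-grid values require `custom = TRUE`.
#' @param focus_offset_um,averaging,pixel_pitch_um,lens grid coordinates.
#' @param custom allow values outside the stated grids.
#' @return an `AcquisitionConfig`.
#' @export
acquisition_config <- function(focus_offset_um = 0, averaging = 8L,
                               pixel_pitch_um = 0.52,
                               lens = c("L20x_na08", "L10x_na045"),
                               custom = FALSE) {
  lens <- match.arg(lens)
  if (pixel_pitch_um == 0.35) pixel_pitch_um <- 0.34
  if (!custom) {
    stopifnot(focus_offset_um %in% c(-5, -2.5, 0, 2.5, 5),
              averaging %in% c(1L, 2L, 4L, 8L),
              pixel_pitch_um %in% c(0.34, 0.52, 0.69))
  } else if (pixel_pitch_um <= 0) stop("pixel pitch must be positive")
  structure(list(focus_offset_um = focus_offset_um,
                 averaging = as.integer(averaging),
                 pixel_pitch_um = pixel_pitch_um, lens = lens),
            class = "AcquisitionConfig")
}

# numpy-style gradient: central differences inside, one-sided at the edges
grad1 <- function(m, along_rows) {
  n <- if (along_rows) nrow(m) else ncol(m)
  if (n < 2) return(m * 0)
  if (along_rows) {
    g <- (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) / 2
    g[1, ] <- m[2, ] - m[1, ]
    g[n, ] <- m[n, ] - m[n - 1, ]
  } else {
    g <- (m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]) / 2
    g[, 1] <- m[, 2] - m[, 1]
    g[, n] <- m[, n] - m[, n - 1]
  }
  g
}

#' Sharpness score of a plane
#'
#' Mean over pixels of `sqrt(gx^2 + gy^2)` with central-difference gradients
#' along rows and columns (one-sided at the borders). Meant for
#' pre-equalization intensities — histogram equalization would distort the
#' comparison across a z-stack.
#' @param plane `ImagePlane` or matrix, at least 2x2.
#' @return non-negative number.
#' @export
sharpness_score <- function(plane) {
  m <- raster_of(plane)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  gx <- grad1(m, FALSE)
  gy <- grad1(m, TRUE)
  mean(sqrt(gx^2 + gy^2))
}

#' Rank a z-stack by sharpness
#'
#' Rank 1 is the sharpest plane; ties break to the earlier stack index.
#' @param zstack list of planes.
#' @return list with `ranks` (integer vector, 1 = sharpest), `best`
#'   (index of the sharpest plane), `scores`.
#' @export
rank_focus <- function(zstack) {
  stopifnot(length(zstack) >= 1)
  s <- vapply(zstack, sharpness_score, numeric(1))
  ord <- order(-s, seq_along(s))
  ranks <- integer(length(s))
  ranks[ord] <- seq_along(s)
  list(ranks = ranks, best = ord[1], scores = s)
}

# bilinear resize for intensity rasters (pixel-center convention)
resize_bilinear <- function(m, target_shape) {
  H <- nrow(m); W <- ncol(m)
  Ho <- target_shape[1]; Wo <- target_shape[2]
  rf <- (seq_len(Ho) - 0.5) * H / Ho + 0.5
  cf <- (seq_len(Wo) - 0.5) * W / Wo + 0.5
  r0 <- pmin(pmax(floor(rf), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(cf), 1), W); c1 <- pmin(c0 + 1, W)
  wr <- pmin(pmax(rf - r0, 0), 1); wc <- pmin(pmax(cf - c0, 0), 1)
  a <- m[r0, c0, drop = FALSE] * (1 - wr) + m[r1, c0, drop = FALSE] * wr
  b <- m[r0, c1, drop = FALSE] * (1 - wr) + m[r1, c1, drop = FALSE] * wr
  a * matrix(1 - wc, Ho, Wo, byrow = TRUE) + b * matrix(wc, Ho, Wo, byrow = TRUE)
}

#' Simulate acquisition of an ideal image under a configuration
#'
#' The parametric forward model standing in for physical re-acquisition:
#' defocus as a Gaussian blur of `sigma_px = k * |focus_offset_um|`; the
#' 10x/NA 0.45 lens as an extra PSF blur of
#' `lens_psf_sigma_px * (0.8/0.45)`; shot/readout noise as additive Gaussian
#' with `std = noise_sigma0 / sqrt(averaging)` (intensity units); sampling
#' density as a bilinear resample to the configured pixel pitch. The
#' identity configuration (focus 0, averaging with `noise_sigma0 = 0`,
#' reference pitch, 20x lens) returns the input bit-exactly.
#'
#' @param ideal a `DEImage` at the reference pitch (0.52 um).
#' @param cfg an [acquisition_config()].
#' @param noise_sigma0 noise std at averaging 1, in intensity units.
#' @param seed RNG seed for the noise draw.
#' @param k defocus blur in px per um of focus offset (default 0.8).
#' @param lens_psf_sigma_px base PSF sigma scaled for the 10x lens (default 0.8).
#' @return a simulated `DEImage` at `cfg$pixel_pitch_um`.
#' @export
simulate_acquisition <- function(ideal, cfg, noise_sigma0 = 0, seed = 1L,
                                 k = 0.8, lens_psf_sigma_px = 0.8) {
  stopifnot(inherits(ideal, "DEImage"), inherits(cfg, "AcquisitionConfig"))
  ref_pitch <- ideal$draq5$pixel_pitch_um
  maxv <- 2^ideal$draq5$bit_depth - 1
  sim_plane <- function(plane, chan_seed) {
    m <- plane$data
    sg <- k * abs(cfg$focus_offset_um)
    if (sg > 0) m <- gauss_blur(m, sg)
    if (cfg$lens == "L10x_na045")
      m <- gauss_blur(m, lens_psf_sigma_px * (0.8 / 0.45))
    if (noise_sigma0 > 0) {
      sdn <- noise_sigma0 / sqrt(cfg$averaging)
      m <- m + with_seed(chan_seed, matrix(rnorm(length(m), 0, sdn), nrow(m)))
    }
    if (cfg$pixel_pitch_um != ref_pitch) {
      target <- pmax(round(dim(m) * ref_pitch / cfg$pixel_pitch_um), 1)
      m <- resize_bilinear(m, target)
    }
    image_plane(pmin(pmax(m, 0), maxv), plane$bit_depth, cfg$pixel_pitch_um)
  }
  de_image(sim_plane(ideal$draq5, seed), sim_plane(ideal$eosin, seed + 1L),
           core_id = ideal$core_id, patient_id = ideal$patient_id,
           acquisition = cfg)
}

#' Integer shift between two rasters by phase cross-correlation
#'
#' Returns the displacement `(dr, dc)` such that `b` equals `a` circularly
#' shifted by `(dr, dc)`; translating `b` back by `-(dr, dc)` aligns it
#' onto `a`. Peak of the inverse FFT of the normalized cross-power
#' spectrum; integer precision; shifts past half the image size wrap to
#' negative values.
#' @param a,b equal-shape, non-constant numeric matrices.
#' @return integer vector `c(dr, dc)`.
#' @export
phase_shift <- function(a, b) {
  a <- raster_of(a); b <- raster_of(b)
  stopifnot(identical(dim(a), dim(b)))
  if (min(a) == max(a) || min(b) == max(b))
    stop("phase correlation undefined for constant input")
  Fa <- fft(a); Fb <- fft(b)
  cp <- Fb * Conj(Fa)
  mod <- Mod(cp)
  cp <- cp / pmax(mod, 1e-12)
  r <- Re(fft(cp, inverse = TRUE))
  p <- which.max(r) - 1L
  n <- nrow(a)
  dr <- p %% n
  dc <- p %/% n
  if (dr > n / 2) dr <- dr - n
  if (dc > ncol(a) / 2) dc <- dc - ncol(a)
  c(as.integer(dr), as.integer(dc))
}

# integer-shift a matrix, zero-filling exposed pixels
shift_matrix <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Hierarchically realign a mask to a reference plane
#'
#' For each window size in order (default 64, 32, 16), both rasters are
#' tiled into full windows; each window's integer shift is estimated by
#' [phase_shift()] and undone on the moving mask (nearest/zero-fill within
#' the window; pixels outside the window untouched). Near-empty moving
#' windows (< 1% nonzero) and constant reference windows are skipped, and
#' per-window shifts are capped at a quarter window to prevent tearing.
#' Later, smaller windows refine residual local misalignment.
#'
#' @param moving_mask `EpithelialMask`, `LabelMask` or integer matrix.
#' @param reference `ImagePlane` or matrix of the same shape.
#' @param windows strictly decreasing window sizes.
#' @param min_content_frac skip threshold on the moving window (default 0.01).
#' @return the realigned mask, same class as the input.
#' @export
hierarchical_register <- function(moving_mask, reference,
                                  windows = c(64L, 32L, 16L),
                                  min_content_frac = 0.01) {
  ref <- raster_of(reference)
  mov <- raster_of(moving_mask)
  stopifnot(identical(dim(mov), dim(ref)), all(diff(windows) < 0))
  for (wsz in windows) {
    if (wsz > min(dim(ref))) {
      warning("window ", wsz, " larger than image; level skipped")
      next
    }
    nr <- nrow(ref) %/% wsz
    nc <- ncol(ref) %/% wsz
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      box <- c((i - 1) * wsz, i * wsz, (j - 1) * wsz, j * wsz)
      mw <- crop_box(mov, box)
      if (mean(mw != 0) < min_content_frac) next
      rw <- crop_box(ref, box)
      # the reference proxy for the moving window: where the mask says
      # tissue should be; registration matches structure, so both rasters
      # must carry comparable content
      if (min(rw) == max(rw) || min(mw) == max(mw)) next
      s <- phase_shift(rw, mw)
      cap <- wsz %/% 4L
      s <- pmin(pmax(s, -cap), cap)
      if (any(s != 0)) mov <- uncrop_box(mov, box, shift_matrix(mw, -s[1], -s[2]))
    }
  }
  if (inherits(moving_mask, "EpithelialMask")) epithelial_mask(mov)
  else if (inherits(moving_mask, "LabelMask")) label_mask(mov, moving_mask$legend)
  else mov
}

# CLAHE + resize + z-normalize a simulated DE pair into a model input array
de_to_model_input <- function(de, input_px) {
  d <- znorm(resize_nearest(clahe(de$draq5), c(input_px, input_px)))
  e <- znorm(resize_nearest(clahe(de$eosin), c(input_px, input_px)))
  arr <- array(0, c(input_px, input_px, 2))
  arr[, , 1] <- d
  arr[, , 2] <- e
  arr
}

#' Evaluate a trained model across acquisition conditions
#'
#' For every configuration in the grid, every phantom crop is re-acquired
#' through [simulate_acquisition()], pushed through the task's conditioning
#' chain (CLAHE, resize, z-normalization) and re-evaluated — the
#' standardization experiment at phantom scale.
#'
#' @param model trained `fg_model` for the task.
#' @param phantom_set list of records with `draq5_raw`, `eosin_raw`
#'   (`ImagePlane`s at the reference pitch) and `label01` (binary tasks) or
#'   `seg_mask` (CANCER_SEG).
#' @param grid list of [acquisition_config()].
#' @param task one of [task_names()].
#' @param noise_sigma0 noise std at averaging 1 (intensity units).
#' @param seed base seed for the simulated noise.
#' @return data.frame with one row per configuration (config columns +
#'   metric columns), with the full `MetricsReport`s in
#'   `attr(, "reports")`.
#' @export
robustness_report <- function(model, phantom_set, grid, task,
                              noise_sigma0 = 0, seed = 1L) {
  task <- match.arg(task, task_names())
  rows <- list()
  reports <- list()
  input_px <- model$spec$input_shape[1]
  for (gi in seq_along(grid)) {
    cfg <- grid[[gi]]
    xs <- vector("list", length(phantom_set))
    for (pi in seq_along(phantom_set)) {
      rec <- phantom_set[[pi]]
      de <- de_image(rec$draq5_raw, rec$eosin_raw)
      sim <- simulate_acquisition(de, cfg, noise_sigma0 = noise_sigma0,
                                  seed = seed + gi * 10000L + pi * 2L)
      xs[[pi]] <- de_to_model_input(sim, input_px)
    }
    if (task == "CANCER_SEG") {
      preds <- predict_model(model, xs)
      truth <- lapply(phantom_set, function(r)
        resize_nearest(r$seg_mask, c(input_px, input_px)))
      rep <- evaluate_task(task, preds, truth)
    } else {
      probs <- predict_model(model, xs)
      truth <- vapply(phantom_set, function(r) r$label01, numeric(1))
      rep <- evaluate_task(task, probs, truth)
    }
    reports[[gi]] <- rep
    rows[[gi]] <- data.frame(
      focus_offset_um = cfg$focus_offset_um, averaging = cfg$averaging,
      pixel_pitch_um = cfg$pixel_pitch_um, lens = cfg$lens,
      accuracy = rep$accuracy, kappa = rep$kappa, auc = rep$auc,
      dice_background = if (is.null(rep$dice_per_class)) NA_real_ else rep$dice_per_class$background,
      dice_healthy = if (is.null(rep$dice_per_class)) NA_real_ else rep$dice_per_class$healthy,
      dice_cancer = if (is.null(rep$dice_per_class)) NA_real_ else rep$dice_per_class$cancer)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "reports") <- reports
  out
}
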