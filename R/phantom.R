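# Seeded generator of gland-structured synthetic tissue in both modalities
# with pixel-perfect ground truth. The per-grade morphologies are deliberate
# caricatures — large open glands for healthy tissue, small crowded glands
# for GP3, fused multi-lumen islands for GP4, solid nuclear sheets for GP5 —
# sufficient to make the classification and segmentation tasks learnable by
# compact models; they claim no histological fidelity.

#' Phantom generation parameters
#'
#' @param canvas_px integer pair, canvas size in pixels.
#' @param pixel_pitch_um pixel pitch (default 0.52, the reference pitch).
#' @param n_glands glands attempted per core.
#' @param gland_radius_um interval of gland radii (um).
#' @param lumen_fraction lumen radius as a fraction of gland radius.
#' @param nucleus_radius_um interval of nucleus radii (um).
#' @param class_mix named probabilities over Healthy/GP3/GP4/GP5 for
#'   per-gland class draws (must sum to 1).
#' @param fusion_prob probability that a GP4 gland grows extra fused lobes.
#' @param sheet_prob probability that a GP5 focus is a large solid sheet.
#' @param stroma_texture_scale sd of the smoothed stroma texture (12-bit units).
#' @param rng_seed seed; generation is bit-reproducible per seed.
#' @return a `PhantomParams` list.
#' @export
phantom_params <- function(canvas_px = c(384L, 384L), pixel_pitch_um = 0.52,
                           n_glands = 48L, gland_radius_um = c(14, 24),
                           lumen_fraction = 0.55,
                           nucleus_radius_um = c(2.2, 3.2),
                           class_mix = c(Healthy = 0.25, GP3 = 0.25,
                                         GP4 = 0.25, GP5 = 0.25),
                           fusion_prob = 0.7, sheet_prob = 0.7,
                           stroma_texture_scale = 180, rng_seed = 1L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% c("Healthy", "GP3", "GP4", "GP5")),
            all(gland_radius_um > 0), all(nucleus_radius_um > 0),
            fusion_prob >= 0, fusion_prob <= 1, sheet_prob >= 0, sheet_prob <= 1,
            lumen_fraction > 0, lumen_fraction < 1)
  structure(list(canvas_px = as.integer(canvas_px),
                 pixel_pitch_um = pixel_pitch_um, n_glands = as.integer(n_glands),
                 gland_radius_um = gland_radius_um,
                 lumen_fraction = lumen_fraction,
                 nucleus_radius_um = nucleus_radius_um, class_mix = class_mix,
                 fusion_prob = fusion_prob, sheet_prob = sheet_prob,
                 stroma_texture_scale = stroma_texture_scale,
                 rng_seed = as.integer(rng_seed)),
            class = "PhantomParams")
}

# paint a filled disk into one or more rasters via a bounding-box distance test
disk_pixels <- function(H, W, cy, cx, r) {
  r0 <- max(1, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
  c0 <- max(1, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(NULL)
  ys <- r0:r1; xs <- c0:c1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sel <- which(d2 <= r^2, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  cbind(ys[sel[, 1]], xs[sel[, 2]])
}

#' Generate one phantom core
#'
#' Places glands (annuli of nuclei around a lumen over eosinophilic stroma),
#' draws each gland's grade from `class_mix` and renders both modalities:
#' the DRAQ5 plane carries nuclei, the Eosin plane cytoplasm and stroma
#' (12-bit), the `LabelMask` marks each gland's grade over its epithelial
#' footprint, the `EpithelialMask` is the union of footprints, and the H&E
#' rendering comes from [de_to_synthetic_he()].
#'
#' @param params a [phantom_params()].
#' @param core_id,patient_id provenance strings.
#' @return list with `de` (`DEImage`), `label` (`LabelMask`), `epi`
#'   (`EpithelialMask`), `he` (`RGBImage`) and the realized per-gland
#'   classes in `gland_classes`.
#' @export
generate_core <- function(params = phantom_params(), core_id = "core01",
                          patient_id = "patient01") {
  H <- params$canvas_px[1]; W <- params$canvas_px[2]
  px <- function(um) um / params$pixel_pitch_um
  max_r <- px(max(params$gland_radius_um)) * 1.4
  if (min(H, W) < 2 * max_r)
    stop("canvas too small for a single gland at the requested radii")
  legend <- annotation_legend()
  with_seed(params$rng_seed, {
    draq5 <- matrix(pmax(rnorm(H * W, 120, 40), 0), H, W)
    eosin <- pmax(1100 + gauss_blur(matrix(rnorm(H * W, 0,
                    params$stroma_texture_scale * 3), H, W), 2.5), 0)
    label <- matrix(0L, H, W)
    epi <- matrix(0L, H, W)
    centers <- matrix(numeric(0), 0, 2)
    classes <- character(0)
    add_nucleus <- function(cy, cx, nr, bright = 3200) {
      pxs <- disk_pixels(H, W, cy, cx, nr)
      if (!is.null(pxs)) draq5[pxs] <<- pmin(bright + rnorm(1, 0, 250), 4095)
      invisible(NULL)
    }
    paint_gland <- function(cy, cx, cls) {
      nr <- px(runif(1, params$nucleus_radius_um[1], params$nucleus_radius_um[2]))
      code <- legend[[if (cls == "GP4") "GP4" else if (cls == "GP5") "GP5"
                      else if (cls == "GP3") "GP3" else "Healthy"]]
      if (cls == "Healthy" || cls == "GP3") {
        r <- px(runif(1, params$gland_radius_um[1], params$gland_radius_um[2]))
        if (cls == "Healthy") r <- r * 1.5 else r <- r * 0.7
        lum <- r * params$lumen_fraction
        ring <- disk_pixels(H, W, cy, cx, r)
        if (is.null(ring)) return(FALSE)
        lpx <- disk_pixels(H, W, cy, cx, lum)
        label[ring] <<- code; epi[ring] <<- 1L
        eosin[ring] <<- pmin(eosin[ring] + 600, 4095)
        if (!is.null(lpx)) {
          label[lpx] <<- 0L; epi[lpx] <<- 0L
          eosin[lpx] <<- pmax(eosin[lpx] - 900, 60)
        }
        spacing <- if (cls == "Healthy") 3.2 * nr else 2.1 * nr
        rn <- (r + lum) / 2
        nth <- max(4, floor(2 * pi * rn / spacing))
        for (t in seq(0, 2 * pi, length.out = nth + 1)[-1]) {
          add_nucleus(cy + rn * sin(t + rnorm(1, 0, 0.08)),
                      cx + rn * cos(t + rnorm(1, 0, 0.08)), nr)
        }
      } else if (cls == "GP4") {
        r <- px(runif(1, params$gland_radius_um[1], params$gland_radius_um[2]))
        lobes <- rbind(c(cy, cx))
        n_extra <- if (runif(1) < params$fusion_prob) sample(2:3, 1) else 1
        for (e in seq_len(n_extra))
          lobes <- rbind(lobes, c(cy + rnorm(1, 0, r * 0.8), cx + rnorm(1, 0, r * 0.8)))
        island <- NULL
        for (li in seq_len(nrow(lobes))) {
          p <- disk_pixels(H, W, lobes[li, 1], lobes[li, 2], r)
          if (!is.null(p)) island <- rbind(island, p)
        }
        if (is.null(island)) return(FALSE)
        label[island] <<- code; epi[island] <<- 1L
        eosin[island] <<- pmin(eosin[island] + 700, 4095)
        # multiple small lumens per epithelial island (cribriform-like)
        for (li in seq_len(nrow(lobes))) {
          lp <- disk_pixels(H, W, lobes[li, 1] + rnorm(1, 0, r * 0.2),
                            lobes[li, 2] + rnorm(1, 0, r * 0.2), r * 0.22)
          if (!is.null(lp)) {
            keep <- label[lp] == code
            lp <- lp[keep, , drop = FALSE]
            label[lp] <<- 0L; epi[lp] <<- 0L
            eosin[lp] <<- pmax(eosin[lp] - 900, 60)
          }
        }
        # dense nuclei across the island
        n_nuc <- max(6, floor(nrow(island) / (9 * nr^2)))
        pick <- island[sample.int(nrow(island), min(n_nuc, nrow(island))), , drop = FALSE]
        for (q in seq_len(nrow(pick))) add_nucleus(pick[q, 1], pick[q, 2], nr)
      } else { # GP5
        r <- px(runif(1, params$gland_radius_um[1], params$gland_radius_um[2]))
        if (runif(1) < params$sheet_prob) r <- r * 1.3
        sheet <- disk_pixels(H, W, cy, cx, r)
        if (is.null(sheet)) return(FALSE)
        label[sheet] <<- code; epi[sheet] <<- 1L
        eosin[sheet] <<- pmin(eosin[sheet] + 500, 4095)
        n_nuc <- max(8, floor(nrow(sheet) / (6 * nr^2)))
        pick <- sheet[sample.int(nrow(sheet), min(n_nuc, nrow(sheet))), , drop = FALSE]
        for (q in seq_len(nrow(pick))) add_nucleus(pick[q, 1], pick[q, 2], nr)
      }
      TRUE
    }
    for (g in seq_len(params$n_glands)) {
      cls <- sample(names(params$class_mix), 1, prob = params$class_mix)
      placed <- FALSE
      for (try in 1:12) {
        cy <- runif(1, max_r, H - max_r)
        cx <- runif(1, max_r, W - max_r)
        min_sep <- px(mean(params$gland_radius_um)) *
          (if (cls == "Healthy") 2.6 else 1.6)
        if (nrow(centers) == 0 ||
            min((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) > min_sep^2) {
          placed <- paint_gland(cy, cx, cls)
          if (placed) {
            centers <- rbind(centers, c(cy, cx))
            classes <- c(classes, cls)
          }
          break
        }
      }
    }
    de <- de_image(image_plane(round(draq5), 12L, params$pixel_pitch_um),
                   image_plane(round(pmin(eosin, 4095)), 12L, params$pixel_pitch_um),
                   core_id = core_id, patient_id = patient_id)
    lm <- label_mask(label)
    em <- epithelial_mask(epi)
    he <- de_to_synthetic_he(de)
    list(de = de, label = lm, epi = em, he = he, gland_classes = classes,
         params = params)
  })
}

#' Generate a defocus z-stack from a plane
#'
#' Plane i is the input blurred with `sigma_px = k * |offset_i|`; offset 0
#' returns the input unchanged.
#' @param plane an `ImagePlane`.
#' @param offsets_um focus offsets (default the reference protocol grid).
#' @param k blur px per um of defocus (default 0.8).
#' @return list of `ImagePlane` in offset order.
#' @export
generate_zstack <- function(plane, offsets_um = c(-5, -2.5, 0, 2.5, 5), k = 0.8) {
  stopifnot(inherits(plane, "ImagePlane"), all(is.finite(offsets_um)))
  lapply(offsets_um, function(o) {
    m <- if (o == 0) plane$data else gauss_blur(plane$data, k * abs(o))
    image_plane(m, plane$bit_depth, plane$pixel_pitch_um)
  })
}

#' Generate a phantom cohort
#'
#' Derives a seed per core, cycles cores through per-core class mixes
#' (defaults: pure Healthy / GP3 / GP4 / GP5 cores, the tissue-microarray
#' situation of one dominant pattern per core) and assigns patients in
#' blocks of `cores_per_patient`.
#'
#' @param n_cores number of cores.
#' @param params_template a [phantom_params()] used for everything but the
#'   seed and class mix.
#' @param seed cohort seed.
#' @param cores_per_patient cores sharing one patient id (default 1).
#' @param per_core_mixes optional list of class-mix vectors cycled over
#'   cores; `NULL` uses the four pure mixes.
#' @return list with `cores` (list of [generate_core()] outputs) and
#'   `manifest` (data.frame core_id, patient_id, dominant_class, seed).
#' @export
generate_cohort <- function(n_cores, params_template = phantom_params(),
                            seed = 1L, cores_per_patient = 1L,
                            per_core_mixes = NULL) {
  stopifnot(n_cores >= 1)
  if (is.null(per_core_mixes)) {
    pure <- function(cls) {
      m <- c(Healthy = 0, GP3 = 0, GP4 = 0, GP5 = 0)
      m[cls] <- 1
      m
    }
    per_core_mixes <- list(pure("Healthy"), pure("GP3"), pure("GP4"), pure("GP5"))
  }
  cores <- vector("list", n_cores)
  rows <- vector("list", n_cores)
  for (i in seq_len(n_cores)) {
    p <- params_template
    p$rng_seed <- as.integer((seed * 131L + i * 17L) %% .Machine$integer.max)
    p$class_mix <- per_core_mixes[[(i - 1) %% length(per_core_mixes) + 1]]
    cid <- sprintf("core%03d", i)
    pid <- sprintf("patient%03d", (i - 1) %/% cores_per_patient + 1)
    cores[[i]] <- generate_core(p, core_id = cid, patient_id = pid)
    dom <- names(which.max(table(factor(cores[[i]]$gland_classes,
                                        levels = names(p$class_mix)))))
    rows[[i]] <- data.frame(core_id = cid, patient_id = pid,
                            dominant_class = dom, seed = p$rng_seed,
                            pixel_pitch_um = p$pixel_pitch_um)
  }
  list(cores = cores, manifest = do.call(rbind, rows))
}
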