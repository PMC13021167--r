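# End-to-end orchestration: phantom cohort -> preprocessing -> crop records
# -> folds -> training -> evaluation -> robustness, with seed control and a
# resolved-config echo in the run directory.

#' Default pipeline configuration
#'
#' All tunables of the end-to-end demo in one nested list. The `desk`
#' preset completes the whole run in minutes on one CPU (small canvases,
#' 128-px crops resized to 64-px model inputs, 8 base filters, reduced
#' augmentation); `paper` restores the published shapes and schedules.
#' Unknown keys passed to [run_pipeline()] are rejected.
#' @param preset `"desk"` or `"paper"`.
#' @param seed master seed; every stochastic stage derives from it.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  desk <- preset == "desk"
  structure(list(
    preset = preset,
    seed = as.integer(seed),
    out_dir = NULL,
    n_cores = if (desk) 24L else 128L,
    cores_per_patient = 1L,
    canvas_px = if (desk) c(384L, 384L) else c(1024L, 1024L),
    crop_edge_um = if (desk) 66.56 else 245.52,
    input_px = if (desk) 64L else 256L,
    rolling_ball_radius = 50L,
    clahe_clip = 0.01,
    clahe_tiles = c(8L, 8L),
    augmentation = if (desk)
      list(n_flip = 40L, n_rot = 60L, n_noise = 20L, n_blur_noise = 20L,
           noise_variance_range = c(0, 0.5), blur_sigma_range = c(0, 5))
    else
      list(n_flip = 1000L, n_rot = 1500L, n_noise = 500L, n_blur_noise = 500L,
           noise_variance_range = c(0, 0.5), blur_sigma_range = c(0, 5)),
    n_folds = 5L,
    n_perm = 1000L,
    classification_task = "HIGH_VS_HEALTHY",
    val_fold = 0L,
    robustness = list(noise_sigma0 = 700, averaging_grid = c(8L, 4L, 2L, 1L),
                      n_seeds = 5L, max_crops = 40L)
  ), class = "PipelineConfig")
}

#' Build crop records for one phantom core
#'
#' The conditioning chain: rolling-ball background subtraction on both
#' fluorescence planes, epithelial gating of the annotation, physical-size
#' cropping, the crop-level labeling rules, then per-crop CLAHE, nearest
#' resize to the model input size and z-normalization. Raw (background-
#' corrected, pre-equalization) crop planes are retained for acquisition
#' simulation.
#'
#' @param core a [generate_core()] output (or a list with `de`, `label`,
#'   `epi`).
#' @param crop_edge_um physical crop edge.
#' @param input_px model input edge.
#' @param rolling_ball_radius radius for background subtraction (pixels).
#' @return list of crop records: `core_id`, `patient_id`, `box`, `label`,
#'   `removal_reason`, `draq5`, `eosin` (processed matrices), `seg_mask`
#'   (input_px-sized 3-class target), `draq5_raw`, `eosin_raw`
#'   (`ImagePlane` crops). Removed crops carry no task targets.
#' @export
build_crop_records <- function(core, crop_edge_um = 66.56, input_px = 64L,
                               rolling_ball_radius = 50L) {
  de <- core$de
  d_corr <- rolling_ball_subtract(de$draq5, rolling_ball_radius)
  e_corr <- rolling_ball_subtract(de$eosin, rolling_ball_radius)
  gated <- gate_annotation(core$label, core$epi)
  boxes <- crop_boxes(dim(gated$data), de$draq5$pixel_pitch_um, crop_edge_um)
  out <- vector("list", length(boxes))
  for (i in seq_along(boxes)) {
    box <- boxes[[i]]
    gmask <- label_mask(crop_box(gated$data, box), gated$legend)
    lab <- assign_crop_label(gmask)
    rec <- list(core_id = de$core_id, patient_id = de$patient_id, box = box,
                label = lab$label, removal_reason = lab$removal_reason)
    if (is.na(lab$removal_reason)) {
      dcrop <- image_plane(crop_box(d_corr$data, box), de$draq5$bit_depth,
                           de$draq5$pixel_pitch_um)
      ecrop <- image_plane(crop_box(e_corr$data, box), de$eosin$bit_depth,
                           de$eosin$pixel_pitch_um)
      rec$draq5_raw <- dcrop
      rec$eosin_raw <- ecrop
      rec$draq5 <- znorm(resize_nearest(clahe(dcrop), c(input_px, input_px)))
      rec$eosin <- znorm(resize_nearest(clahe(ecrop), c(input_px, input_px)))
      rec$seg_mask <- map_to_task(
        label_mask(resize_nearest(gmask$data, c(input_px, input_px)), gated$legend),
        "CANCER_SEG")
    }
    out[[i]] <- rec
  }
  out
}

#' Crop manifest
#'
#' One row per crop across a list of records, with provenance, label and
#' removal reason — the package's crop CSV dialect.
#' @param records flat list of crop records.
#' @return data.frame.
#' @export
crop_manifest <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(core_id = r$core_id, patient_id = r$patient_id,
               r0 = r$box[1], r1 = r$box[2], c0 = r$box[3], c1 = r$box[4],
               label = ifelse(is.na(r$label), "", r$label),
               removal_reason = ifelse(is.na(r$removal_reason), "",
                                       r$removal_reason))))
}

records_to_xy <- function(records, task) {
  if (task == "CANCER_SEG") {
    list(x = lapply(records, function(r) {
           a <- array(0, c(dim(r$draq5), 2))
           a[, , 1] <- r$draq5; a[, , 2] <- r$eosin
           a
         }),
         y = lapply(records, function(r) r$seg_mask))
  } else {
    keep <- !vapply(records, function(r) is.na(map_to_task(r$label, task)),
                    logical(1))
    recs <- records[keep]
    list(x = lapply(recs, function(r) {
           a <- array(0, c(dim(r$draq5), 2))
           a[, , 1] <- r$draq5; a[, , 2] <- r$eosin
           a
         }),
         y = vapply(recs, function(r) map_to_task(r$label, task), integer(1)),
         records = recs)
  }
}

#' Run the end-to-end pipeline
#'
#' Stages run in dependency order: `phantom` (cohort generation), `crops`
#' (conditioning + labeling), `folds` (balanced patient-atomic split),
#' `train` (classifier and cancer-segmentation U-Net on the non-validation
#' folds, with augmentation), `evaluate` (held-out fold metrics),
#' `robustness` (the averaging/noise axis of the standardization grid).
#' Artifacts (manifests, metrics JSON, the resolved config) land under
#' `config$out_dir` when set. Re-running with an identical config
#' reproduces identical manifests and metrics.
#'
#' @param config a [pipeline_config()]; unknown keys are rejected.
#' @param stages character subset of
#'   `c("phantom","crops","folds","train","evaluate","robustness")`.
#' @return invisible list of stage artifacts (cohort, records, folds,
#'   models, metrics, robustness table).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("phantom", "crops", "folds", "train",
                                    "evaluate", "robustness")) {
  known <- names(pipeline_config())
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                                pretty = TRUE), file.path(out_dir, "config.json"))
  }
  art <- list(config = config)
  need <- function(stage, field) {
    if (is.null(art[[field]]))
      stop("stage '", stage, "' requires the missing upstream stage artifact '",
           field, "'; run its stage first")
  }

  if ("phantom" %in% stages) {
    art$cohort <- generate_cohort(config$n_cores,
      phantom_params(canvas_px = config$canvas_px),
      seed = config$seed, cores_per_patient = config$cores_per_patient)
    if (!is.null(out_dir))
      write_manifest(art$cohort$manifest, file.path(out_dir, "cohort.csv"))
  }

  if ("crops" %in% stages) {
    need("crops", "cohort")
    art$records <- list()
    for (core in art$cohort$cores) {
      art$records <- c(art$records,
        build_crop_records(core, config$crop_edge_um, config$input_px,
                           config$rolling_ball_radius))
    }
    art$kept <- Filter(function(r) is.na(r$removal_reason), art$records)
    if (!is.null(out_dir))
      write_manifest(crop_manifest(art$records), file.path(out_dir, "crops.csv"))
  }

  if ("folds" %in% stages) {
    need("folds", "kept")
    task <- config$classification_task
    fold_df <- do.call(rbind, lapply(art$kept, function(r)
      data.frame(core_id = r$core_id, patient_id = r$patient_id,
                 label01 = map_to_task(r$label, task))))
    art$folds <- build_balanced_folds(fold_df, n_folds = config$n_folds,
                                      n_perm = config$n_perm,
                                      seed = config$seed + 1L)
    if (!is.null(out_dir)) {
      ctf <- art$folds$core_to_fold
      write_manifest(data.frame(core_id = names(ctf), fold = unname(ctf)),
                     file.path(out_dir, "folds.csv"))
    }
  }

  if ("train" %in% stages) {
    need("train", "folds")
    split <- fold_split(art$folds, config$val_fold)
    in_train <- vapply(art$kept, function(r) r$core_id %in% split$train, logical(1))
    specs <- default_model_specs(config$preset, seed = config$seed + 2L)
    aug <- do.call(augmentation_spec,
                   c(config$augmentation, list(seed = config$seed + 3L)))

    tr_recs <- art$kept[in_train]
    va_recs <- art$kept[!in_train]
    # classifier: augmented crops join the training set of the chosen task
    task <- config$classification_task
    aug_in <- lapply(tr_recs, function(r)
      list(draq5 = r$draq5, eosin = r$eosin, mask = r$seg_mask,
           label = r$label, core_id = r$core_id, patient_id = r$patient_id))
    aug_out <- lapply(augment_crops(aug_in, aug), function(r) {
      r$seg_mask <- r$mask
      r$removal_reason <- NA_character_
      r
    })
    tr_aug <- c(tr_recs, aug_out)
    cls_tr <- records_to_xy(tr_aug, task)
    cls_va <- records_to_xy(va_recs, task)
    cls <- build_model(specs$classifier)
    art$classifier_fit <- train_model(cls, cls_tr$x, cls_tr$y, cls_va$x, cls_va$y)

    seg_tr <- records_to_xy(tr_aug, "CANCER_SEG")
    seg_va <- records_to_xy(va_recs, "CANCER_SEG")
    seg <- build_model(specs$cancer_unet)
    art$segmenter_fit <- train_model(seg, seg_tr$x, seg_tr$y, seg_va$x, seg_va$y)
  }

  if ("evaluate" %in% stages) {
    need("evaluate", "classifier_fit")
    split <- fold_split(art$folds, config$val_fold)
    va_recs <- Filter(function(r) r$core_id %in% split$val, art$kept)
    task <- config$classification_task
    cls_va <- records_to_xy(va_recs, task)
    probs <- predict_model(art$classifier_fit$model, cls_va$x)
    art$metrics <- list()
    art$metrics[[task]] <- evaluate_task(task, probs, cls_va$y)
    seg_va <- records_to_xy(va_recs, "CANCER_SEG")
    preds <- predict_model(art$segmenter_fit$model, seg_va$x)
    art$metrics$CANCER_SEG <- evaluate_task("CANCER_SEG", preds, seg_va$y)
    if (!is.null(out_dir)) {
      mj <- lapply(art$metrics, function(m) unclass(m))
      writeLines(jsonlite::toJSON(mj, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, null = "null"),
                 file.path(out_dir, "metrics.json"))
    }
  }

  if ("robustness" %in% stages) {
    need("robustness", "classifier_fit")
    split <- fold_split(art$folds, config$val_fold)
    va_recs <- Filter(function(r) r$core_id %in% split$val, art$kept)
    task <- config$classification_task
    cls_va <- records_to_xy(va_recs, task)
    recs <- cls_va$records
    keep <- seq_len(min(length(recs), config$robustness$max_crops))
    pset <- lapply(keep, function(i) {
      r <- recs[[i]]
      list(draq5_raw = r$draq5_raw, eosin_raw = r$eosin_raw,
           label01 = cls_va$y[i])
    })
    grid <- lapply(config$robustness$averaging_grid, function(a)
      acquisition_config(0, a, 0.52, "L20x_na08"))
    tabs <- list()
    for (s in seq_len(config$robustness$n_seeds)) {
      tab <- robustness_report(art$classifier_fit$model, pset, grid, task,
                               noise_sigma0 = config$robustness$noise_sigma0,
                               seed = config$seed + 100L * s)
      tab$noise_seed <- s
      tabs[[s]] <- tab
    }
    art$robustness <- do.call(rbind, tabs)
    if (!is.null(out_dir))
      write.csv(art$robustness, file.path(out_dir, "robustness.csv"),
                row.names = FALSE)
  }
  invisible(art)
}
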