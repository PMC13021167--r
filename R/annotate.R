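# Ground-truth construction: epithelial gating, crop labeling rules,
# slide-level grade presence, task mappings, stain normalization.

#' Task identifiers
#'
#' The three binary classification tasks and the 3-class cancer segmentation
#' task. For binary tasks the first-named class codes 1, the second 0.
#' @return character vector of task names.
#' @export
task_names <- function() c("LOW_VS_HEALTHY", "HIGH_VS_HEALTHY", "HIGH_VS_LOW", "CANCER_SEG")

low_grade_classes <- function() c("GP3")
high_grade_classes <- function() c("GP4", "Cribriform", "Glomeruloid", "GP5")

#' Gate an annotation mask by the epithelial mask
#'
#' Annotation survives only where the epithelial mask is 1; everything else
#' becomes background. Idempotent.
#' @param ann a `LabelMask`.
#' @param epi an `EpithelialMask` of the same shape.
#' @return gated `LabelMask`.
#' @export
gate_annotation <- function(ann, epi) {
  stopifnot(inherits(ann, "LabelMask"), inherits(epi, "EpithelialMask"),
            identical(dim(ann$data), dim(epi$data)))
  label_mask(ann$data * epi$data, legend = ann$legend)
}

#' Assign a ground-truth class to one crop
#'
#' The predominant class is the modal non-background class (ties break to
#' the lowest legend code; any two-way tie necessarily fails the 75% purity
#' rule). Removal rules, applied in order: no annotated pixel at all
#' (`no_annotation`); predominant class under 15% of all crop pixels
#' (`below_15pct`); predominant class under 75% of annotated pixels
#' (`below_75pct`).
#'
#' @param gated_crop_mask `LabelMask` for the crop, already epithelially gated.
#' @param min_crop_frac,min_purity_frac the 15% and 75% thresholds.
#' @return list with `label` (class name or `NA`), `code`, and
#'   `removal_reason` (`NA` if kept).
#' @export
assign_crop_label <- function(gated_crop_mask, min_crop_frac = 0.15,
                              min_purity_frac = 0.75) {
  m <- gated_crop_mask$data
  legend <- gated_crop_mask$legend
  total <- length(m)
  fg <- m[m != 0L]
  if (length(fg) == 0)
    return(list(label = NA_character_, code = NA_integer_,
                removal_reason = "no_annotation"))
  counts <- table(fg)
  top_count <- max(counts)
  top_code <- min(as.integer(names(counts)[counts == top_count]))
  if (top_count < min_crop_frac * total)
    return(list(label = NA_character_, code = NA_integer_,
                removal_reason = "below_15pct"))
  if (top_count < min_purity_frac * length(fg))
    return(list(label = NA_character_, code = NA_integer_,
                removal_reason = "below_75pct"))
  list(label = names(legend)[match(top_code, legend)], code = top_code,
       removal_reason = NA_character_)
}

#' Grades present in a slide
#'
#' A class counts as present when its epithelially-gated pixel count reaches
#' `min_frac` of all epithelial pixels (default 5%).
#' @param slide_mask a `LabelMask`.
#' @param epi an `EpithelialMask` of the same shape.
#' @param min_frac presence threshold (default 0.05).
#' @return character vector of present class names (possibly empty).
#' @export
grade_presence <- function(slide_mask, epi, min_frac = 0.05) {
  gated <- gate_annotation(slide_mask, epi)$data
  n_epi <- sum(epi$data)
  if (n_epi == 0) return(character(0))
  counts <- table(gated[gated != 0L])
  codes <- as.integer(names(counts))[counts >= min_frac * n_epi]
  legend <- slide_mask$legend
  names(legend)[match(codes, legend)]
}

#' Map a raw class (or mask) onto a task target
#'
#' Low grade = GP3; high grade = GP4, Cribriform, Glomeruloid, GP5. Binary
#' tasks return 1 for the first-named side, 0 for the second, and `NA`
#' (excluded sentinel) for classes outside the pair. `CANCER_SEG` maps a
#' `LabelMask` elementwise: background/stroma 0, healthy epithelium 1, any
#' cancer class 2.
#'
#' @param x class name (for binary tasks) or `LabelMask` (for CANCER_SEG).
#' @param task one of [task_names()].
#' @return 0/1/`NA` for binary tasks; integer matrix for CANCER_SEG.
#' @export
map_to_task <- function(x, task) {
  task <- match.arg(task, task_names())
  if (task == "CANCER_SEG") {
    stopifnot(inherits(x, "LabelMask"))
    legend <- x$legend
    cancer_codes <- unname(legend[c(low_grade_classes(), high_grade_classes())])
    out <- matrix(0L, nrow(x$data), ncol(x$data))
    out[x$data == legend[["Healthy"]]] <- 1L
    out[x$data %in% cancer_codes] <- 2L
    return(out)
  }
  grp <- function(cls) {
    if (cls %in% low_grade_classes()) "LOW"
    else if (cls %in% high_grade_classes()) "HIGH"
    else if (cls == "Healthy") "HEALTHY"
    else "OTHER"
  }
  g <- grp(x)
  sides <- strsplit(task, "_VS_")[[1]]
  if (g == sides[1]) 1L else if (g == sides[2]) 0L else NA_integer_
}

# --- stain normalization ---------------------------------------------------

#' Luminosity standardization
#'
#' Rescales an RGB image so its 95th-percentile luminance maps to white,
#' removing global illumination differences before stain estimation.
#' @param src an `RGBImage`.
#' @param percentile luminance percentile mapped to 255 (default 95).
#' @return an `RGBImage`.
#' @export
luminosity_standardize <- function(src, percentile = 95) {
  lum <- rgb_to_gray(src)
  p <- as.numeric(quantile(lum, percentile / 100))
  if (p <= 0) return(src)
  rgb_image(pmin(round(src$data * (255 / p)), 255), src$pixel_pitch_um)
}

# multiplicative-update non-negative factorization OD ~ C %*% S
# (n_px x 3) ~ (n_px x 2) (2 x 3); S rows L2-normalized each sweep
nmf_stains <- function(od, n_iter = 200, s_init = NULL, eps = 1e-8) {
  if (is.null(s_init))
    s_init <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  s <- s_init / sqrt(rowSums(s_init^2))
  c_mat <- pmax(od %*% t(s), eps)
  for (it in seq_len(n_iter)) {
    c_mat <- c_mat * (od %*% t(s)) / (c_mat %*% s %*% t(s) + eps)
    c_mat <- pmax(c_mat, 0)
    s <- s * (t(c_mat) %*% od) / (t(c_mat) %*% c_mat %*% s + eps)
    s <- pmax(s, 0)
    nrm <- sqrt(rowSums(s^2))
    nrm[nrm == 0] <- 1
    s <- s / nrm
  }
  list(concentrations = pmax(od %*% t(s) %*% solve(s %*% t(s) + diag(2) * eps), 0),
       stains = s)
}

rgb_to_od <- function(rgbdata) -log((rgbdata + 1) / 256)
od_to_rgb <- function(od) pmin(pmax(256 * exp(-od) - 1, 0), 255)

#' Estimate a two-stain matrix and concentrations from an RGB image
#'
#' Converts to optical density and factorizes `OD ~ C S` with non-negative
#' concentrations `C` (pixels x 2) and stain matrix `S` (2 x 3, unit rows)
#' by multiplicative updates initialized at conventional H&E directions.
#' Near-white pixels (OD below `beta`) are excluded from the estimation.
#' @param src an `RGBImage`.
#' @param beta OD threshold excluding background pixels (default 0.15).
#' @param n_iter update sweeps.
#' @return list with `stains` (2x3), `concentrations` (pixels x 2 for all
#'   pixels), `shape`.
#' @export
estimate_stains <- function(src, beta = 0.15, n_iter = 200) {
  d <- src$data
  od <- cbind(as.vector(rgb_to_od(d[, , 1])), as.vector(rgb_to_od(d[, , 2])),
              as.vector(rgb_to_od(d[, , 3])))
  keep <- rowSums(od) > beta
  if (sum(keep) < 10) return(NULL)
  fit <- nmf_stains(od[keep, , drop = FALSE], n_iter = n_iter)
  s <- fit$stains
  # order rows as (hematoxylin-like, eosin-like): hematoxylin absorbs red
  # relatively more than eosin does
  if (s[1, 1] / (s[1, 2] + 1e-8) < s[2, 1] / (s[2, 2] + 1e-8))
    s <- s[2:1, , drop = FALSE]
  conc <- pmax(od %*% t(s) %*% solve(s %*% t(s) + diag(2) * 1e-8), 0)
  list(stains = s, concentrations = conc, shape = dim(d)[1:2])
}

#' Stain-normalize an RGB image against a target
#'
#' Luminosity-standardizes the source, estimates its two-stain factorization
#' in optical density, rescales each stain's concentrations so the 99th
#' percentile matches the target's, swaps in the target's stain matrix and
#' re-exponentiates. A near-white source (no OD signal) returns the
#' luminosity-standardized source with a warning.
#'
#' @param src,target `RGBImage` objects with non-white content.
#' @return an `RGBImage` in the target's stain space.
#' @export
stain_normalize <- function(src, target) {
  src_std <- luminosity_standardize(src)
  fit_s <- estimate_stains(src_std)
  fit_t <- estimate_stains(luminosity_standardize(target))
  if (is.null(fit_s) || is.null(fit_t)) {
    warning("insufficient stain signal: returning luminosity-standardized source")
    return(src_std)
  }
  cs <- fit_s$concentrations
  ct <- fit_t$concentrations
  for (k in 1:2) {
    ps <- as.numeric(quantile(cs[, k], 0.99))
    pt <- as.numeric(quantile(ct[, k], 0.99))
    if (ps > 0) cs[, k] <- cs[, k] * (pt / ps)
  }
  od_new <- cs %*% fit_t$stains
  sh <- fit_s$shape
  out <- array(0, c(sh, 3))
  for (ch in 1:3) out[, , ch] <- matrix(od_to_rgb(od_new[, ch]), sh[1], sh[2])
  rgb_image(round(out), src$pixel_pitch_um)
}

#' Predict the epithelial mask of an H&E image
#'
#' The inference chain around a trained epithelial segmentation model:
#' tissue masking, physical-size cropping, per-crop luminosity
#' standardization + stain normalization against a reference, per-channel
#' CLAHE, scaling to `[0,1]`, nearest resize to the model's input size,
#' inference, nearest resize back, thresholding at 0.5; pixels outside the
#' tissue mask are forced to background.
#'
#' @param he an `RGBImage`.
#' @param model either a trained segmentation model from [train_model()] or
#'   a function `(array H x W x 3 in [0,1]) -> probability matrix`.
#' @param target_ref `RGBImage` stain-normalization target, or `NULL` to
#'   skip stain normalization.
#' @param crop_edge_um physical crop size (default 245.52).
#' @param input_px model input edge (default 256).
#' @param threshold probability threshold (default 0.5).
#' @return an `EpithelialMask`.
#' @export
predict_epithelium <- function(he, model, target_ref = NULL,
                               crop_edge_um = 245.52, input_px = 256L,
                               threshold = 0.5) {
  tmask <- tissue_mask(he)
  out <- matrix(0L, nrow(tmask), ncol(tmask))
  boxes <- crop_boxes(dim(tmask), he$pixel_pitch_um, crop_edge_um)
  infer <- if (is.function(model)) model else function(x) predict_model(model, list(x))[[1]]
  for (box in boxes) {
    crop <- rgb_image(crop_box(he$data, box), he$pixel_pitch_um)
    crop <- luminosity_standardize(crop)
    if (!is.null(target_ref)) crop <- stain_normalize(crop, target_ref)
    arr <- crop$data
    for (ch in 1:3) arr[, , ch] <- clahe(arr[, , ch]) * 255
    arr <- resize_nearest(arr / 255, c(input_px, input_px))
    prob <- infer(arr)
    if (is.list(prob)) prob <- prob[[1]]
    prob <- if (length(dim(prob)) == 3) prob[, , 1] else as.matrix(prob)
    full <- resize_nearest(prob, c(box[2] - box[1], box[4] - box[3]))
    out <- uncrop_box(out, box, as.integer(full >= threshold))
  }
  epithelial_mask(out * tmask)
}
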