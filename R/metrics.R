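# Evaluation statistics: Dice, Jaccard, accuracy, Cohen kappa (unweighted
# and quadratic-weighted), ROC AUC, and per-task report assembly.

#' Dice and Jaccard overlap of two binary rasters
#'
#' `dice = 2|a&b| / (|a|+|b|)`, `jaccard = |a&b| / |a|b|`; two empty masks
#' score (1, 1) by convention (avoids NaN on empty classes in small
#' phantoms).
#' @param a,b binary rasters (0/1) of equal shape.
#' @return named numeric vector `c(dice=, jaccard=)`.
#' @export
dice_jaccard <- function(a, b) {
  a <- raster_of(a); b <- raster_of(b)
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a == 1 & b == 1)
  sa <- sum(a == 1); sb <- sum(b == 1)
  if (sa + sb == 0) return(c(dice = 1, jaccard = 1))
  uni <- sa + sb - inter
  c(dice = 2 * inter / (sa + sb), jaccard = inter / uni)
}

#' Cohen's kappa
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` over the confusion matrix `O` and
#' the chance-expected matrix `E`, with weights `w_ij = (i - j)^2`
#' (quadratic) or `1[i != j]` (unweighted). If truth and prediction are both
#' a single identical class, kappa is defined as 1 (0 if they differ), with
#' a warning.
#' @param y_true,y_pred equal-length label vectors (any shared alphabet;
#'   ordinal order for quadratic weights is the sorted alphabet).
#' @param weights `"none"` or `"quadratic"`.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(y_true, y_pred, weights = c("none", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  lev <- sort(union(unique(y_true), unique(y_pred)))
  k <- length(lev)
  if (k == 1) {
    warning("single-class truth and prediction: kappa degenerate")
    return(if (all(y_true == y_pred)) 1 else 0)
  }
  O <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(k)
  w <- if (weights == "quadratic") outer(idx, idx, function(i, j) (i - j)^2)
       else outer(idx, idx, function(i, j) as.numeric(i != j))
  denom <- sum(w * E)
  if (denom == 0) {
    warning("degenerate chance agreement: kappa defined by identity")
    return(if (all(y_true == y_pred)) 1 else 0)
  }
  1 - sum(w * O) / denom
}

#' ROC AUC (Mann-Whitney formulation)
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, counting ties as 1/2 — computed from midranks, so it is
#' invariant under strictly monotone transforms of the scores.
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 truth; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble the metrics report for one task
#'
#' Binary tasks: accuracy/kappa at the 0.5 threshold, plus AUC.
#' `CANCER_SEG`: per-class Dice (background / healthy / cancer), pixel
#' accuracy, and kappa (unweighted and quadratic) over pixel labels.
#'
#' @param task one of [task_names()].
#' @param predictions binary tasks: numeric probability vector. CANCER_SEG:
#'   list of H x W x 3 probability arrays or H x W hard class matrices.
#' @param truth binary tasks: 0/1 vector. CANCER_SEG: list of H x W integer
#'   masks with values 0..2.
#' @param threshold binary decision threshold (default 0.5).
#' @return a `MetricsReport` list.
#' @export
evaluate_task <- function(task, predictions, truth, threshold = 0.5) {
  task <- match.arg(task, task_names())
  if (task == "CANCER_SEG") {
    hard <- lapply(predictions, function(p) {
      if (length(dim(p)) == 3) {
        matrix(max.col(matrix(p, ncol = dim(p)[3])) - 1L, dim(p)[1], dim(p)[2])
      } else p
    })
    yp <- unlist(lapply(hard, as.vector))
    yt <- unlist(lapply(truth, as.vector))
    dice <- vapply(0:2, function(cl)
      dice_jaccard((yp == cl) * 1, (yt == cl) * 1)[["dice"]], numeric(1))
    rep <- list(task = task, accuracy = mean(yp == yt),
                kappa = cohen_kappa(yt, yp, "none"),
                kappa_quadratic = cohen_kappa(yt, yp, "quadratic"),
                auc = NA_real_,
                dice_per_class = list(background = dice[1], healthy = dice[2],
                                      cancer = dice[3]),
                n = length(truth))
  } else {
    yp <- as.integer(predictions >= threshold)
    yt <- as.integer(truth)
    rep <- list(task = task, accuracy = mean(yp == yt),
                kappa = cohen_kappa(yt, yp, "none"),
                kappa_quadratic = cohen_kappa(yt, yp, "quadratic"),
                auc = roc_auc(predictions, yt),
                dice_per_class = NULL, n = length(truth))
  }
  structure(rep, class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport [%s]  n=%d  acc=%.4f  kappa=%.4f", x$task, x$n,
              x$accuracy, x$kappa))
  if (!is.na(x$auc)) cat(sprintf("  auc=%.4f", x$auc))
  if (!is.null(x$dice_per_class))
    cat(sprintf("  dice(bg/healthy/cancer)=%.3f/%.3f/%.3f",
                x$dice_per_class$background, x$dice_per_class$healthy,
                x$dice_per_class$cancer))
  cat("\n")
  invisible(x)
}
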