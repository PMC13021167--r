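# Patient-level, class-balanced k-fold cross-validation via random
# permutation search.

#' Build class-balanced, patient-atomic folds
#'
#' For each of `n_perm` seeded random permutations, patients are dealt in
#' order into `n_folds` groups of (as near as possible) equal patient counts
#' — leftovers beyond equal group sizes go to the last fold. Each candidate
#' assignment is scored by the mean squared error between the per-fold
#' class-0/class-1 crop-count ratios and 1; the assignment with the smallest
#' MSE wins. A fold with zero class-1 crops scores that permutation +Inf, so
#' it is never selected. All cores of one patient always share a fold.
#'
#' @param records data.frame with columns `core_id`, `patient_id`, `label01`
#'   (0/1 task label per crop; `NA` rows are ignored), e.g. from
#'   [crop_manifest()] after [map_to_task()].
#' @param n_folds number of folds (default 5).
#' @param n_perm number of sampled permutations (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return a `FoldAssignment`: list with `core_to_fold` (named integer
#'   vector, folds 0-based), `patient_to_fold`, `mse`, `seed`, `n_perm`,
#'   `n_folds`.
#' @export
build_balanced_folds <- function(records, n_folds = 5L, n_perm = 1000L, seed = 1L) {
  stopifnot(all(c("core_id", "patient_id", "label01") %in% names(records)))
  rec <- records[!is.na(records$label01), , drop = FALSE]
  if (!all(rec$label01 %in% c(0, 1)))
    stop("label01 must be 0/1 (after task mapping)")
  if (length(unique(rec$label01)) < 2)
    stop("both task classes must be present in the data")
  patients <- sort(unique(records$patient_id))
  n_pat <- length(patients)
  if (n_pat < n_folds) stop("need at least n_folds distinct patients")
  # per-patient class counts (crops)
  c0 <- vapply(patients, function(p) sum(rec$patient_id == p & rec$label01 == 0), numeric(1))
  c1 <- vapply(patients, function(p) sum(rec$patient_id == p & rec$label01 == 1), numeric(1))
  base_size <- n_pat %/% n_folds
  # dealing scheme: first base_size shuffled patients -> fold 0, next ->
  # fold 1, ...; leftovers appended to the last fold
  fold_of_pos <- c(rep(0:(n_folds - 1), each = base_size),
                   rep(n_folds - 1, n_pat - base_size * n_folds))
  best <- NULL
  best_mse <- Inf
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n_pat)
      f0 <- rowsum(c0[perm], fold_of_pos)[, 1]
      f1 <- rowsum(c1[perm], fold_of_pos)[, 1]
      if (any(f1 == 0)) next
      mse <- mean((f0 / f1 - 1)^2)
      if (mse < best_mse) {
        best_mse <- mse
        best <- perm
      }
    }
  })
  if (is.null(best))
    stop("no permutation produced folds with both classes; data too sparse")
  pat_fold <- integer(n_pat)
  pat_fold[best] <- fold_of_pos
  pat_fold <- stats::setNames(pat_fold, patients)
  core_pat <- unique(records[, c("core_id", "patient_id")])
  core_to_fold <- stats::setNames(pat_fold[core_pat$patient_id], core_pat$core_id)
  structure(list(core_to_fold = core_to_fold, patient_to_fold = pat_fold,
                 mse = best_mse, seed = seed, n_perm = n_perm,
                 n_folds = as.integer(n_folds)),
            class = "FoldAssignment")
}

#' Split cores into training and validation sets by fold
#'
#' @param assignment a `FoldAssignment`.
#' @param val_fold 0-based validation fold index.
#' @return list with `train` and `val` core-id character vectors; disjoint,
#'   covering all cores, with no patient on both sides.
#' @export
fold_split <- function(assignment, val_fold) {
  stopifnot(inherits(assignment, "FoldAssignment"),
            val_fold >= 0, val_fold < assignment$n_folds)
  ctf <- assignment$core_to_fold
  val <- names(ctf)[ctf == val_fold]
  train <- names(ctf)[ctf != val_fold]
  # patient-leakage guard: asserted on every split
  pf <- assignment$patient_to_fold
  stopifnot(!any(names(pf)[pf == val_fold] %in% names(pf)[pf != val_fold]))
  list(train = train, val = val)
}
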