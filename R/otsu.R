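#' Multi-Otsu thresholding
#'
#' Places `n_classes - 1` thresholds on a binned intensity histogram so that
#' the between-class variance (equivalently, the weighted sum of squared
#' class means) is maximized. The search is exact: a dynamic program over
#' cumulative histogram moments, O(n_classes * n_bins^2).
#'
#' @param x an `ImagePlane`, a numeric matrix of intensities, or a histogram
#'   given as a numeric vector of counts (`names(x)` or the attribute
#'   `mids` supply bin-center intensities; unnamed counts are taken at
#'   intensities `0:(length(x)-1)`).
#' @param n_classes number of classes, 2..5.
#' @param n_bins number of histogram bins when `x` is an image (default 255,
#'   the pipeline's convention).
#' @return numeric vector of `n_classes - 1` strictly increasing thresholds,
#'   expressed as bin-center intensities on the input scale. A pixel belongs
#'   to class k when it lies in `(t[k-1], t[k]]`-style bins; callers use
#'   strict `<` comparisons against these centers.
#' @export
multi_otsu <- function(x, n_classes = 3, n_bins = 255) {
  stopifnot(n_classes >= 2, n_classes <= 5)
  if (n_bins < n_classes) stop("n_bins must be >= n_classes")
  if (inherits(x, "ImagePlane")) x <- x$data
  if (is.matrix(x)) {
    v <- as.vector(x)
    rng <- range(v)
    if (rng[1] == rng[2])
      stop("constant image: multi-Otsu thresholds are undefined")
    # skimage-style binning over the data range; bin centers carry the scale
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    counts <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), n_bins), n_bins)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  } else {
    counts <- as.numeric(x)
    mids <- if (!is.null(attr(x, "mids"))) attr(x, "mids")
            else if (!is.null(names(x))) as.numeric(names(x))
            else seq_len(length(x)) - 1
    if (sum(counts > 0) < n_classes)
      stop("histogram has fewer occupied bins than classes")
  }
  L <- length(counts)
  p <- counts / sum(counts)
  P <- cumsum(p)
  M <- cumsum(p * mids)
  # seg(i, j): weight * mean^2 of bins i..j  (1-based, inclusive)
  segval <- function(i, j) {
    w <- P[j] - if (i > 1) P[i - 1] else 0
    if (w <= 0) return(0)
    m <- M[j] - if (i > 1) M[i - 1] else 0
    m^2 / w
  }
  k <- n_classes
  # DP over last-bin-of-class: best[c, j] = max value of first c classes using bins 1..j
  best <- matrix(-Inf, k, L)
  argb <- matrix(NA_integer_, k, L)
  for (j in 1:L) best[1, j] <- segval(1, j)
  for (cl in 2:k) {
    for (j in cl:L) {
      # class cl occupies bins (i+1)..j
      cand <- (cl - 1):(j - 1)
      vals <- vapply(cand, function(i) best[cl - 1, i] + segval(i + 1, j),
                     numeric(1))
      # ties (runs of empty bins) resolve to the highest cut, so thresholds
      # sit just below the next occupied population and strict '<' tests on
      # pixel values select exactly the lower populations
      w <- max(which(vals >= max(vals) - 1e-12))
      best[cl, j] <- vals[w]
      argb[cl, j] <- cand[w]
    }
  }
  cuts <- integer(k - 1)
  j <- L
  for (cl in k:2) {
    j <- argb[cl, j]
    cuts[cl - 1] <- j
  }
  mids[cuts]
}
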