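# Shared fixtures, generated in code at test time.

# tri-modal H&E-like phantom: dark nuclei disks on pink stroma with white
# lumens; returns the image plus the exact nuclei/lumen pixel sets
trimodal_he <- function(n = 96, nuclei_val = 40, stroma_val = 190,
                        lumen_val = 255, seed = 11) {
  set.seed(seed)
  img <- array(stroma_val, c(n, n, 3))
  nuc <- matrix(FALSE, n, n)
  lum <- matrix(FALSE, n, n)
  paint <- function(mask, cy, cx, r) {
    d2 <- outer((1:n - cy)^2, (1:n - cx)^2, `+`)
    mask | (d2 <= r^2)
  }
  for (i in 1:6) nuc <- paint(nuc, sample(10:(n - 10), 1), sample(10:(n - 10), 1), 4)
  for (i in 1:3) lum <- paint(lum, sample(15:(n - 15), 1), sample(15:(n - 15), 1), 7)
  nuc <- nuc & !lum
  for (ch in 1:3) {
    sl <- img[, , ch]
    sl[lum] <- lumen_val
    sl[nuc] <- nuclei_val
    img[, , ch] <- sl
  }
  list(he = rgb_image(img, 0.52), nuclei = nuc, lumen = lum)
}

# brute-force multi-Otsu: exhaustive search over threshold tuples on a
# histogram, maximizing the weighted sum of squared class means
exhaustive_otsu <- function(counts, mids, n_classes) {
  L <- length(counts)
  p <- counts / sum(counts)
  bcv <- function(cuts) {
    b <- c(0, cuts, L)
    s <- 0
    for (k in seq_len(length(b) - 1)) {
      ii <- (b[k] + 1):b[k + 1]
      w <- sum(p[ii])
      if (w > 0) s <- s + sum(p[ii] * mids[ii])^2 / w
    }
    s
  }
  # ties (runs of empty bins) break to the highest cuts, the package's
  # convention, so strict '<' pixel tests select the lower populations
  best <- -Inf; bestc <- NULL
  if (n_classes == 2) {
    for (i in 1:(L - 1)) {
      v <- bcv(i)
      if (v >= best - 1e-12) { best <- max(v, best); bestc <- i }
    }
  } else if (n_classes == 3) {
    for (i in 1:(L - 2)) for (j in (i + 1):(L - 1)) {
      v <- bcv(c(i, j))
      if (v >= best - 1e-12) { best <- max(v, best); bestc <- c(i, j) }
    }
  } else stop("oracle supports 2 or 3 classes")
  list(thresholds = mids[bestc], objective = best, bcv = bcv)
}

# histogram of a matrix matching multi_otsu's internal binning
otsu_histogram <- function(m, n_bins = 255) {
  v <- as.vector(m)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE), n_bins), n_bins)
  list(counts = counts, mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

# random LabelMask over the full legend
random_label_mask <- function(n = 20, seed = 1) {
  set.seed(seed)
  label_mask(matrix(sample(0:6, n * n, replace = TRUE,
                           prob = c(.5, .1, .1, .1, .07, .06, .07)), n, n))
}

random_epi_mask <- function(n = 20, seed = 2) {
  set.seed(seed)
  epithelial_mask(matrix(rbinom(n * n, 1, 0.6), n, n))
}

small_phantom_core <- function(seed = 5, canvas = c(256L, 256L),
                               mix = c(Healthy = .4, GP3 = .2, GP4 = .2, GP5 = .2)) {
  generate_core(phantom_params(canvas_px = canvas, n_glands = 24L,
                               gland_radius_um = c(8, 14),
                               class_mix = mix, rng_seed = seed),
                core_id = paste0("c", seed), patient_id = paste0("p", seed))
}

# independent oracle: grayscale opening with an explicitly rasterized
# paraboloid structuring element (direct 2-D min/max over the full support)
paraboloid_opening_oracle <- function(m, radius, maxv) {
  hw <- min(ceiling(sqrt(2 * radius * maxv)), 2 * radius, max(dim(m)) - 1)
  offs <- expand.grid(dy = -hw:hw, dx = -hw:hw)
  offs$p <- (offs$dy^2 + offs$dx^2) / (2 * radius)
  H <- nrow(m); W <- ncol(m)
  ero <- matrix(Inf, H, W)
  for (k in seq_len(nrow(offs))) {
    sy <- (1:H) + offs$dy[k]; sx <- (1:W) + offs$dx[k]
    oky <- sy >= 1 & sy <= H; okx <- sx >= 1 & sx <= W
    if (!any(oky) || !any(okx)) next
    ero[oky, okx] <- pmin(ero[oky, okx],
                          m[sy[oky], sx[okx], drop = FALSE] - offs$p[k])
  }
  dil <- matrix(-Inf, H, W)
  for (k in seq_len(nrow(offs))) {
    sy <- (1:H) + offs$dy[k]; sx <- (1:W) + offs$dx[k]
    oky <- sy >= 1 & sy <= H; okx <- sx >= 1 & sx <= W
    if (!any(oky) || !any(okx)) next
    dil[oky, okx] <- pmax(dil[oky, okx],
                          ero[sy[oky], sx[okx], drop = FALSE] + offs$p[k])
  }
  dil
}
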