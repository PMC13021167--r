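test_that("multi_otsu matches exhaustive search on random histograms", {
  set.seed(10)
  for (rep in 1:50) {
    L <- sample(8:64, 1)
    k <- sample(2:3, 1)
    h <- runif(L, 0.01, 10)
    attr(h, "mids") <- 0:(L - 1)
    got <- multi_otsu(h, n_classes = k, n_bins = L)
    orc <- exhaustive_otsu(h, 0:(L - 1), k)
    # compare achieved objective (thresholds may tie on degenerate draws)
    cuts <- match(got, 0:(L - 1))
    expect_equal(orc$bcv(cuts), orc$objective, tolerance = 1e-10)
  }
})

test_that("multi_otsu separates a two-point histogram and validates arguments", {
  h <- numeric(256)
  h[11] <- 5; h[201] <- 7   # mass at intensities 10 and 200
  attr(h, "mids") <- 0:255
  t1 <- multi_otsu(h, n_classes = 2, n_bins = 256)
  expect_gt(t1, 10)
  expect_lte(t1, 200)
  expect_error(multi_otsu(matrix(7, 5, 5), 2), "constant")
  expect_error(multi_otsu(h, n_classes = 3, n_bins = 2), "n_bins")
  expect_identical(formals(multi_otsu)$n_bins, 255)
})

test_that("nuclei mask matches an exhaustive-threshold oracle on tri-modal phantoms", {
  fx <- trimodal_he()
  g <- rgb_to_gray(fx$he)
  hist <- otsu_histogram(g, 255)
  orc <- exhaustive_otsu(hist$counts, hist$mids, 3)
  oracle_mask <- (g < orc$thresholds[1]) * 1
  oracle_mask <- matrix(as.integer(round(as.matrix(
    EBImage::erode(oracle_mask, EBImage::makeBrush(3, "disc"))))), nrow(g))
  got <- nuclei_mask_from_he(fx$he)
  expect_identical(got, oracle_mask)
  expect_true(all(got[!fx$nuclei] == 0))
})

test_that("nuclei mask degenerate cases: white image and isolated pixels", {
  white <- rgb_image(array(255, c(16, 16, 3)), 1)
  expect_warning(m <- nuclei_mask_from_he(white), "constant")
  expect_true(all(m == 0))
  # a single dark pixel is erased by the erosion
  img <- array(200, c(16, 16, 3))
  img[8, 8, ] <- 10
  expect_true(all(nuclei_mask_from_he(rgb_image(img, 1)) == 0))
})

test_that("synthetic D&E: empty mask with zero noise gives an all-zero DRAQ5 plane", {
  white <- rgb_image(array(255, c(24, 24, 3)), 0.52)
  warns <- capture_warnings(
    de <- he_to_synthetic_de(white, synthetic_de_params(noise_variance = 0)))
  expect_match(warns, "zero-variance|constant", all = FALSE)
  expect_true(all(de$draq5$data == 0))
})

test_that("synthetic D&E is seed-reproducible and support-contained", {
  fx <- trimodal_he(n = 64)
  prm <- synthetic_de_params(noise_variance = 0, rng_seed = 9)
  de1 <- he_to_synthetic_de(fx$he, prm)
  de2 <- he_to_synthetic_de(fx$he, prm)
  expect_identical(de1$draq5$data, de2$draq5$data)
  expect_identical(de1$eosin$data, de2$eosin$data)

  # with noise off, DRAQ5 support is contained in the dilated nuclei mask
  nm <- nuclei_mask_from_he(fx$he, prm$erosion_radius_px)
  support <- synthetic_draq5_support(nm, prm)
  # planes are z-normalized: "zero" pixels share the plane minimum offset
  d <- de1$draq5$data
  nonzero <- abs(d - min(d)) > 1e-9
  expect_true(all(support[nonzero] == 1))
  # Eosin is zero (minimum) on the pre-dilation nuclei mask interior
  e <- de1$eosin$data
  # interior eroded past the dilation + smoothing footprint (1 + 2 px)
  core_nuc <- as.matrix(EBImage::erode(nm, EBImage::makeBrush(7, "disc"))) > 0
  if (any(core_nuc)) expect_true(all(abs(e[core_nuc] - min(e)) < 1e-9))
})

test_that("Beer-Lambert recoloring matches the closed-form formula", {
  prm <- synthetic_he_params(gamma_draq5 = 1.5, gamma_eosin = 2,
                             od_hematoxylin_rgb = c(0.6, 0.2, 0.1),
                             od_eosin_rgb = c(0.05, 0.8, 0.1))
  d <- image_plane(matrix(c(4095, 1000), 1, 2), 12L, 0.52)
  e <- image_plane(matrix(c(0, 2000), 1, 2), 12L, 0.52)
  he <- de_to_synthetic_he(de_image(d, e), prm)
  dn <- c(1, 1000 / 4095)^1.5
  en <- c(0, 1)^2
  for (ch in 1:3) {
    want <- round(pmin(255 * exp(-(prm$od_hematoxylin_rgb[ch] * dn +
                                   prm$od_eosin_rgb[ch] * en)), 255))
    expect_equal(he$data[1, , ch], want)
  }
})

test_that("zero D&E input renders uniform white and responses are monotone", {
  z <- image_plane(matrix(0, 8, 8), 12L, 0.52)
  he <- de_to_synthetic_he(de_image(z, z))
  expect_true(all(he$data == 255))

  # increasing DRAQ5 at one pixel can only darken every channel there
  set.seed(3)
  base <- matrix(runif(64, 0, 4000), 8, 8)
  e <- image_plane(matrix(runif(64, 0, 4000), 8, 8), 12L, 0.52)
  lo <- base; hi <- base
  lo[4, 4] <- 500; hi[4, 4] <- 3000
  base[1, 1] <- 4095  # pin the plane maximum so normalization is shared
  lo[1, 1] <- 4095; hi[1, 1] <- 4095
  he_lo <- de_to_synthetic_he(de_image(image_plane(lo, 12L, 0.52), e))
  he_hi <- de_to_synthetic_he(de_image(image_plane(hi, 12L, 0.52), e))
  expect_true(all(he_hi$data[4, 4, ] <= he_lo$data[4, 4, ]))
})

test_that("phantom round trip keeps nuclei darker and bluer than stroma", {
  fx <- trimodal_he(n = 64)
  de <- he_to_synthetic_de(fx$he, synthetic_de_params(noise_variance = 0))
  he2 <- de_to_synthetic_he(de)
  nuc <- fx$nuclei & nuclei_mask_from_he(fx$he) > 0
  stroma <- !fx$nuclei & !fx$lumen
  # blue-dominant darkness: nuclei keep relatively more blue than red
  nuc_rb <- mean(he2$data[, , 1][nuc]) - mean(he2$data[, , 3][nuc])
  str_rb <- mean(he2$data[, , 1][stroma]) - mean(he2$data[, , 3][stroma])
  expect_lt(nuc_rb, str_rb)
  expect_lt(mean(he2$data[, , 1][nuc]), mean(he2$data[, , 1][stroma]))
})
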