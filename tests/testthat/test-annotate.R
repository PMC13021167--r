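test_that("epithelial gating equals the elementwise masking oracle and is idempotent", {
  ann <- random_label_mask(24, seed = 31)
  epi <- random_epi_mask(24, seed = 32)
  g <- gate_annotation(ann, epi)
  expect_identical(g$data, ann$data * epi$data)
  expect_identical(gate_annotation(g, epi)$data, g$data)
  ones <- epithelial_mask(matrix(1L, 24, 24))
  expect_identical(gate_annotation(ann, ones)$data, ann$data)
  zeros <- epithelial_mask(matrix(0L, 24, 24))
  expect_true(all(gate_annotation(ann, zeros)$data == 0))
})

test_that("crop labeling applies the 15% and 75% removal rules in order", {
  mk <- function(fill) label_mask(matrix(fill, 10, 10))
  # all background
  expect_equal(assign_crop_label(mk(0L))$removal_reason, "no_annotation")
  # GP3 30 px, Healthy 5 px, rest background: 30% of crop, 85.7% purity
  m <- matrix(0L, 10, 10); m[1:30] <- 2L; m[31:35] <- 1L
  r <- assign_crop_label(label_mask(m))
  expect_equal(r$label, "GP3")
  expect_true(is.na(r$removal_reason))
  # GP3 10 px only: under the 15%-of-crop floor
  m <- matrix(0L, 10, 10); m[1:10] <- 2L
  expect_equal(assign_crop_label(label_mask(m))$removal_reason, "below_15pct")
  # two-way tie GP3/GP4 at 35 px each: purity 50% fails the 75% rule
  m <- matrix(0L, 10, 10); m[1:35] <- 2L; m[36:70] <- 3L
  expect_equal(assign_crop_label(label_mask(m))$removal_reason, "below_75pct")
})

test_that("crop labeling is rotation-invariant and matches a recount oracle", {
  oracle <- function(m) {
    fg <- m[m != 0]
    if (!length(fg)) return("no_annotation")
    cnt <- sort(table(fg), decreasing = TRUE)
    top <- as.integer(names(cnt))[cnt == max(cnt)]
    if (max(cnt) < 0.15 * length(m)) return("below_15pct")
    if (max(cnt) < 0.75 * length(fg)) return("below_75pct")
    names(annotation_legend())[match(min(top), annotation_legend())]
  }
  set.seed(33)
  for (i in 1:40) {
    m <- matrix(sample(0:6, 64, TRUE, prob = c(runif(1, 0.2, 3), runif(6))), 8, 8)
    lm <- label_mask(m)
    r <- assign_crop_label(lm)
    got <- if (is.na(r$removal_reason)) r$label else r$removal_reason
    expect_identical(got, oracle(m))
    rot <- label_mask(t(m[8:1, ]))
    r2 <- assign_crop_label(rot)
    expect_identical(r2$label, r$label)
    expect_identical(r2$removal_reason, r$removal_reason)
  }
})

test_that("grade presence uses the 5% epithelial-pixel floor", {
  m <- matrix(1L, 20, 20)
  epi <- epithelial_mask(matrix(1L, 20, 20))
  m[1:16] <- 3L  # 4% GP4, 96% Healthy
  expect_identical(grade_presence(label_mask(m), epi), "Healthy")
  m[1:20] <- 3L  # 5% exactly: included
  expect_setequal(grade_presence(label_mask(m), epi), c("Healthy", "GP4"))
  expect_length(grade_presence(label_mask(m), epithelial_mask(matrix(0L, 20, 20))), 0)
})

test_that("task mapping groups grades and builds 3-class rasters", {
  expect_equal(map_to_task("Cribriform", "HIGH_VS_HEALTHY"), 1L)
  expect_equal(map_to_task("Healthy", "HIGH_VS_HEALTHY"), 0L)
  expect_equal(map_to_task("GP3", "LOW_VS_HEALTHY"), 1L)
  expect_equal(map_to_task("GP5", "HIGH_VS_LOW"), 1L)
  expect_equal(map_to_task("GP3", "HIGH_VS_LOW"), 0L)
  expect_true(is.na(map_to_task("Healthy", "HIGH_VS_LOW")))
  m <- matrix(1L, 10, 10); m[, 6:10] <- 6L
  seg <- map_to_task(label_mask(m), "CANCER_SEG")
  expect_true(all(seg[, 1:5] == 1L) && all(seg[, 6:10] == 2L))
  # elementwise oracle over a random mask
  lm <- random_label_mask(16, seed = 34)
  seg2 <- map_to_task(lm, "CANCER_SEG")
  want <- matrix(0L, 16, 16)
  want[lm$data == 1L] <- 1L
  want[lm$data >= 2L] <- 2L
  expect_identical(seg2, want)
})

test_that("stain normalization is close to identity against itself", {
  fx <- trimodal_he(n = 64, seed = 35)
  out <- stain_normalize(fx$he, fx$he)
  mad <- mean(abs(out$data - luminosity_standardize(fx$he)$data))
  expect_lt(mad, 5)
})

test_that("stain estimation recovers a known two-stain factorization", {
  set.seed(36)
  s_true <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  s_true <- s_true / sqrt(rowSums(s_true^2))
  n <- 40
  conc <- cbind(runif(n * n, 0, 1.2), runif(n * n, 0, 1.2))
  od <- conc %*% s_true
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pmin(pmax(256 * exp(-od[, ch]) - 1, 0), 255), n, n)
  fit <- estimate_stains(rgb_image(round(img), 1))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(fit$stains[1, ], s_true[1, ]), 0.95)
  expect_gt(cosine(fit$stains[2, ], s_true[2, ]), 0.95)
})

test_that("normalizing two color casts to one target pulls them together", {
  fx <- trimodal_he(n = 64, seed = 37)
  recast <- function(he, gains) {
    d <- he$data
    for (ch in 1:3) d[, , ch] <- pmin(round(d[, , ch] * gains[ch]), 255)
    rgb_image(d, he$pixel_pitch_um)
  }
  a <- recast(fx$he, c(1.2, 0.9, 0.8))
  b <- recast(fx$he, c(0.8, 1.0, 1.15))
  gap <- function(x, y) sum(abs(apply(x$data, 3, mean) - apply(y$data, 3, mean)))
  pre <- gap(a, b)
  post <- gap(stain_normalize(a, fx$he), stain_normalize(b, fx$he))
  expect_lt(post, pre)
})

test_that("near-white sources fall back to luminosity standardization", {
  white <- rgb_image(array(254, c(16, 16, 3)), 1)
  fx <- trimodal_he(n = 32, seed = 38)
  expect_warning(out <- stain_normalize(white, fx$he), "insufficient")
  expect_s3_class(out, "RGBImage")
})

test_that("epithelium prediction is gated by the tissue mask", {
  # white slide: everything outside tissue is background, whatever the model
  white <- rgb_image(array(255, c(64, 64, 3)), 1)
  always_on <- function(x) matrix(1, dim(x)[1], dim(x)[2])
  suppressWarnings(m <- predict_epithelium(white, always_on, target_ref = NULL,
                                           crop_edge_um = 32, input_px = 16L))
  expect_true(all(m$data == 0))

  # identity-model harness: a phantom whose epithelium the "model" knows
  core <- small_phantom_core(seed = 39, canvas = c(128L, 128L))
  truth <- core$epi$data
  oracle_model <- local({
    i <- 0
    boxes <- crop_boxes(dim(truth), core$he$pixel_pitch_um, 33.28)
    function(x) {
      i <<- i + 1
      crop_box(truth, boxes[[i]])
    }
  })
  got <- predict_epithelium(core$he, oracle_model, target_ref = NULL,
                            crop_edge_um = 33.28, input_px = 64L)
  tmask <- tissue_mask(core$he)
  expect_identical(got$data, matrix(as.integer(truth * tmask), nrow(truth)))
  # output is always a subset of the tissue mask
  expect_true(all(got$data <= tmask))

  # constant-probability model: threshold at 0.5 keeps the tissue gate
  flat <- function(x) matrix(0.5, dim(x)[1], dim(x)[2])
  got2 <- predict_epithelium(core$he, flat, target_ref = NULL,
                             crop_edge_um = 33.28, input_px = 64L)
  expect_identical(got2$data, matrix(as.integer(tmask), nrow(truth)))
})
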