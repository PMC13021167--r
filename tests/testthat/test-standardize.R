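test_that("sharpness score matches hand evaluation and detects blur", {
  expect_equal(sharpness_score(matrix(7, 4, 4)), 0)
  # 2x2 plane [[0,1],[0,1]]: column gradient 1 everywhere, row gradient 0
  m <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(sharpness_score(m), 1)
  set.seed(61)
  step <- matrix(0, 32, 32)
  step[, 17:32] <- 100
  step <- step + matrix(rnorm(1024, 0, 2), 32)
  blurred <- fluorograde:::gauss_blur(step, 2)
  expect_lt(sharpness_score(blurred), sharpness_score(step))
})

test_that("focus ranking recovers a known blur order and breaks ties by index", {
  set.seed(62)
  base <- matrix(runif(64 * 64, 0, 4000), 64, 64)
  sigmas <- c(3, 0, 4, 1, 2)
  stack <- lapply(sigmas, function(s)
    image_plane(if (s == 0) base else fluorograde:::gauss_blur(base, s), 12L, 0.52))
  rf <- rank_focus(stack)
  expect_equal(rf$ranks, c(4L, 1L, 5L, 2L, 3L))
  expect_equal(rf$best, 2L)
  same <- rank_focus(list(stack[[1]], stack[[1]], stack[[1]]))
  expect_equal(same$ranks, 1:3)
  expect_equal(rank_focus(stack[2])$ranks, 1L)
})

test_that("the identity acquisition configuration is bit-exact", {
  core <- small_phantom_core(seed = 63, canvas = c(128L, 128L))
  cfg <- acquisition_config(0, 8L, 0.52, "L20x_na08")
  sim <- simulate_acquisition(core$de, cfg, noise_sigma0 = 0, seed = 1)
  expect_identical(sim$draq5$data, core$de$draq5$data)
  expect_identical(sim$eosin$data, core$de$eosin$data)
})

test_that("simulated noise scales as one over the square root of averaging", {
  flat <- image_plane(matrix(2000, 100, 100), 12L, 0.52)
  de <- de_image(flat, flat)
  sd_at <- function(avg, seed) {
    cfg <- acquisition_config(0, avg, 0.52, "L20x_na08")
    sim <- simulate_acquisition(de, cfg, noise_sigma0 = 120, seed = seed)
    sd(as.vector(sim$draq5$data))
  }
  ratio <- sd_at(2L, 5) / sd_at(8L, 6)
  expect_lt(abs(ratio - 2), 0.1)  # sqrt(8/2) = 2 within 5%
})

test_that("defocus and the wide lens lower sharpness; resampling changes pitch", {
  core <- small_phantom_core(seed = 64, canvas = c(128L, 128L))
  sc <- vapply(c(0, 2.5, 5), function(f) {
    cfg <- acquisition_config(f, 8L, 0.52, "L20x_na08")
    sharpness_score(simulate_acquisition(core$de, cfg, 0, 1)$draq5)
  }, numeric(1))
  expect_true(all(diff(sc) < 0))
  lens <- simulate_acquisition(core$de,
    acquisition_config(0, 8L, 0.52, "L10x_na045"), 0, 1)
  expect_lt(sharpness_score(lens$draq5), sc[1])
  coarse <- simulate_acquisition(core$de,
    acquisition_config(0, 8L, 0.69, "L20x_na08"), 0, 1)
  expect_equal(coarse$draq5$pixel_pitch_um, 0.69)
  expect_equal(nrow(coarse$draq5$data), round(128 * 0.52 / 0.69))
  expect_error(acquisition_config(1.3, 8L, 0.52), "focus_offset")
  expect_silent(acquisition_config(0, 8L, 10, custom = TRUE))
})

test_that("phase correlation recovers exact integer shifts", {
  set.seed(65)
  a <- matrix(rnorm(96 * 80), 96, 80)
  expect_equal(phase_shift(a, a), c(0L, 0L))
  for (i in 1:20) {
    dr <- sample(-20:20, 1); dc <- sample(-20:20, 1)
    b <- a[((seq_len(96) - 1 - dr) %% 96) + 1, ((seq_len(80) - 1 - dc) %% 80) + 1]
    expect_equal(phase_shift(a, b), c(dr, dc))
  }
  expect_error(phase_shift(matrix(1, 8, 8), a[1:8, 1:8]), "constant")
})

test_that("hierarchical registration restores globally shifted masks", {
  core <- small_phantom_core(seed = 66, canvas = c(192L, 192L))
  mask <- core$epi$data
  expect_gte(mean(mask), 0.2)
  ref <- core$de$draq5$data * 0 + mask  # self-reference
  moved <- fluorograde:::shift_matrix(mask, 3, 2)
  pre <- dice_jaccard(moved, mask)[["dice"]]
  reg <- hierarchical_register(epithelial_mask(moved), mask)
  post <- dice_jaccard(reg$data, mask)[["dice"]]
  expect_gte(post, pre)
  expect_gte(post, 0.95)
  # zero-shift input is untouched
  same <- hierarchical_register(epithelial_mask(mask), mask)
  expect_identical(same$data, mask)
  expect_warning(hierarchical_register(epithelial_mask(mask[1:32, 1:32]),
                                       mask[1:32, 1:32]), "skipped")
})

test_that("robustness report composes simulation, conditioning and evaluation", {
  core <- small_phantom_core(seed = 67, canvas = c(128L, 128L))
  boxes <- crop_boxes(dim(core$epi$data), 0.52, 33.28)
  pset <- lapply(seq_along(boxes), function(i) {
    list(draq5_raw = image_plane(crop_box(core$de$draq5$data, boxes[[i]]), 12L, 0.52),
         eosin_raw = image_plane(crop_box(core$de$eosin$data, boxes[[i]]), 12L, 0.52),
         label01 = i %% 2)
  })
  spec <- model_spec("classifier_cnn", c(32L, 32L, 2L), 4L,
                     loss = "binary_cross_entropy", seed = 2)
  model <- build_model(spec)

  expect_equal(nrow(robustness_report(model, pset, list(), "HIGH_VS_HEALTHY")), 0)

  grid <- list(acquisition_config(0, 8L, 0.52, "L20x_na08"))
  tab <- robustness_report(model, pset, grid, "HIGH_VS_HEALTHY",
                           noise_sigma0 = 0, seed = 1)
  # identity config equals plain evaluation of the conditioned crops
  xs <- lapply(pset, function(r)
    fluorograde:::de_to_model_input(de_image(r$draq5_raw, r$eosin_raw), 32L))
  direct <- evaluate_task("HIGH_VS_HEALTHY", predict_model(model, xs),
                          vapply(pset, `[[`, numeric(1), "label01"))
  expect_equal(tab$auc, direct$auc)
  expect_equal(tab$accuracy, direct$accuracy)
})
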