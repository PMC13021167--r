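test_that("model building is seed-deterministic with lawful parameter counts", {
  spec <- model_spec("unet_4c3e", c(32L, 32L, 2L), 4L, loss = "dice", seed = 11)
  m1 <- build_model(spec)
  m2 <- build_model(spec)
  expect_identical(m1$params, m2$params)
  deeper <- build_model(model_spec("unet_6c5e", c(64L, 64L, 2L), 4L,
                                   loss = "sparse_categorical_cross_entropy",
                                   seed = 11))
  expect_gt(n_parameters(deeper), n_parameters(m1))
  # parameter count is a pure function of the spec, not the seed
  m3 <- build_model(model_spec("unet_4c3e", c(32L, 32L, 2L), 4L,
                               loss = "dice", seed = 99))
  expect_equal(n_parameters(m3), n_parameters(m1))
  expect_false(identical(m3$params, m1$params))
  expect_error(model_spec("classifier_cnn", c(64L, 64L, 3L)), "2 input channels")
  expect_error(model_spec("unet_6c5e", c(40L, 40L, 2L)), "divisible")
})

test_that("the default augmentation schedule yields exactly 3500 crops", {
  set.seed(12)
  crops <- lapply(1:3, function(i)
    list(draq5 = matrix(rnorm(64), 8, 8), eosin = matrix(rnorm(64), 8, 8),
         mask = matrix(sample(0:2, 64, TRUE), 8, 8), label = "GP3"))
  spec <- augmentation_spec(seed = 5)
  out <- augment_crops(crops, spec)
  expect_length(out, 3500)
  expect_equal(sum(grepl("flip", vapply(out, `[[`, "", "augmented"))), 1000)
  expect_equal(sum(grepl("rot", vapply(out, `[[`, "", "augmented"))), 1500)
  # deterministic under the seed
  out2 <- augment_crops(crops, spec)
  expect_identical(out[[7]]$draq5, out2[[7]]$draq5)
})

test_that("geometric augmentations are involutive and move masks with pixels", {
  set.seed(13)
  crops <- list(list(draq5 = matrix(rnorm(100), 10, 10),
                     eosin = matrix(rnorm(100), 10, 10),
                     mask = matrix(sample(0:2, 100, TRUE), 10, 10)))
  spec <- augmentation_spec(n_flip = 8, n_rot = 0, n_noise = 0,
                            n_blur_noise = 0, seed = 3)
  for (rec in augment_crops(crops, spec)) {
    geom <- if (rec$augmented == "flip_h") function(m) m[, ncol(m):1]
            else function(m) m[nrow(m):1, ]
    # applying the flip again recovers the source crop bit-exactly
    expect_identical(geom(rec$draq5), crops[[1]]$draq5)
    # the mask moved with the pixels under the same transform
    expect_identical(geom(rec$mask), crops[[1]]$mask)
  }
  spec_r <- augmentation_spec(n_flip = 0, n_rot = 9, n_noise = 0,
                              n_blur_noise = 0, seed = 4)
  for (rec in augment_crops(crops, spec_r)) {
    k <- switch(rec$augmented, rot90 = 3L, rot180 = 2L, rot270 = 1L)
    undo <- fluorograde:::rot90cw(rec$draq5, k)
    expect_identical(undo, crops[[1]]$draq5)
    expect_identical(fluorograde:::rot90cw(rec$mask, k), crops[[1]]$mask)
  }
})

test_that("noise augmentation respects the sampled variance range", {
  set.seed(14)
  crops <- list(list(draq5 = matrix(0, 40, 40), eosin = matrix(0, 40, 40)))
  # pin the variance to a point mass: empirical sd must match sqrt(v)
  spec <- augmentation_spec(n_flip = 0, n_rot = 0, n_noise = 30,
                            n_blur_noise = 0,
                            noise_variance_range = c(0.2, 0.2), seed = 6)
  out <- augment_crops(crops, spec)
  sds <- vapply(out, function(r) sd(as.vector(r$draq5)), numeric(1))
  expect_lt(abs(mean(sds) - sqrt(0.2)), 0.02)
  # with the full range, per-crop variances stay within [0, 0.5]
  spec2 <- augmentation_spec(n_flip = 0, n_rot = 0, n_noise = 200,
                             n_blur_noise = 0, seed = 7)
  out2 <- augment_crops(crops, spec2)
  v <- vapply(out2, function(r) var(as.vector(r$draq5)), numeric(1))
  expect_true(all(v < 0.62))  # 0.5 plus sampling slack at n = 1600
  spec3 <- augmentation_spec(n_flip = 0, n_rot = 0, n_noise = 0,
                             n_blur_noise = 40, seed = 8)
  crops3 <- list(list(draq5 = matrix(rnorm(1600), 40, 40),
                      eosin = matrix(rnorm(1600), 40, 40),
                      mask = matrix(1L, 40, 40)))
  out3 <- augment_crops(crops3, spec3)
  # masks are never blurred or noised
  for (r in out3) expect_identical(r$mask, crops3[[1]]$mask)
})

test_that("training selects the epoch with the lowest validation loss", {
  set.seed(15)
  mk <- function(mu) {
    a <- array(rnorm(16 * 16 * 2, 0, 1), c(16, 16, 2))
    a[, , 1] <- a[, , 1] + mu
    a
  }
  xs <- c(lapply(1:12, function(i) mk(1)), lapply(1:12, function(i) mk(-1)))
  ys <- rep(c(1, 0), each = 12)
  spec <- model_spec("classifier_cnn", c(16L, 16L, 2L), 4L,
                     init = "xavier_uniform", loss = "binary_cross_entropy",
                     lr = 2e-3, epochs = 6L, batch_size = 6L, seed = 16)
  fit <- train_model(build_model(spec), xs, ys, xs[c(1:4, 13:16)], ys[c(1:4, 13:16)])
  h <- fit$history
  expect_length(h$val_loss, 6)
  expect_equal(h$selected_epoch, which.min(h$val_loss) - 1L)
  # the separable problem is learned: loss falls, accuracy is high
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_gte(mean((predict_model(fit$model, xs) > 0.5) == ys), 0.9)
  # the returned weights reproduce exactly the selected validation loss
  expect_equal(fluorograde:::model_loss(fit$model, xs[c(1:4, 13:16)],
                                        ys[c(1:4, 13:16)]),
               min(h$val_loss))
})

test_that("fine-tuning with zero epochs is a no-op and defaults are family-aware", {
  spec <- model_spec("classifier_cnn", c(16L, 16L, 2L), 2L,
                     loss = "binary_cross_entropy", epochs = 3L, seed = 17)
  m <- build_model(spec)
  xs <- lapply(1:4, function(i) array(rnorm(512), c(16, 16, 2)))
  ys <- c(0, 1, 0, 1)
  ft <- finetune_model(m, xs, ys, xs, ys, epochs = 0L)
  expect_identical(ft$model$params, m$params)
  ft2 <- finetune_model(m, xs, ys, xs, ys, epochs = 1L)
  expect_false(identical(ft2$model$params, m$params))
})

test_that("fold selection uses the right criterion with earliest-index ties", {
  mk <- function(kappa, dice) {
    structure(list(task = "CANCER_SEG", accuracy = 0.5, kappa = kappa,
                   kappa_quadratic = kappa, auc = NA_real_,
                   dice_per_class = list(background = dice[1],
                                         healthy = dice[2], cancer = dice[3]),
                   n = 10), class = "MetricsReport")
  }
  res <- list(mk(0.4, c(.5, .5, .5)), mk(0.7, c(.1, .1, .1)),
              mk(0.1, c(.9, .8, .9)), mk(0.7, c(.2, .2, .2)), mk(0.2, c(0, 0, 0)))
  expect_equal(select_fold(res, "max_kappa"), 1L)
  expect_equal(select_fold(res, "max_dice_sum"), 2L)
  expect_equal(select_fold(res[1], "max_kappa"), 0L)
})
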