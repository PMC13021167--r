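# Model builders, the augmentation schedule, seeded training with
# best-epoch selection, fine-tuning and fold selection.

#' Specify a model
#'
#' Three families: `classifier_cnn` (two-channel crop in, one sigmoid unit
#' out), `unet_4c3e` (four contraction / three expansion blocks, the
#' epithelial segmentation variant) and `unet_6c5e` (six contraction / five
#' expansion blocks, the cancer segmentation variant). U-Net contraction
#' blocks hold two 3x3 convolutions with filter counts doubling from
#' `base_filters`; expansion blocks mirror them with nearest upsampling and
#' skip concatenation; the head is a 1x1 convolution (sigmoid for binary
#' masks, softmax over 3 classes for cancer segmentation).
#'
#' @param family one of `classifier_cnn`, `unet_4c3e`, `unet_6c5e`.
#' @param input_shape integer triple (H, W, channels); H and W must be
#'   divisible by the network's pooling depth. The classifier requires 2
#'   input channels.
#' @param base_filters filters in the first block (default 16).
#' @param n_classes output classes for `unet_6c5e` segmentation (default 3).
#' @param init weight initializer, `he_normal` or `xavier_uniform`.
#' @param loss `dice`, `binary_cross_entropy` or
#'   `sparse_categorical_cross_entropy`.
#' @param lr Adam learning rate. @param epochs training epochs.
#' @param batch_size minibatch size. @param seed RNG seed for init/shuffles.
#' @return a `ModelSpec`.
#' @export
model_spec <- function(family = c("classifier_cnn", "unet_4c3e", "unet_6c5e"),
                       input_shape = c(64L, 64L, 2L), base_filters = 16L,
                       n_classes = 3L,
                       init = c("he_normal", "xavier_uniform"),
                       loss = c("dice", "binary_cross_entropy",
                                "sparse_categorical_cross_entropy"),
                       lr = 1e-3, epochs = 10L, batch_size = 8L, seed = 1L) {
  family <- match.arg(family)
  init <- match.arg(init)
  loss <- match.arg(loss)
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  if (family == "classifier_cnn" && input_shape[3] != 2)
    stop("classifier_cnn requires 2 input channels (DRAQ5 + Eosin)")
  n_down <- switch(family, classifier_cnn = 4L, unet_4c3e = 4L, unet_6c5e = 6L)
  div <- 2L^(n_down - 1L)
  if (family != "classifier_cnn" &&
      (input_shape[1] %% div != 0 || input_shape[2] %% div != 0))
    stop("U-Net input sides must be divisible by ", div)
  structure(list(family = family, input_shape = as.integer(input_shape),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes), init = init, loss = loss,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 n_down = n_down),
            class = "ModelSpec")
}

#' Reference training configurations
#'
#' The published hyperparameter registry (`paper` preset: 256-px inputs,
#' dice / binary CE / sparse categorical CE losses, Adam learning rates
#' 0.001 / 0.0001 / 0.02, 30 / 20 / 20 epochs, batch 32) and the package's
#' `desk` preset, scaled so each model trains in minutes on one CPU
#' (64-px inputs, 8 base filters, smaller batches, stability-adjusted
#' learning rates).
#' @param preset `"paper"` or `"desk"`.
#' @param seed seed stored in every spec.
#' @return named list of `ModelSpec`: `epithelial_unet`, `classifier`,
#'   `cancer_unet`.
#' @export
default_model_specs <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    list(
      epithelial_unet = model_spec("unet_4c3e", c(256L, 256L, 3L), 16L,
                                   init = "he_normal", loss = "dice",
                                   lr = 1e-3, epochs = 30L, batch_size = 32L,
                                   seed = seed),
      classifier = model_spec("classifier_cnn", c(256L, 256L, 2L), 16L,
                              init = "xavier_uniform",
                              loss = "binary_cross_entropy",
                              lr = 1e-4, epochs = 20L, batch_size = 32L,
                              seed = seed),
      cancer_unet = model_spec("unet_6c5e", c(256L, 256L, 2L), 16L,
                               init = "he_normal",
                               loss = "sparse_categorical_cross_entropy",
                               lr = 0.02, epochs = 20L, batch_size = 32L,
                               seed = seed))
  } else {
    list(
      epithelial_unet = model_spec("unet_4c3e", c(64L, 64L, 3L), 8L,
                                   init = "he_normal", loss = "dice",
                                   lr = 1e-3, epochs = 10L, batch_size = 8L,
                                   seed = seed),
      classifier = model_spec("classifier_cnn", c(64L, 64L, 2L), 8L,
                              init = "xavier_uniform",
                              loss = "binary_cross_entropy",
                              lr = 1e-3, epochs = 12L, batch_size = 8L,
                              seed = seed),
      cancer_unet = model_spec("unet_6c5e", c(64L, 64L, 2L), 8L,
                               init = "he_normal",
                               loss = "sparse_categorical_cross_entropy",
                               lr = 2e-3, epochs = 12L, batch_size = 8L,
                               seed = seed))
  }
}

#' Build an untrained model
#'
#' Weights are drawn under `spec$seed` with the spec's initializer; the
#' parameter count is a pure function of the spec.
#' @param spec a [model_spec()].
#' @return an `fg_model` (list of parameter arrays plus the spec).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "ModelSpec"))
  F0 <- spec$base_filters
  cin <- spec$input_shape[3]
  params <- list()
  with_seed(spec$seed, {
    if (spec$family == "classifier_cnn") {
      cs <- c(cin, F0, 2L * F0, 4L * F0, 8L * F0)
      for (b in 1:4)
        params[[paste0("conv", b)]] <- conv_param(cs[b], cs[b + 1], spec$init)
      params$fc1 <- dense_param(8L * F0, 32L, spec$init)
      params$fc2 <- dense_param(32L, 1L, spec$init)
    } else {
      nd <- spec$n_down
      fs <- F0 * 2L^(0:(nd - 1))
      for (b in 1:nd) {
        params[[paste0("enc", b, "a")]] <-
          conv_param(if (b == 1) cin else fs[b - 1], fs[b], spec$init)
        params[[paste0("enc", b, "b")]] <- conv_param(fs[b], fs[b], spec$init)
      }
      for (j in (nd - 1):1) {
        below <- if (j == nd - 1) fs[nd] else fs[j + 1]
        params[[paste0("dec", j, "a")]] <-
          conv_param(below + fs[j], fs[j], spec$init)
        params[[paste0("dec", j, "b")]] <- conv_param(fs[j], fs[j], spec$init)
      }
      outc <- if (spec$loss == "sparse_categorical_cross_entropy") spec$n_classes else 1L
      params$head <- dense_param(fs[1], outc, spec$init)
    }
  })
  structure(list(spec = spec, params = params), class = "fg_model")
}

#' Number of trainable parameters
#' @param model an `fg_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) sum(vapply(p, length, numeric(1))), numeric(1)))
}

# --- forward / backward ----------------------------------------------------

unet_forward <- function(params, X, shape, spec, keep_cache = FALSE) {
  nd <- spec$n_down
  caches <- list()
  skips <- list()
  cur <- X; sh <- shape
  for (b in 1:nd) {
    za <- conv3x3_forward(cur, sh, params[[paste0("enc", b, "a")]]$W,
                          params[[paste0("enc", b, "a")]]$b)
    aa <- relu_forward(za)
    zb <- conv3x3_forward(aa, sh, params[[paste0("enc", b, "b")]]$W,
                          params[[paste0("enc", b, "b")]]$b)
    ab <- relu_forward(zb)
    caches[[paste0("enc", b)]] <- list(xin = cur, za = za, aa = aa, zb = zb,
                                       ab = ab, shape = sh)
    if (b < nd) {
      skips[[b]] <- ab
      pl <- maxpool_forward(ab, sh)
      caches[[paste0("pool", b)]] <- pl
      cur <- pl$out
      sh <- pl$shape
    } else cur <- ab
  }
  for (j in (nd - 1):1) {
    up <- upsample_forward(cur, sh)
    sh <- up$shape
    cat_in <- cbind(skips[[j]], up$out)
    za <- conv3x3_forward(cat_in, sh, params[[paste0("dec", j, "a")]]$W,
                          params[[paste0("dec", j, "a")]]$b)
    aa <- relu_forward(za)
    zb <- conv3x3_forward(aa, sh, params[[paste0("dec", j, "b")]]$W,
                          params[[paste0("dec", j, "b")]]$b)
    ab <- relu_forward(zb)
    caches[[paste0("dec", j)]] <- list(up = up, cat_in = cat_in, za = za,
                                       aa = aa, zb = zb, ab = ab, shape = sh)
    cur <- ab
  }
  logits <- cur %*% params$head$W +
    matrix(rep(params$head$b, each = nrow(cur)), nrow(cur))
  list(logits = logits, last = cur,
       caches = if (keep_cache) caches else NULL, shape = sh)
}

unet_backward <- function(params, fwd, dLogits, spec) {
  nd <- spec$n_down
  caches <- fwd$caches
  grads <- list()
  grads$head <- list(W = crossprod(fwd$last, dLogits), b = colSums(dLogits))
  d <- dLogits %*% t(params$head$W)
  for (j in 1:(nd - 1)) {
    cc <- caches[[paste0("dec", j)]]
    d <- relu_backward(cc$zb, d)
    bw <- conv3x3_backward(cc$aa, cc$shape, params[[paste0("dec", j, "b")]]$W, d)
    grads[[paste0("dec", j, "b")]] <- list(W = bw$dW, b = bw$db)
    d <- relu_backward(cc$za, bw$dX)
    bw <- conv3x3_backward(cc$cat_in, cc$shape, params[[paste0("dec", j, "a")]]$W, d)
    grads[[paste0("dec", j, "a")]] <- list(W = bw$dW, b = bw$db)
    nskip <- ncol(caches[[paste0("enc", j)]]$ab)
    dskip <- bw$dX[, seq_len(nskip), drop = FALSE]
    dup <- bw$dX[, -seq_len(nskip), drop = FALSE]
    dbelow <- upsample_backward(caches[[paste0("dec", j)]]$up, dup,
                                nrow(caches[[paste0("dec", j)]]$up$out) %/% 4L)
    # skip gradient re-enters the encoder at level j; dbelow continues to
    # the next decoder block (or the encoder bottom when j == nd - 1)
    caches[[paste0("dec", j)]]$dskip <- dskip
    d <- dbelow
  }
  # encoder backward, from the bottom block up; d is now the gradient into
  # the bottom encoder block's output
  d_from_above <- d
  for (b in nd:1) {
    cc <- caches[[paste0("enc", b)]]
    d <- d_from_above
    if (b < nd) {
      dpool <- maxpool_backward(caches[[paste0("pool", b)]], d_from_above, nrow(cc$ab))
      d <- dpool + caches[[paste0("dec", b)]]$dskip
    }
    d <- relu_backward(cc$zb, d)
    bw <- conv3x3_backward(cc$aa, cc$shape, params[[paste0("enc", b, "b")]]$W, d)
    grads[[paste0("enc", b, "b")]] <- list(W = bw$dW, b = bw$db)
    d <- relu_backward(cc$za, bw$dX)
    bw <- conv3x3_backward(cc$xin, cc$shape, params[[paste0("enc", b, "a")]]$W, d)
    grads[[paste0("enc", b, "a")]] <- list(W = bw$dW, b = bw$db)
    d_from_above <- bw$dX
  }
  grads
}

classifier_forward <- function(params, X, shape, keep_cache = FALSE) {
  caches <- list()
  cur <- X; sh <- shape
  for (b in 1:4) {
    z <- conv3x3_forward(cur, sh, params[[paste0("conv", b)]]$W,
                         params[[paste0("conv", b)]]$b)
    a <- relu_forward(z)
    pl <- maxpool_forward(a, sh)
    caches[[paste0("blk", b)]] <- list(xin = cur, z = z, a = a, pool = pl, shape = sh)
    cur <- pl$out
    sh <- pl$shape
  }
  N <- sh[3]
  npix <- sh[1] * sh[2]
  grp <- rep(seq_len(N), each = npix)
  gap <- rowsum(cur, grp) / npix
  z1 <- gap %*% params$fc1$W + matrix(rep(params$fc1$b, each = N), N)
  a1 <- relu_forward(z1)
  z2 <- a1 %*% params$fc2$W + matrix(rep(params$fc2$b, each = N), N)
  list(logits = z2, gap = gap, z1 = z1, a1 = a1, final_shape = sh,
       last = cur, caches = if (keep_cache) caches else NULL)
}

classifier_backward <- function(params, fwd, dLogits) {
  grads <- list()
  grads$fc2 <- list(W = crossprod(fwd$a1, dLogits), b = colSums(dLogits))
  d1 <- relu_backward(fwd$z1, dLogits %*% t(params$fc2$W))
  grads$fc1 <- list(W = crossprod(fwd$gap, d1), b = colSums(d1))
  dgap <- d1 %*% t(params$fc1$W)
  sh <- fwd$final_shape
  npix <- sh[1] * sh[2]
  d <- dgap[rep(seq_len(sh[3]), each = npix), , drop = FALSE] / npix
  for (b in 4:1) {
    cc <- fwd$caches[[paste0("blk", b)]]
    d <- maxpool_backward(cc$pool, d, nrow(cc$a))
    d <- relu_backward(cc$z, d)
    bw <- conv3x3_backward(cc$xin, cc$shape, params[[paste0("conv", b)]]$W, d)
    grads[[paste0("conv", b)]] <- list(W = bw$dW, b = bw$db)
    d <- bw$dX
  }
  grads
}

# stack a list of (H, W, C) arrays into the engine's (H*W*N, C) layout
stack_inputs <- function(xs) {
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]
  C <- if (length(dim(xs[[1]])) == 3) dim(xs[[1]])[3] else 1L
  N <- length(xs)
  X <- matrix(0, H * W * N, C)
  for (n in seq_len(N)) {
    rows <- ((n - 1) * H * W + 1):(n * H * W)
    if (C == 1) X[rows, 1] <- as.vector(xs[[n]])
    else for (ch in seq_len(C)) X[rows, ch] <- as.vector(xs[[n]][, , ch])
  }
  list(X = X, shape = c(H, W, N))
}

# --- losses ----------------------------------------------------------------

loss_grad <- function(spec, logits, y) {
  n <- nrow(logits)
  switch(spec$loss,
    binary_cross_entropy = {
      p <- sigmoid(logits[, 1])
      eps <- 1e-7
      loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
      list(loss = loss, dLogits = matrix((p - y) / n, ncol = 1))
    },
    dice = {
      p <- sigmoid(logits[, 1])
      s <- 1
      inter <- sum(p * y)
      u <- sum(p) + sum(y) + s
      d <- (2 * inter + s) / u
      dp <- -(2 * y / u - (2 * inter + s) / u^2)
      list(loss = 1 - d, dLogits = matrix(dp * p * (1 - p), ncol = 1))
    },
    sparse_categorical_cross_entropy = {
      p <- softmax_rows(logits)
      eps <- 1e-9
      idx <- cbind(seq_len(n), y + 1L)
      loss <- -mean(log(p[idx] + eps))
      one <- matrix(0, n, ncol(logits))
      one[idx] <- 1
      list(loss = loss, dLogits = (p - one) / n)
    })
}

model_loss <- function(model, xs, ys, batch = 16L) {
  tot <- 0; wt <- 0
  for (start in seq(1, length(xs), by = batch)) {
    ii <- start:min(start + batch - 1, length(xs))
    st <- stack_inputs(xs[ii])
    fwd <- if (model$spec$family == "classifier_cnn")
      classifier_forward(model$params, st$X, st$shape)
    else unet_forward(model$params, st$X, st$shape, model$spec)
    y <- if (model$spec$family == "classifier_cnn") unlist(ys[ii])
         else unlist(lapply(ys[ii], as.vector))
    lg <- loss_grad(model$spec, fwd$logits, y)
    tot <- tot + lg$loss * length(ii)
    wt <- wt + length(ii)
  }
  tot / wt
}

#' Train a model
#'
#' Adam at the spec's learning rate and batch size, with seeded shuffling.
#' After every epoch the validation loss is recorded; the returned model
#' carries the weights of the epoch with the lowest validation loss (ties
#' break to the earliest epoch).
#'
#' @param model an untrained or pretrained `fg_model`.
#' @param train_x,train_y training inputs (list of H x W x C arrays) and
#'   targets (numeric 0/1 vector for classifiers; list of H x W integer
#'   masks for segmentation — binary for dice, 0..K-1 for K-class).
#' @param val_x,val_y validation set in the same form.
#' @param lr,epochs optional overrides of the spec values.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-epoch weights) and `history`
#'   (`train_loss`, `val_loss`, `selected_epoch`, 0-based).
#' @export
train_model <- function(model, train_x, train_y, val_x, val_y,
                        lr = NULL, epochs = NULL, verbose = FALSE) {
  spec <- model$spec
  stopifnot(length(train_x) > 0, length(val_x) > 0)
  lr <- if (is.null(lr)) spec$lr else lr
  epochs <- if (is.null(epochs)) spec$epochs else epochs
  params <- model$params
  state <- adam_new(params)
  is_cls <- spec$family == "classifier_cnn"
  tr_loss <- numeric(0); va_loss <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = -1L)
  if (epochs >= 1) with_seed(spec$seed + 1L, {
    n <- length(train_x)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, n, by = spec$batch_size)) {
        ii <- ord[start:min(start + spec$batch_size - 1, n)]
        st <- stack_inputs(train_x[ii])
        y <- if (is_cls) unlist(train_y[ii])
             else unlist(lapply(train_y[ii], as.vector))
        fwd <- if (is_cls) classifier_forward(params, st$X, st$shape, keep_cache = TRUE)
               else unet_forward(params, st$X, st$shape, spec, keep_cache = TRUE)
        lg <- loss_grad(spec, fwd$logits, y)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", ep, "; lower the learning rate")
        grads <- if (is_cls) classifier_backward(params, fwd, lg$dLogits)
                 else unet_backward(params, fwd, lg$dLogits, spec)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(ii)
        ep_n <- ep_n + length(ii)
      }
      m2 <- structure(list(spec = spec, params = params), class = "fg_model")
      vl <- model_loss(m2, val_x, val_y)
      tr_loss <- c(tr_loss, ep_loss / ep_n)
      va_loss <- c(va_loss, vl)
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep - 1L)
      if (verbose)
        message(sprintf("epoch %d/%d  train %.4f  val %.4f", ep, epochs,
                        ep_loss / ep_n, vl))
    }
  })
  out <- structure(list(spec = spec,
                        params = if (best$epoch >= 0) best$params else params),
                   class = "fg_model")
  list(model = out,
       history = list(train_loss = tr_loss, val_loss = va_loss,
                      selected_epoch = if (length(va_loss))
                        which.min(va_loss) - 1L else -1L))
}

#' Fine-tune a pretrained model
#'
#' Same loop as [train_model()] with overridden learning rate and epochs;
#' the reference transfer-learning settings are 2e-5 / 20 epochs for
#' classifiers and 0.01 / 10 epochs for segmentation. `epochs = 0` returns
#' the model unchanged.
#' @inheritParams train_model
#' @param lr,epochs fine-tuning overrides; `NULL` picks the reference
#'   default for the model family.
#' @return as [train_model()].
#' @export
finetune_model <- function(model, train_x, train_y, val_x, val_y,
                           lr = NULL, epochs = NULL, verbose = FALSE) {
  is_cls <- model$spec$family == "classifier_cnn"
  if (is.null(lr)) lr <- if (is_cls) 2e-5 else 0.01
  if (is.null(epochs)) epochs <- if (is_cls) 20L else 10L
  train_model(model, train_x, train_y, val_x, val_y, lr = lr,
              epochs = epochs, verbose = verbose)
}

#' Predict with a trained model
#'
#' @param model an `fg_model`.
#' @param xs list of H x W x C input arrays.
#' @param batch internal batch size.
#' @return classifier: numeric vector of probabilities. Binary U-Net: list
#'   of H x W probability matrices. Multi-class U-Net: list of H x W x K
#'   probability arrays.
#' @export
predict_model <- function(model, xs, batch = 16L) {
  spec <- model$spec
  is_cls <- spec$family == "classifier_cnn"
  out <- vector(if (is_cls) "numeric" else "list", length(xs))
  for (start in seq(1, length(xs), by = batch)) {
    ii <- start:min(start + batch - 1, length(xs))
    st <- stack_inputs(xs[ii])
    if (is_cls) {
      fwd <- classifier_forward(model$params, st$X, st$shape)
      out[ii] <- sigmoid(fwd$logits[, 1])
    } else {
      fwd <- unet_forward(model$params, st$X, st$shape, spec)
      H <- st$shape[1]; W <- st$shape[2]
      k <- ncol(fwd$logits)
      probs <- if (k == 1) sigmoid(fwd$logits) else softmax_rows(fwd$logits)
      for (j in seq_along(ii)) {
        rows <- ((j - 1) * H * W + 1):(j * H * W)
        out[[ii[j]]] <- if (k == 1) matrix(probs[rows, 1], H, W)
                        else array(probs[rows, ], c(H, W, k))
      }
    }
  }
  out
}

#' Select the best cross-validation fold
#'
#' `max_kappa` picks the fold with the highest Cohen kappa (the binary-task
#' rule); `max_dice_sum` the highest background + healthy + cancer Dice sum
#' (the segmentation rule). Ties break to the lowest fold index.
#' @param per_fold_results list of `MetricsReport` (see [evaluate_task()]).
#' @param criterion `max_kappa` or `max_dice_sum`.
#' @return 0-based fold index.
#' @export
select_fold <- function(per_fold_results, criterion = c("max_kappa", "max_dice_sum")) {
  criterion <- match.arg(criterion)
  stopifnot(length(per_fold_results) >= 1)
  score <- vapply(per_fold_results, function(r) {
    if (criterion == "max_kappa") r$kappa else sum(unlist(r$dice_per_class))
  }, numeric(1))
  which.max(score) - 1L
}

# --- augmentation ----------------------------------------------------------

#' Specify the augmentation schedule
#'
#' Defaults reproduce the published schedule: 1000 flips (500 horizontal +
#' 500 vertical), 1500 rotations (500 each of 90/180/270 degrees), 500
#' additive Gaussian noise draws with variance ~ Uniform(0, 0.5) on the
#' z-normalized scale, and 500 Gaussian blurs with sigma ~ Uniform(0, 5)
#' followed by the same noise — 3500 augmented crops in total. Segmentation
#' masks follow the geometric transforms but are never noised or blurred.
#' @param n_flip,n_rot,n_noise,n_blur_noise augmentation counts.
#' @param noise_variance_range,blur_sigma_range sampling intervals.
#' @param seed RNG seed.
#' @return an `AugmentationSpec`.
#' @export
augmentation_spec <- function(n_flip = 1000L, n_rot = 1500L, n_noise = 500L,
                              n_blur_noise = 500L,
                              noise_variance_range = c(0, 0.5),
                              blur_sigma_range = c(0, 5), seed = 1L) {
  stopifnot(n_flip >= 0, n_rot >= 0, n_noise >= 0, n_blur_noise >= 0,
            noise_variance_range[1] >= 0, blur_sigma_range[1] >= 0)
  structure(list(n_flip = as.integer(n_flip), n_rot = as.integer(n_rot),
                 n_noise = as.integer(n_noise),
                 n_blur_noise = as.integer(n_blur_noise),
                 noise_variance_range = noise_variance_range,
                 blur_sigma_range = blur_sigma_range, seed = as.integer(seed)),
            class = "AugmentationSpec")
}

rot90cw <- function(m, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

flip_h <- function(m) m[, ncol(m):1, drop = FALSE]
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]

#' Generate augmented crops
#'
#' Source crops are drawn uniformly with replacement; exactly
#' `n_flip + n_rot + n_noise + n_blur_noise` new crops are produced.
#' Geometric transforms apply to both channels and any mask; noise and blur
#' apply to the intensity channels only.
#'
#' @param crops list of records, each a list with matrices `draq5`, `eosin`
#'   (z-normalized), optionally `mask`, plus any label fields (carried
#'   through).
#' @param spec an [augmentation_spec()].
#' @return list of augmented records (only the new crops).
#' @export
augment_crops <- function(crops, spec = augmentation_spec()) {
  stopifnot(length(crops) > 0)
  n_total <- spec$n_flip + spec$n_rot + spec$n_noise + spec$n_blur_noise
  kinds <- c(rep("flip_h", ceiling(spec$n_flip / 2)),
             rep("flip_v", spec$n_flip - ceiling(spec$n_flip / 2)),
             rep("rot90", ceiling(spec$n_rot / 3)),
             rep("rot180", ceiling((spec$n_rot * 2) / 3) - ceiling(spec$n_rot / 3)),
             rep("rot270", spec$n_rot - ceiling((spec$n_rot * 2) / 3)),
             rep("noise", spec$n_noise),
             rep("blur_noise", spec$n_blur_noise))
  with_seed(spec$seed, {
    out <- vector("list", n_total)
    src <- sample.int(length(crops), n_total, replace = TRUE)
    for (i in seq_len(n_total)) {
      rec <- crops[[src[i]]]
      kind <- kinds[i]
      geom <- switch(kind,
        flip_h = flip_h, flip_v = flip_v,
        rot90 = function(m) rot90cw(m, 1L),
        rot180 = function(m) rot90cw(m, 2L),
        rot270 = function(m) rot90cw(m, 3L),
        NULL)
      if (!is.null(geom)) {
        rec$draq5 <- geom(rec$draq5)
        rec$eosin <- geom(rec$eosin)
        if (!is.null(rec$mask)) rec$mask <- geom(rec$mask)
      } else {
        if (kind == "blur_noise") {
          sg <- runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
          rec$draq5 <- gauss_blur(rec$draq5, sg)
          rec$eosin <- gauss_blur(rec$eosin, sg)
        }
        v <- runif(1, spec$noise_variance_range[1], spec$noise_variance_range[2])
        if (v > 0) {
          rec$draq5 <- rec$draq5 + matrix(rnorm(length(rec$draq5), 0, sqrt(v)),
                                          nrow(rec$draq5))
          rec$eosin <- rec$eosin + matrix(rnorm(length(rec$eosin), 0, sqrt(v)),
                                          nrow(rec$eosin))
        }
      }
      rec$augmented <- kind
      out[[i]] <- rec
    }
    out
  })
}
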