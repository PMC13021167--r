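# Minimal seeded neural-network engine for the package's compact models.
#
# Activations are stored as matrices X of shape (H*W*N, C): spatial index
# (row-major within an image, h fastest) times batch, by channel. All heavy
# lifting is row gathers plus BLAS GEMMs (im2col by 3x3 offset slices), so
# desk-scale U-Nets train in minutes on one CPU. Everything is deterministic
# under the model seed.

.idx_cache <- new.env(parent = emptyenv())

# single-image gather index for a (dy, dx) shift with zero padding:
# value 0 marks out-of-bounds (mapped to a zero row by callers)
shift_idx0 <- function(H, W, dy, dx) {
  key <- paste("s", H, W, dy, dx, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  sh <- (1:H) + dy
  sw <- (1:W) + dx
  ih <- ifelse(sh >= 1 & sh <= H, sh, NA)
  iw <- ifelse(sw >= 1 & sw <= W, sw, NA)
  idx <- outer(ih, (iw - 1) * H, `+`)
  idx[is.na(idx)] <- 0L
  out <- as.integer(idx)
  .idx_cache[[key]] <- out
  out
}

# expand a single-image index (0 = pad) to a batch gather index; pad rows
# point at the appended zero row npix*N + 1
batch_idx <- function(idx0, H, W, N) {
  npix <- H * W
  full <- as.vector(outer(idx0, (0:(N - 1)) * npix, `+`))
  full[rep(idx0 == 0L, N)] <- npix * N + 1L
  full
}

conv3x3_forward <- function(X, shape, Warr, b) {
  H <- shape[1]; W <- shape[2]; N <- shape[3]
  Cin <- dim(Warr)[3]; Cout <- dim(Warr)[4]
  Xp <- rbind(X, 0)
  out <- matrix(rep(b, each = nrow(X)), nrow(X), Cout)
  for (kx in 1:3) for (ky in 1:3) {
    idx <- batch_idx(shift_idx0(H, W, ky - 2L, kx - 2L), H, W, N)
    Wk <- matrix(Warr[ky, kx, , ], Cin, Cout)
    out <- out + Xp[idx, , drop = FALSE] %*% Wk
  }
  out
}

conv3x3_backward <- function(X, shape, Warr, dOut) {
  H <- shape[1]; W <- shape[2]; N <- shape[3]
  Cin <- dim(Warr)[3]; Cout <- dim(Warr)[4]
  Xp <- rbind(X, 0)
  dW <- array(0, dim(Warr))
  dX <- matrix(0, nrow(X), Cin)
  for (kx in 1:3) for (ky in 1:3) {
    idx <- batch_idx(shift_idx0(H, W, ky - 2L, kx - 2L), H, W, N)
    Wk <- matrix(Warr[ky, kx, , ], Cin, Cout)
    dW[ky, kx, , ] <- crossprod(Xp[idx, , drop = FALSE], dOut)
    grad <- dOut %*% t(Wk)
    valid <- idx <= nrow(X)
    tgt <- idx[valid]
    dX[tgt, ] <- dX[tgt, ] + grad[valid, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = colSums(dOut))
}

pool_idx <- function(H, W) {
  key <- paste("p", H, W, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ho <- 1:Ho; wo <- 1:Wo
  at <- function(dh, dw) as.integer(outer(2L * ho - 1L + dh, (2L * wo - 2L + dw) * H, `+`))
  out <- list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L))
  .idx_cache[[key]] <- out
  out
}

maxpool_forward <- function(X, shape) {
  H <- shape[1]; W <- shape[2]; N <- shape[3]
  i0 <- pool_idx(H, W)
  idx <- lapply(i0, function(k) as.vector(outer(k, (0:(N - 1)) * H * W, `+`)))
  cand <- lapply(idx, function(i) X[i, , drop = FALSE])
  out <- cand[[1]]
  win <- matrix(1L, nrow(out), ncol(out))
  for (k in 2:4) {
    better <- cand[[k]] > out
    out[better] <- cand[[k]][better]
    win[better] <- k
  }
  list(out = out, win = win, idx = idx,
       shape = c(H %/% 2L, W %/% 2L, N))
}

maxpool_backward <- function(pool, dOut, in_rows) {
  dX <- matrix(0, in_rows, ncol(dOut))
  for (k in 1:4) {
    g <- dOut * (pool$win == k)
    dX[pool$idx[[k]], ] <- dX[pool$idx[[k]], ] + g
  }
  dX
}

upsample_idx <- function(H, W) {
  key <- paste("u", H, W, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  ho <- 1:(2L * H); wo <- 1:(2L * W)
  src <- as.integer(outer((ho + 1L) %/% 2L, (((wo + 1L) %/% 2L) - 1L) * H, `+`))
  .idx_cache[[key]] <- src
  src
}

upsample_forward <- function(X, shape) {
  H <- shape[1]; W <- shape[2]; N <- shape[3]
  i0 <- upsample_idx(H, W)
  idx <- as.vector(outer(i0, (0:(N - 1)) * H * W, `+`))
  list(out = X[idx, , drop = FALSE], idx = idx, shape = c(2L * H, 2L * W, N))
}

upsample_backward <- function(up, dOut, in_rows) {
  # every input row feeds exactly 4 output rows, so groups are 1..in_rows
  rowsum(dOut, group = up$idx, reorder = TRUE)
}

relu_forward <- function(X) pmax(X, 0)
relu_backward <- function(X, dOut) dOut * (X > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- parameter initialization ---------------------------------------------

init_array <- function(dims, fan_in, fan_out, init) {
  n <- prod(dims)
  v <- if (init == "he_normal") rnorm(n, 0, sqrt(2 / fan_in))
       else runif(n, -sqrt(6 / (fan_in + fan_out)), sqrt(6 / (fan_in + fan_out)))
  array(v, dims)
}

conv_param <- function(cin, cout, init) {
  list(W = init_array(c(3, 3, cin, cout), 9 * cin, 9 * cout, init),
       b = numeric(cout))
}

dense_param <- function(cin, cout, init) {
  list(W = init_array(c(cin, cout), cin, cout, init), b = numeric(cout))
}

# --- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  zero <- function(p) lapply(p, function(a) a * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) for (k in names(params[[nm]])) {
    g <- grads[[nm]][[k]]
    if (is.null(g)) next
    state$m[[nm]][[k]] <- beta1 * state$m[[nm]][[k]] + (1 - beta1) * g
    state$v[[nm]][[k]] <- beta2 * state$v[[nm]][[k]] + (1 - beta2) * g^2
    params[[nm]][[k]] <- params[[nm]][[k]] -
      lr * (state$m[[nm]][[k]] / bc1) / (sqrt(state$v[[nm]][[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
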