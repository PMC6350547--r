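# Tensor layer primitives with explicit forward caches and backward
# passes. Feature maps are arrays with dim (H, W, N, C): with samples
# before channels, an (H, W, N, C) block reshapes to the (H*W*N) x C
# matrix that im2col and batch norm need without any transposition, so
# the inner products run as plain BLAS matmuls on contiguous memory.
# Convolution weights are stored as a (kh*kw*Cin) x Cout matrix with a
# "dims" attribute giving (kh, kw, Cin, Cout).

conv_out_size <- function(n, k, stride, pad, dilation) {
  eff <- (k - 1L) * dilation + 1L
  (n + 2L * pad - eff) %/% stride + 1L
}

im2col <- function(x, kh, kw, stride, pad, dilation) {
  d <- dim(x)
  list(cols = .im2col_cpp(x, as.integer(d), kh, kw, stride, pad, dilation),
       oh = conv_out_size(d[1], kh, stride, pad, dilation),
       ow = conv_out_size(d[2], kw, stride, pad, dilation),
       in_dim = d,
       kh = kh, kw = kw, stride = stride, pad = pad, dilation = dilation)
}

col2im <- function(dcols, info) {
  dx <- .col2im_cpp(dcols, as.integer(info$in_dim), info$kh, info$kw,
                    info$stride, info$pad, info$dilation)
  dim(dx) <- info$in_dim
  dx
}

# W: (kh*kw*Cin) x Cout matrix with attr "dims" = c(kh, kw, Cin, Cout)
conv_forward <- function(x, W, b, stride = 1L, pad = 1L, dilation = 1L) {
  dm <- attr(W, "dims")
  ic <- im2col(x, dm[1], dm[2], stride, pad, dilation)
  y_mat <- .colaffine_cpp(ic$cols %*% W, dm[4], rep(1, dm[4]), b)
  dim(y_mat) <- c(ic$oh, ic$ow, dim(x)[3], dm[4])
  list(y = y_mat, cache = ic)
}

conv_backward <- function(dy, cache, W, need_dx = TRUE) {
  dm <- attr(W, "dims")
  dy_mat <- dy
  dim(dy_mat) <- c(cache$oh * cache$ow * cache$in_dim[3], dm[4])
  dW <- crossprod(cache$cols, dy_mat)
  attr(dW, "dims") <- dm
  db <- colSums(dy_mat)
  dx <- if (need_dx) col2im(tcrossprod(dy_mat, W), cache) else NULL
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization per channel over (H, W, N). In training mode batch
# statistics are used and running statistics updated; in eval mode the
# running statistics are used.
bn_forward <- function(x, gamma, beta, run_mean, run_var,
                       training = TRUE, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); C <- d[4]; m <- d[1] * d[2] * d[3]
  xr <- x
  dim(xr) <- c(m, C)
  if (training) {
    mu <- colMeans(xr)
    v <- pmax(colMeans(xr * xr) - mu * mu, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- .colaffine_cpp(xr, C, inv_sd, -mu * inv_sd)
  dim(xhat) <- c(m, C)
  yr <- .colaffine_cpp(xhat, C, gamma, beta)
  dim(yr) <- d
  list(y = yr,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                    dims = d, training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy, cache) {
  d <- cache$dims; C <- d[4]; m <- d[1] * d[2] * d[3]
  dyr <- dy
  dim(dyr) <- c(m, C)
  dgamma <- colSums(dyr * cache$xhat)
  dbeta <- colSums(dyr)
  dxhat <- dyr * rep(cache$gamma, each = m)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxr <- (m * dxhat - rep(s1, each = m) -
              cache$xhat * rep(s2, each = m)) *
      rep(cache$inv_sd / m, each = m)
  } else {
    dxr <- dxhat * rep(cache$inv_sd, each = m)
  }
  dim(dxr) <- d
  list(dx = dxr, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

# 2x2 average pooling with stride 2 (spatial dims must be even)
avgpool_forward <- function(x) {
  d <- dim(x)
  assert_that(d[1] %% 2 == 0 && d[2] %% 2 == 0,
              "average pooling needs even spatial dimensions")
  i1 <- seq.int(1L, d[1], 2L); i2 <- seq.int(2L, d[1], 2L)
  j1 <- seq.int(1L, d[2], 2L); j2 <- seq.int(2L, d[2], 2L)
  y <- (x[i1, j1, , , drop = FALSE] + x[i2, j1, , , drop = FALSE] +
        x[i1, j2, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool_backward <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  g <- dy / 4
  i1 <- seq.int(1L, in_dim[1], 2L); i2 <- seq.int(2L, in_dim[1], 2L)
  j1 <- seq.int(1L, in_dim[2], 2L); j2 <- seq.int(2L, in_dim[2], 2L)
  dx[i1, j1, , ] <- g; dx[i2, j1, , ] <- g
  dx[i1, j2, , ] <- g; dx[i2, j2, , ] <- g
  dx
}

# global average pooling: (H, W, N, C) -> (C, N)
gap_forward <- function(x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1] * d[2], d[3] * d[4])
  y <- t(matrix(colMeans(xr), d[3], d[4]))   # (C, N)
  list(y = y, cache = d)
}

gap_backward <- function(dy, in_dim) {
  per <- t(dy) / (in_dim[1] * in_dim[2])     # (N, C)
  array(rep(as.numeric(per), each = in_dim[1] * in_dim[2]), in_dim)
}

# inverted dropout on a (C, N) feature matrix
dropout_forward <- function(f, rate, training, mask = NULL) {
  if (!training || rate <= 0) return(list(y = f, cache = NULL))
  if (is.null(mask)) {
    mask <- matrix(stats::rbinom(length(f), 1L, 1 - rate) / (1 - rate),
                   nrow(f), ncol(f))
  }
  list(y = f * mask, cache = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# fully connected: f (C, N), W (C, K), b (K) -> logits (K, N)
fc_forward <- function(f, W, b) {
  list(y = crossprod(W, f) + b, cache = f)
}

fc_backward <- function(dlogits, cache_f, W) {
  list(dW = tcrossprod(cache_f, dlogits),
       db = rowSums(dlogits),
       df = W %*% dlogits)
}

# column-wise softmax of logits (K, N)
softmax_cols <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# mean soft-target cross entropy; targets (K, N) sum to 1 per column
cross_entropy_soft <- function(probs, targets) {
  -mean(colSums(targets * log(pmax(probs, 1e-12))))
}

# gradient of mean cross entropy w.r.t. logits
cross_entropy_grad <- function(probs, targets) {
  (probs - targets) / ncol(probs)
}

# concatenate feature maps along the channel axis (dim 4)
concat_ch <- function(xs) {
  if (length(xs) == 1L) return(xs[[1]])
  d <- dim(xs[[1]])
  Cs <- vapply(xs, function(x) dim(x)[4], integer(1))
  # channel-last layout: concatenation is contiguous
  out <- unlist(xs, use.names = FALSE)
  dim(out) <- c(d[1], d[2], d[3], sum(Cs))
  out
}

# split a channel-gradient back into per-input pieces
split_ch <- function(dz, Cs) {
  d <- dim(dz)
  per <- d[1] * d[2] * d[3]
  out <- vector("list", length(Cs))
  off <- 0L
  for (i in seq_along(Cs)) {
    piece <- dz[per * off + seq_len(per * Cs[i])]
    dim(piece) <- c(d[1], d[2], d[3], Cs[i])
    out[[i]] <- piece
    off <- off + Cs[i]
  }
  out
}

# He fan-in initializer for a conv weight matrix
init_conv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  W <- matrix(stats::rnorm(kh * kw * cin * cout, 0, sd), kh * kw * cin, cout)
  attr(W, "dims") <- c(kh, kw, cin, cout)
  W
}
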