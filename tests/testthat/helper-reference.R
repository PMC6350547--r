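# Independent reference implementations used as oracles. These are
# deliberately naive (direct loops, no im2col, no shared code with the
# package internals) and only ever run on tiny inputs.

# direct-loop 2d convolution; x (H, W, N, C), W matrix (kh*kw*Cin) x Cout
# with attr dims, column order: kernel position slower than channel,
# position index k = (kj-1)*kh + ki with ki the row offset.
naive_conv <- function(x, W, b, stride = 1, pad = 1, dilation = 1) {
  dm <- attr(W, "dims")
  kh <- dm[1]; kw <- dm[2]; cin <- dm[3]; cout <- dm[4]
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]
  oh <- (H + 2 * pad - ((kh - 1) * dilation + 1)) %/% stride + 1
  ow <- (Wd + 2 * pad - ((kw - 1) * dilation + 1)) %/% stride + 1
  y <- array(0, c(oh, ow, N, cout))
  for (n in seq_len(N)) for (co in seq_len(cout)) {
    for (io in seq_len(oh)) for (jo in seq_len(ow)) {
      acc <- b[co]
      for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        ii <- (io - 1) * stride + (ki - 1) * dilation + 1 - pad
        jj <- (jo - 1) * stride + (kj - 1) * dilation + 1 - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
          k <- (kj - 1) * kh + (ki - 1)
          for (ci in seq_len(cin)) {
            acc <- acc + x[ii, jj, n, ci] * W[k * cin + ci, co]
          }
        }
      }
      y[io, jo, n, co] <- acc
    }
  }
  y
}

# training-mode batch norm with batch statistics (biased variance)
naive_bn <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- array(0, d)
  for (c in seq_len(d[4])) {
    v <- x[, , , c]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    y[, , , c] <- gamma[c] * (v - mu) / sqrt(va + eps) + beta[c]
  }
  y
}

naive_relu <- function(x) pmax(x, 0)

naive_avgpool <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1] / 2, d[2] / 2, d[3], d[4]))
  for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2)) {
    y[i, j, , ] <- (x[2 * i - 1, 2 * j - 1, , ] + x[2 * i, 2 * j - 1, , ] +
                    x[2 * i - 1, 2 * j, , ] + x[2 * i, 2 * j, , ]) / 4
  }
  y
}

naive_concat <- function(xs) {
  d <- dim(xs[[1]])
  Cs <- vapply(xs, function(x) dim(x)[4], integer(1))
  out <- array(0, c(d[1], d[2], d[3], sum(Cs)))
  off <- 0
  for (x in xs) {
    out[, , , off + seq_len(dim(x)[4])] <- x
    off <- off + dim(x)[4]
  }
  out
}

# standard (unweighted) dense layer and block: layer 0 transforms the
# block input, layer l >= 1 the plain concatenation of all previous
# layer outputs; each layer applies conv -> batch norm -> ReLU; the
# block output is the concatenation of the layer outputs
naive_dense_block <- function(x, layer_params) {
  outs <- list()
  for (l in seq_along(layer_params)) {
    pp <- layer_params[[l]]
    z <- if (l == 1) x else naive_concat(outs)
    y <- naive_conv(z, pp$conv$W, pp$conv$b, stride = 1, pad = 1)
    outs[[l]] <- naive_relu(naive_bn(y, pp$bn$gamma, pp$bn$beta))
  }
  naive_concat(outs)
}

# random parameter set for one dense layer with given input channels
random_layer_params <- function(in_ch, growth) {
  W <- matrix(rnorm(9 * in_ch * growth, 0, 0.3), 9 * in_ch, growth)
  attr(W, "dims") <- c(3L, 3L, in_ch, growth)
  list(bn = list(gamma = runif(growth, 0.5, 1.5),
                 beta = rnorm(growth, 0, 0.2)),
       conv = list(W = W, b = rnorm(growth, 0, 0.1)))
}

# Hill tail-index estimator on the top k order statistics of |x|
hill_tail_index <- function(x, k = 1000) {
  a <- sort(abs(x), decreasing = TRUE)
  1 / mean(log(a[seq_len(k)] / a[k + 1]))
}
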