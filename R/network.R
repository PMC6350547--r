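#' Network architecture configuration
#'
#' Describes the modified DenseNet: a stem convolution, a sequence of
#' dense blocks whose skip connections carry trainable scalar weights,
#' transition stages that downsample either by dilated convolution
#' (default) or 2x2 average pooling, and a 4-way classification head.
#'
#' @param input_size Input image side length (square grayscale input).
#' @param n_classes Number of output classes (4 for this application).
#' @param stem_channels Channels produced by the stem convolution.
#' @param block_layers Integer vector, one entry per dense block, giving
#'   the number of layers in each block.
#' @param growth_rate Channels added by each dense layer.
#' @param downsample `"dilated_conv"` (3x3, dilation 2, stride 2) or
#'   `"pool"` (2x2 average pooling); both halve the spatial size.
#' @param compression Channel compression factor of the 1x1 transition
#'   convolution.
#' @param dropout_rate Dropout rate on the classifier head, in [0, 1).
#' @param use_batch_norm Whether layers include batch normalization.
#' @param arch Optional preset: `"small"` (the desk-scale default:
#'   2 blocks x 3 layers, growth 8, input 32) or `"clinical"`
#'   (DenseNet121-like: blocks 6/12/24/16, growth 32, input 255).
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_size = 32L, n_classes = 4L,
                           stem_channels = 8L,
                           block_layers = c(3L, 3L),
                           growth_rate = 8L,
                           downsample = c("dilated_conv", "pool"),
                           compression = 0.5,
                           dropout_rate = 0.2,
                           use_batch_norm = TRUE,
                           arch = NULL) {
  downsample <- match.arg(downsample)
  if (!is.null(arch)) {
    if (arch == "clinical") {
      input_size <- 255L; stem_channels <- 64L
      block_layers <- c(6L, 12L, 24L, 16L); growth_rate <- 32L
    } else if (arch != "small") {
      stop("unknown arch preset: ", arch, call. = FALSE)
    }
  }
  assert_that(n_classes == 4L, "this application is fixed at 4 classes")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  n_down <- length(block_layers) - 1L
  assert_that(input_size %/% (2^n_down) >= 4,
              "input_size too small for the number of downsampling stages")
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 stem_channels = as.integer(stem_channels),
                 block_layers = as.integer(block_layers),
                 growth_rate = as.integer(growth_rate),
                 downsample = downsample,
                 compression = compression,
                 dropout_rate = dropout_rate,
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "network_config")
}

#' Build a weighted-DenseNet model
#'
#' Constructs the model with seeded He-style fan-in initialization of all
#' convolutions and every skip-connection weight set exactly to 1.0, so
#' the freshly built network computes the same function as a standard
#' (unweighted) dense architecture with the same parameters.
#'
#' Within a dense block, layer 0 transforms the block input; layer l >= 1
#' receives the outputs of layers 0..l-1, each feature map scaled by its
#' own trainable scalar k_{l,i} before concatenation, then applies the
#' transform F_l: a 3x3 convolution producing `growth_rate` channels,
#' batch norm, and ReLU activation. The convolution comes first so that
#' the channels are mixed before normalization: batch norm is invariant
#' to a per-channel scale, so a skip weight feeding straight into it
#' would receive a zero gradient and could never be learned. A block's
#' output is the concatenation of all of its layer outputs, so layer l
#' owns exactly l skip weights and a block of L layers owns L(L-1)/2 of
#' them.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `spect_net`: a list with `config`, a named
#'   `params` list (all trainable tensors, including per-layer `skip`
#'   weight vectors), and `state` (batch-norm running statistics).
#' @export
build_network <- function(config = network_config(), seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  params <- list()
  state <- list()
  g <- config$growth_rate
  add_bn <- function(name, ch) {
    params[[paste0(name, ".gamma")]] <<- rep(1, ch)
    params[[paste0(name, ".beta")]] <<- rep(0, ch)
    state[[name]] <<- list(mean = rep(0, ch), var = rep(1, ch))
  }

  params[["stem.conv.W"]] <- init_conv(3L, 3L, 1L, config$stem_channels)
  params[["stem.conv.b"]] <- rep(0, config$stem_channels)
  if (config$use_batch_norm) add_bn("stem.bn", config$stem_channels)
  ch <- config$stem_channels

  n_blocks <- length(config$block_layers)
  for (b in seq_len(n_blocks)) {
    L <- config$block_layers[b]
    for (l in seq_len(L) - 1L) {
      in_ch <- if (l == 0L) ch else l * g
      nm <- sprintf("block%d.layer%d", b, l)
      params[[paste0(nm, ".conv.W")]] <- init_conv(3L, 3L, in_ch, g)
      params[[paste0(nm, ".conv.b")]] <- rep(0, g)
      if (config$use_batch_norm) add_bn(paste0(nm, ".bn"), g)
      if (l >= 1L) params[[paste0(nm, ".skip")]] <- rep(1, l)
    }
    ch <- L * g
    if (b < n_blocks) {
      nm <- sprintf("trans%d", b)
      out_ch <- max(1L, as.integer(floor(config$compression * ch)))
      params[[paste0(nm, ".conv.W")]] <- init_conv(1L, 1L, ch, out_ch)
      params[[paste0(nm, ".conv.b")]] <- rep(0, out_ch)
      if (config$use_batch_norm) add_bn(paste0(nm, ".bn"), out_ch)
      if (config$downsample == "dilated_conv") {
        params[[paste0(nm, ".down.W")]] <- init_conv(3L, 3L, out_ch, out_ch)
        params[[paste0(nm, ".down.b")]] <- rep(0, out_ch)
      }
      ch <- out_ch
    }
  }
  params[["head.fc.W"]] <- matrix(stats::rnorm(ch * config$n_classes, 0,
                                               sqrt(2 / ch)),
                                  ch, config$n_classes)
  params[["head.fc.b"]] <- rep(0, config$n_classes)

  structure(list(config = config, params = params, state = state),
            class = "spect_net")
}

#' @export
print.spect_net <- function(x, ...) {
  cat(sprintf("<spect_net: input %dx%d, blocks [%s] x growth %d, %s downsampling, %d parameters>\n",
              x$config$input_size, x$config$input_size,
              paste(x$config$block_layers, collapse = ","),
              x$config$growth_rate, x$config$downsample,
              length(get_flat(x$params))))
  invisible(x)
}

# flatten all trainable parameters into one numeric vector / write back
get_flat <- function(params) unlist(params, use.names = FALSE)

set_flat <- function(params, vec) {
  off <- 0L
  for (nm in names(params)) {
    n <- length(params[[nm]])
    params[[nm]][] <- vec[off + seq_len(n)]
    off <- off + n
  }
  params
}

#' Count of skip-connection weights in a model
#'
#' A block with L layers carries L(L-1)/2 trainable skip scalars.
#'
#' @param model A `spect_net`.
#' @return Named integer vector, one entry per dense block.
#' @export
count_skip_weights <- function(model) {
  nb <- length(model$config$block_layers)
  out <- integer(nb)
  for (b in seq_len(nb)) {
    nms <- grep(sprintf("^block%d\\.layer\\d+\\.skip$", b),
                names(model$params), value = TRUE)
    out[b] <- sum(vapply(model$params[nms], length, integer(1)))
  }
  names(out) <- paste0("block", seq_len(nb))
  out
}

# --- forward pass -----------------------------------------------------

# One weighted dense layer: scale each incoming feature map by its skip
# weight, concatenate, then the transform F_l = 3x3 conv -> BN -> ReLU.
# The conv precedes normalization so the skip scale reaches the loss
# (BN is invariant to a per-channel scale). `skip` is NULL for layer 0.
wdl_forward <- function(features, skip, bn_gamma, bn_beta, bn_state,
                        conv_W, conv_b, training, use_bn) {
  if (!is.null(skip)) {
    assert_that(length(skip) == length(features),
                "skip weight count must match the number of feature maps")
    scaled <- mapply(function(x, k) x * k, features, skip, SIMPLIFY = FALSE)
  } else {
    assert_that(length(features) == 1L, "layer 0 takes exactly one input")
    scaled <- features
  }
  z <- concat_ch(scaled)
  cv <- conv_forward(z, conv_W, conv_b, stride = 1L, pad = 1L)
  if (use_bn) {
    bn <- bn_forward(cv$y, bn_gamma, bn_beta, bn_state$mean, bn_state$var,
                     training = training)
    a <- bn$y
  } else {
    bn <- NULL
    a <- cv$y
  }
  r <- relu_forward(a)
  list(y = r$y,
       cache = list(bn = bn, relu = r$cache, conv = cv$cache,
                    features = features, skip = skip,
                    Cs = vapply(features, function(x) dim(x)[4], integer(1))),
       bn_state = if (use_bn) list(mean = bn$run_mean, var = bn$run_var)
                  else bn_state)
}

wdl_backward <- function(dy, cache, conv_W, use_bn) {
  da <- relu_backward(dy, cache$relu)
  if (use_bn) {
    bb <- bn_backward(da, cache$bn$cache)
    dcv <- bb$dx
    dgamma <- bb$dgamma; dbeta <- bb$dbeta
  } else {
    dcv <- da
    dgamma <- NULL; dbeta <- NULL
  }
  cb <- conv_backward(dcv, cache$conv, conv_W)
  dparts <- split_ch(cb$dx, cache$Cs)
  if (!is.null(cache$skip)) {
    dskip <- numeric(length(cache$skip))
    dfeat <- vector("list", length(dparts))
    for (i in seq_along(dparts)) {
      dskip[i] <- sum(dparts[[i]] * cache$features[[i]])
      dfeat[[i]] <- dparts[[i]] * cache$skip[i]
    }
  } else {
    dskip <- NULL
    dfeat <- dparts
  }
  list(dfeat = dfeat, dskip = dskip, dW = cb$dW, db = cb$db,
       dgamma = dgamma, dbeta = dbeta)
}

#' Apply one weighted dense layer to a list of feature maps
#'
#' Functional form of the block's basic operation: each incoming feature
#' map `x_i` is multiplied by its scalar skip weight `k_i`, the scaled
#' maps are concatenated along the channel axis, and the transform F_l
#' (3x3 same convolution, batch norm with batch statistics, ReLU) is
#' applied. With all weights 1 this reduces to the standard dense layer.
#'
#' @param features List of arrays of dim (H, W, N, C_i), all spatially
#'   congruent.
#' @param weights Numeric vector of skip weights, one per feature map.
#' @param params List with elements `conv` (list `W`, `b` as produced by
#'   the builder) and `bn` (list `gamma`, `beta` over the output
#'   channels); `bn` may be omitted to skip normalization.
#' @return The output feature map, an array (H, W, N, growth).
#' @export
weighted_dense_layer <- function(features, weights, params) {
  assert_that(length(weights) == length(features),
              "weight-count mismatch: need one skip weight per feature map")
  use_bn <- !is.null(params$bn)
  scaled <- mapply(function(x, k) x * k, features, weights, SIMPLIFY = FALSE)
  z <- concat_ch(scaled)
  y <- conv_forward(z, params$conv$W, params$conv$b, stride = 1L, pad = 1L)$y
  if (use_bn) {
    g <- length(params$bn$gamma)
    st <- list(mean = rep(0, g), var = rep(1, g))
    y <- bn_forward(y, params$bn$gamma, params$bn$beta, st$mean, st$var,
                    training = TRUE)$y
  }
  relu_forward(y)$y
}

# Full network forward pass.
#   x: array (H, W, 1, N)
#   training: batch-norm batch statistics + dropout active
#   update_state: commit updated BN running statistics (returned model)
#   dropout_mask: optional fixed mask for deterministic re-evaluation
# Returns list(probs (N x K), logits (K, N), cache, state)
nn_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                       dropout_mask = NULL) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  d <- dim(x)
  assert_that(d[1] == cfg$input_size && d[2] == cfg$input_size,
              sprintf("input size %dx%d does not match configured %d",
                      d[1], d[2], cfg$input_size))
  use_bn <- cfg$use_batch_norm
  cache <- list()

  cv <- conv_forward(x, p[["stem.conv.W"]], p[["stem.conv.b"]],
                     stride = 1L, pad = 1L)
  cur <- cv$y
  if (keep_cache) cache$stem <- cv$cache
  if (use_bn) {
    bn <- bn_forward(cur, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
                     st[["stem.bn"]]$mean, st[["stem.bn"]]$var,
                     training = training)
    if (training) st[["stem.bn"]] <- list(mean = bn$run_mean,
                                          var = bn$run_var)
    cur <- bn$y
    if (keep_cache) cache$stem_bn <- bn$cache
  }
  r <- relu_forward(cur)
  cur <- r$y
  if (keep_cache) cache$stem_relu <- r$cache

  n_blocks <- length(cfg$block_layers)
  for (b in seq_len(n_blocks)) {
    L <- cfg$block_layers[b]
    outs <- vector("list", L)
    lcaches <- if (keep_cache) vector("list", L) else NULL
    for (l in seq_len(L) - 1L) {
      nm <- sprintf("block%d.layer%d", b, l)
      feats <- if (l == 0L) list(cur) else outs[seq_len(l)]
      skip <- if (l >= 1L) p[[paste0(nm, ".skip")]] else NULL
      wl <- wdl_forward(feats, skip,
                        p[[paste0(nm, ".bn.gamma")]],
                        p[[paste0(nm, ".bn.beta")]],
                        st[[paste0(nm, ".bn")]],
                        p[[paste0(nm, ".conv.W")]],
                        p[[paste0(nm, ".conv.b")]],
                        training, use_bn)
      outs[[l + 1L]] <- wl$y
      if (use_bn && training) st[[paste0(nm, ".bn")]] <- wl$bn_state
      if (keep_cache) lcaches[[l + 1L]] <- wl$cache
    }
    cur <- concat_ch(outs)
    if (keep_cache) {
      cache[[sprintf("block%d", b)]] <-
        list(lcaches = lcaches,
             Cs = vapply(outs, function(x) dim(x)[4], integer(1)))
    }

    if (b < n_blocks) {
      nm <- sprintf("trans%d", b)
      tc <- list()
      cv1 <- conv_forward(cur, p[[paste0(nm, ".conv.W")]],
                          p[[paste0(nm, ".conv.b")]], stride = 1L, pad = 0L)
      cur <- cv1$y
      tc$conv <- cv1$cache
      if (use_bn) {
        bn <- bn_forward(cur, p[[paste0(nm, ".bn.gamma")]],
                         p[[paste0(nm, ".bn.beta")]],
                         st[[paste0(nm, ".bn")]]$mean,
                         st[[paste0(nm, ".bn")]]$var, training = training)
        if (training) st[[paste0(nm, ".bn")]] <-
          list(mean = bn$run_mean, var = bn$run_var)
        cur <- bn$y
        tc$bn <- bn$cache
      }
      r <- relu_forward(cur)
      cur <- r$y
      tc$relu <- r$cache
      if (cfg$downsample == "dilated_conv") {
        cvd <- conv_forward(cur, p[[paste0(nm, ".down.W")]],
                            p[[paste0(nm, ".down.b")]],
                            stride = 2L, pad = 2L, dilation = 2L)
        cur <- cvd$y
        tc$down <- cvd$cache
      } else {
        ap <- avgpool_forward(cur)
        cur <- ap$y
        tc$down <- ap$cache
      }
      if (keep_cache) cache[[nm]] <- tc
    }
  }

  hc <- list()
  gp <- gap_forward(cur)
  hc$gap <- gp$cache
  dr <- dropout_forward(gp$y, cfg$dropout_rate, training, mask = dropout_mask)
  hc$dropout <- dr$cache
  fc <- fc_forward(dr$y, p[["head.fc.W"]], p[["head.fc.b"]])
  hc$fc <- fc$cache
  if (keep_cache) cache$head <- hc
  logits <- fc$y
  probs <- t(softmax_cols(logits))
  colnames(probs) <- spect_classes()

  list(probs = probs, logits = logits,
       cache = if (keep_cache) cache else NULL,
       state = st,
       dropout_mask = dr$cache)
}

# Full backward pass; dlogits is (K, N). Returns named gradient list
# congruent with model$params.
nn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  use_bn <- cfg$use_batch_norm
  grads <- lapply(p, function(x) { g <- x; g[] <- 0; g })

  hc <- cache$head
  fb <- fc_backward(dlogits, hc$fc, p[["head.fc.W"]])
  grads[["head.fc.W"]] <- fb$dW
  grads[["head.fc.b"]] <- fb$db
  df <- dropout_backward(fb$df, hc$dropout)
  dx <- gap_backward(df, hc$gap)

  n_blocks <- length(cfg$block_layers)
  for (b in rev(seq_len(n_blocks))) {
    if (b < n_blocks) {
      nm <- sprintf("trans%d", b)
      tc <- cache[[nm]]
      if (cfg$downsample == "dilated_conv") {
        cb <- conv_backward(dx, tc$down, p[[paste0(nm, ".down.W")]])
        grads[[paste0(nm, ".down.W")]] <- cb$dW
        grads[[paste0(nm, ".down.b")]] <- cb$db
        dx <- cb$dx
      } else {
        dx <- avgpool_backward(dx, tc$down)
      }
      dx <- relu_backward(dx, tc$relu)
      if (use_bn) {
        bb <- bn_backward(dx, tc$bn)
        grads[[paste0(nm, ".bn.gamma")]] <- bb$dgamma
        grads[[paste0(nm, ".bn.beta")]] <- bb$dbeta
        dx <- bb$dx
      }
      cb <- conv_backward(dx, tc$conv, p[[paste0(nm, ".conv.W")]])
      grads[[paste0(nm, ".conv.W")]] <- cb$dW
      grads[[paste0(nm, ".conv.b")]] <- cb$db
      dx <- cb$dx
    }

    bc <- cache[[sprintf("block%d", b)]]
    L <- cfg$block_layers[b]
    # dx currently holds the gradient of the block output = concat(outs)
    douts <- split_ch(dx, bc$Cs)
    dblock_in <- NULL
    for (l in rev(seq_len(L) - 1L)) {
      nm <- sprintf("block%d.layer%d", b, l)
      wb <- wdl_backward(douts[[l + 1L]], bc$lcaches[[l + 1L]],
                         p[[paste0(nm, ".conv.W")]], use_bn)
      grads[[paste0(nm, ".conv.W")]] <- wb$dW
      grads[[paste0(nm, ".conv.b")]] <- wb$db
      if (use_bn) {
        grads[[paste0(nm, ".bn.gamma")]] <- wb$dgamma
        grads[[paste0(nm, ".bn.beta")]] <- wb$dbeta
      }
      if (l >= 1L) {
        grads[[paste0(nm, ".skip")]] <- wb$dskip
        for (i in seq_len(l)) {
          douts[[i]] <- douts[[i]] + wb$dfeat[[i]]
        }
      } else {
        dblock_in <- wb$dfeat[[1L]]
      }
    }
    dx <- dblock_in
  }
  # stem (input gradient discarded)
  dx <- relu_backward(dx, cache$stem_relu)
  if (use_bn) {
    bb <- bn_backward(dx, cache$stem_bn)
    grads[["stem.bn.gamma"]] <- bb$dgamma
    grads[["stem.bn.beta"]] <- bb$dbeta
    dx <- bb$dx
  }
  cb <- conv_backward(dx, cache$stem, p[["stem.conv.W"]], need_dx = FALSE)
  grads[["stem.conv.W"]] <- cb$dW
  grads[["stem.conv.b"]] <- cb$db
  grads
}

# stack a list of pixel matrices into an input tensor (H, W, 1, N)
stack_images <- function(pixel_list) {
  H <- nrow(pixel_list[[1]])
  x <- array(0, c(H, ncol(pixel_list[[1]]), length(pixel_list), 1L))
  for (i in seq_along(pixel_list)) x[, , i, 1L] <- pixel_list[[i]]
  x
}

#' Forward pass: class probabilities for a batch
#'
#' Runs the network in evaluation mode (running batch-norm statistics,
#' no dropout) and returns one probability vector per image. Each row is
#' nonnegative and sums to 1.
#'
#' @param model A `spect_net`.
#' @param images A list of `labeled_image`/`soft_sample`, a single pixel
#'   matrix, or an array (H, W, 1, N).
#' @return Numeric matrix (N x 4) with columns named by `spect_classes()`.
#' @export
predict_proba <- function(model, images) {
  if (is.matrix(images)) images <- list(list(pixels = images))
  if (is.list(images)) {
    x <- stack_images(lapply(images, `[[`, "pixels"))
  } else x <- images
  nn_forward(model, x, training = FALSE)$probs
}

#' Load matching parameters from a named weight source
#'
#' Copies every tensor from `weight_source` whose name and shape match a
#' model parameter; skip weights and any shape-mismatched tensors keep
#' their current values. This is the transfer-learning hook: a checkpoint
#' exported from a compatible (e.g. ImageNet-pretrained) backbone can
#' seed the convolutions while the architecture's new parameters keep
#' their initialization.
#'
#' @param model A `spect_net`.
#' @param weight_source Named list of numeric tensors, e.g. from
#'   [export_weights()], or a path to an RDS file holding one.
#' @return List with `model` (updated), `loaded` and `skipped` name
#'   vectors. Zero matches produces a warning, not an error.
#' @export
load_pretrained <- function(model, weight_source) {
  if (is.character(weight_source)) {
    if (!file.exists(weight_source)) {
      stop("weight source not readable: ", weight_source, call. = FALSE)
    }
    weight_source <- readRDS(weight_source)
  }
  loaded <- character(0)
  skipped <- character(0)
  for (nm in names(model$params)) {
    src <- weight_source[[nm]]
    cur <- model$params[[nm]]
    if (!is.null(src) && length(src) == length(cur) &&
        identical(dim(src), dim(cur))) {
      model$params[[nm]][] <- src
      loaded <- c(loaded, nm)
    } else {
      skipped <- c(skipped, nm)
    }
  }
  if (length(loaded) == 0) {
    warning("no parameter in the weight source matched the model")
  }
  list(model = model, loaded = loaded, skipped = skipped)
}

#' Export a model's parameters as a named list
#'
#' @param model A `spect_net`.
#' @return Named list of numeric tensors suitable for
#'   [load_pretrained()].
#' @export
export_weights <- function(model) model$params
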