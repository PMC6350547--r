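test_that("weighted dense layer with unit weights equals the standard layer", {
  set.seed(51)
  for (rep in 1:5) {
    x0 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    x1 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    pp <- random_layer_params(6L, 4L)
    y_pkg <- weighted_dense_layer(list(x0, x1), c(1, 1), pp)
    z_ref <- naive_conv(naive_concat(list(x0, x1)), pp$conv$W, pp$conv$b)
    y_ref <- naive_relu(naive_bn(z_ref, pp$bn$gamma, pp$bn$beta))
    expect_lt(max(abs(y_pkg - y_ref)), 1e-6 * max(1, max(abs(y_ref))))
  }
})

test_that("a zero skip weight makes the layer invariant to that input", {
  set.seed(52)
  x0 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  x1 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  x1_perturbed <- x1 + array(rnorm(length(x1), 0, 10), dim(x1))
  pp <- random_layer_params(6L, 4L)
  y_a <- weighted_dense_layer(list(x0, x1), c(1, 0), pp)
  y_b <- weighted_dense_layer(list(x0, x1_perturbed), c(1, 0), pp)
  expect_equal(y_a, y_b, tolerance = 1e-12)
})

test_that("scaling a weight and inversely scaling its input is neutral", {
  set.seed(53)
  x0 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  x1 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  pp <- random_layer_params(6L, 4L)
  y_a <- weighted_dense_layer(list(x0, x1), c(1, 2), pp)
  y_b <- weighted_dense_layer(list(x0, x1 * 2), c(1, 1), pp)
  expect_equal(y_a, y_b, tolerance = 1e-12)
  expect_error(weighted_dense_layer(list(x0, x1), c(1), pp), "mismatch")
})

test_that("skip-weight count per block is L(L-1)/2 and initialized to 1", {
  for (L in c(2L, 3L, 5L)) {
    cfg <- network_config(input_size = 16L, stem_channels = 4L,
                          block_layers = c(L, 2L), growth_rate = 3L)
    m <- build_network(cfg, seed = 1)
    expect_equal(unname(count_skip_weights(m)[1]), L * (L - 1L) / 2L)
    skips <- unlist(m$params[grep("skip", names(m$params))])
    expect_true(all(skips == 1))
  }
})

test_that("forward pass yields one probability vector per image", {
  m <- build_network(tiny_net_config(), seed = 2)
  mb <- random_minibatch(5, 16)
  probs <- predict_proba(m, mb)
  expect_equal(dim(probs), c(5L, 4L))
  expect_true(all(probs >= 0))
  expect_true(all(is.finite(probs)))
  expect_equal(unname(rowSums(probs)), rep(1, 5), tolerance = 1e-6)

  # duplicated image in eval mode gives identical rows
  probs2 <- predict_proba(m, c(mb[1], mb[1]))
  expect_equal(probs2[1, ], probs2[2, ])

  # wrong input size is rejected
  expect_error(predict_proba(m, matrix(0.5, 20, 20)), "does not match")
})

test_that("network building is deterministic in the seed", {
  a <- build_network(tiny_net_config(), seed = 9)
  b <- build_network(tiny_net_config(), seed = 9)
  c3 <- build_network(tiny_net_config(), seed = 10)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c3$params))
})

test_that("too many downsampling stages for the input are rejected", {
  expect_error(network_config(input_size = 16L,
                              block_layers = c(2L, 2L, 2L, 2L)),
               "too small")
})

test_that("dilated-conv and pooling downsampling give identical shapes", {
  mb <- random_minibatch(2, 32)
  for (blocks in list(c(2L, 2L), c(2L, 2L, 2L))) {
    cfg_d <- network_config(input_size = 32L, stem_channels = 4L,
                            block_layers = blocks, growth_rate = 3L,
                            downsample = "dilated_conv")
    cfg_p <- network_config(input_size = 32L, stem_channels = 4L,
                            block_layers = blocks, growth_rate = 3L,
                            downsample = "pool")
    pd <- predict_proba(build_network(cfg_d, 1), mb)
    pp <- predict_proba(build_network(cfg_p, 1), mb)
    expect_equal(dim(pd), dim(pp))
  }
})

test_that("load_pretrained copies exactly the matching tensors", {
  m <- build_network(tiny_net_config(), seed = 3)

  # empty source: nothing loaded, model unchanged, warning not error
  expect_warning(res <- load_pretrained(m, list()), "no parameter")
  expect_length(res$loaded, 0)
  expect_identical(res$model$params, m$params)

  # round trip through the model's own export restores every tensor
  donor <- build_network(tiny_net_config(), seed = 4)
  res <- load_pretrained(m, export_weights(donor))
  expect_length(res$skipped, 0)
  expect_identical(res$model$params, donor$params)

  # a single matching tensor changes exactly that tensor
  one <- export_weights(donor)["stem.conv.W"]
  res <- load_pretrained(m, one)
  expect_identical(res$loaded, "stem.conv.W")
  changed <- vapply(names(m$params), function(nm)
    !identical(res$model$params[[nm]], m$params[[nm]]), logical(1))
  expect_identical(names(m$params)[changed], "stem.conv.W")

  # shape mismatch is skipped, not copied
  bad <- list(`stem.conv.b` = rep(0.5, 99))
  expect_warning(res <- load_pretrained(m, bad), "no parameter")
  expect_identical(res$model$params, m$params)

  # unreadable file path errors
  expect_error(load_pretrained(m, "/nonexistent/weights.rds"),
               "not readable")
})

test_that("analytic gradients match finite differences", {
  m <- build_network(tiny_net_config(), seed = 5)
  mb <- random_minibatch(3, 16, seed = 55)
  cl <- compute_loss(m, mb)
  flat <- pollentrain:::get_flat(m$params)
  gflat <- pollentrain:::get_flat(cl$grads)
  loss_at <- function(v) {
    mm <- m
    mm$params <- pollentrain:::set_flat(m$params, v)
    x <- pollentrain:::stack_images(lapply(mb, `[[`, "pixels"))
    tg <- vapply(mb, `[[`, numeric(4), "label_vec")
    fw <- pollentrain:::nn_forward(mm, x, training = TRUE)
    pollentrain:::cross_entropy_soft(t(fw$probs), tg)
  }
  set.seed(56)
  idx <- sample(length(flat), 40)
  h <- 1e-5
  num <- vapply(idx, function(k) {
    vp <- flat; vm <- flat
    vp[k] <- vp[k] + h; vm[k] <- vm[k] - h
    (loss_at(vp) - loss_at(vm)) / (2 * h)
  }, numeric(1))
  rel <- abs(num - gflat[idx]) / pmax(1e-6, abs(num) + abs(gflat[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("skip weights move away from 1 under training", {
  set.seed(61)
  d <- generate_dataset(c(graves = 15, hashimoto = 15, subacute = 15,
                          normal = 15), 32, seed = 61)
  samples <- lapply(d, function(im)
    pollentrain:::as_soft(im))
  m <- build_network(network_config(dropout_rate = 0), seed = 62)
  cfg <- train_config(batch_size = 5L, max_epochs = 6L, lr_init = 0.05,
                      fpa_every_k_steps = Inf, early_stop_patience = 10L,
                      validation_fraction = 0.1, seed = 63)
  tr <- train_network(m, samples, cfg)
  expect_gte(nrow(tr$history$steps), 50)
  skips <- unlist(tr$model$params[grep("skip", names(tr$model$params))])
  expect_gt(max(abs(skips - 1)), 1e-4)
})
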