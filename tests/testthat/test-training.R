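test_that("cross entropy hits its known values at canonical predictions", {
  # uniform prediction vs one-hot target: -ln(1/4)
  m <- build_network(tiny_net_config(), seed = 5)
  m$params[["head.fc.W"]][] <- 0
  m$params[["head.fc.b"]][] <- 0
  mb <- lapply(1:4, function(i) {
    lv <- numeric(4); lv[i] <- 1
    list(pixels = matrix(runif(16 * 16), 16, 16), label_vec = lv)
  })
  cl <- compute_loss(m, mb)
  expect_equal(cl$loss, log(4), tolerance = 1e-9)
  expect_equal(unname(cl$probs[1, ]), rep(0.25, 4), tolerance = 1e-12)

  # prediction equal to a soft target: loss = target entropy (the
  # cross-entropy lower bound); checked directly on the loss function
  tg <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.25, 0.25, 0.25, 0.25), 4, 2)
  ent <- -mean(colSums(tg * log(tg)))
  expect_equal(pollentrain:::cross_entropy_soft(tg, tg), ent)

  # perfect one-hot prediction has zero loss
  p <- matrix(c(1, 0, 0, 0), 4, 1)
  expect_equal(pollentrain:::cross_entropy_soft(p, p), 0, tolerance = 1e-10)
})

test_that("gradients flow to every parameter group including skips", {
  m <- build_network(tiny_net_config(), seed = 6)
  mb <- random_minibatch(4, 16, seed = 66)
  cl <- compute_loss(m, mb)
  gn <- vapply(cl$grads, function(g) sum(abs(g)), numeric(1))
  expect_true(all(gn[grep("conv.W|fc.W|skip", names(gn))] > 0))
})

test_that("trial_update_loss evaluates w - lr*grad and restores the model", {
  m <- build_network(tiny_net_config(), seed = 7)
  mb <- random_minibatch(3, 16, seed = 77)
  cl <- compute_loss(m, mb)
  before <- m$params

  # lr = 0 returns the current loss exactly
  expect_equal(trial_update_loss(m, mb, cl$grads, 0, cl$dropout_mask),
               cl$loss, tolerance = 1e-12)

  # matches an independent manual update + forward pass
  lr <- 0.03
  got <- trial_update_loss(m, mb, cl$grads, lr, cl$dropout_mask)
  mm <- m
  mm$params <- pollentrain:::set_flat(
    m$params,
    pollentrain:::get_flat(m$params) - lr * pollentrain:::get_flat(cl$grads))
  x <- pollentrain:::stack_images(lapply(mb, `[[`, "pixels"))
  tg <- vapply(mb, `[[`, numeric(4), "label_vec")
  want <- pollentrain:::cross_entropy_soft(
    t(pollentrain:::nn_forward(mm, x, training = TRUE)$probs), tg)
  expect_equal(got, want, tolerance = 1e-12)

  # model untouched
  expect_identical(m$params, before)
})

test_that("training improves the loss and honors the incumbent guarantee", {
  set.seed(91)
  d <- generate_dataset(c(graves = 20, hashimoto = 20, subacute = 20,
                          normal = 20), 32, seed = 91)
  samples <- lapply(d, pollentrain:::as_soft)
  m <- build_network(network_config(), seed = 92)
  cfg <- train_config(batch_size = 5L, max_epochs = 2L, lr_init = 0.05,
                      fpa = fpa_config(n_iterations = 2L, n_pollen = 4L),
                      fpa_every_k_steps = 1, early_stop_patience = 3L,
                      validation_fraction = 0.1, seed = 93)
  tr <- train_network(m, samples, cfg)
  h <- tr$history$steps
  expect_true(all(h$loss_after <= h$incumbent_loss + 1e-10))
  expect_true(all(is.finite(h$loss_after)))
  expect_equal(nrow(tr$history$epochs), 2)
  # trained model beats the untrained one on its own training data
  ev0 <- evaluate_model(m, samples)
  ev1 <- evaluate_model(tr$model, samples)
  expect_gte(sum(diag(ev1$cm)), sum(diag(ev0$cm)))
})

test_that("identical seed and config reproduce the training history", {
  d <- generate_dataset(c(graves = 10, hashimoto = 10, subacute = 10,
                          normal = 10), 32, seed = 94)
  samples <- lapply(d, pollentrain:::as_soft)
  cfg <- train_config(batch_size = 5L, max_epochs = 1L, lr_init = 0.05,
                      fpa = fpa_config(n_iterations = 2L, n_pollen = 4L),
                      early_stop_patience = 2L, seed = 95)
  a <- train_network(build_network(network_config(), seed = 96), samples, cfg)
  b <- train_network(build_network(network_config(), seed = 96), samples, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
})

test_that("disabling the search reproduces plain fixed-rate SGD", {
  d <- generate_dataset(c(graves = 8, hashimoto = 8, subacute = 8,
                          normal = 8), 32, seed = 97)
  samples <- lapply(d, pollentrain:::as_soft)
  net_cfg <- network_config(dropout_rate = 0)
  cfg <- train_config(batch_size = 4L, max_epochs = 1L, lr_init = 0.04,
                      fpa_every_k_steps = Inf, early_stop_patience = 2L,
                      validation_fraction = 0.15, seed = 98)
  tr <- train_network(build_network(net_cfg, seed = 99), samples, cfg)

  # independent reference SGD loop replaying the same RNG stream
  m <- build_network(net_cfg, seed = 99)
  set.seed(98)
  sp <- pollentrain:::stratified_val_split(samples, 0.15)
  tr_set <- samples[sp$train]
  ord <- sample(length(tr_set))
  i <- 1
  while (i <= length(tr_set)) {
    j <- min(i + 3, length(tr_set))
    mb <- tr_set[ord[i:j]]
    i <- j + 1
    cl <- compute_loss(m, mb)
    m$state <- cl$state
    m$params <- pollentrain:::set_flat(
      m$params,
      pollentrain:::get_flat(m$params) -
        0.04 * pollentrain:::get_flat(cl$grads))
  }
  # with one epoch the best-validation model is the end-of-epoch model
  expect_equal(pollentrain:::get_flat(tr$model$params),
               pollentrain:::get_flat(m$params), tolerance = 1e-12)
  expect_true(all(tr$history$steps$lr == 0.04))
})

test_that("early stopping halts within patience of the last improvement", {
  d <- generate_dataset(c(graves = 8, hashimoto = 8, subacute = 8,
                          normal = 8), 32, seed = 101)
  samples <- lapply(d, pollentrain:::as_soft)
  # zero learning rate: no improvement is possible after epoch 1
  cfg <- train_config(batch_size = 8L, max_epochs = 10L, lr_init = 0,
                      fpa_every_k_steps = Inf, early_stop_patience = 2L,
                      validation_fraction = 0.15, seed = 102)
  net <- network_config(dropout_rate = 0, use_batch_norm = FALSE)
  tr <- train_network(build_network(net, seed = 103), samples, cfg)
  expect_lte(nrow(tr$history$epochs), 3)
})

test_that("training rejects an empty train set or missing classes", {
  expect_error(train_network(build_network(tiny_net_config(), 1), list(),
                             train_config()), "empty")
  d <- generate_dataset(c(graves = 6, hashimoto = 6, subacute = 6,
                          normal = 0), 32, seed = 104)
  samples <- lapply(d, pollentrain:::as_soft)
  expect_error(train_network(build_network(network_config(), 1), samples,
                             train_config()), "normal")
})
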