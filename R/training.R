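#' Training configuration
#'
#' @param batch_size Minibatch size (default 5).
#' @param max_epochs Maximum number of epochs.
#' @param lr_init Initial incumbent learning rate, used before the first
#'   FPA search and as the fixed rate when the search is disabled.
#' @param fpa An [fpa_config()] controlling the per-minibatch
#'   learning-rate search.
#' @param fpa_every_k_steps Run the FPA search every k-th minibatch
#'   (default 1 = every minibatch); `Inf` disables it, reducing the loop
#'   to plain fixed-rate SGD.
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement.
#' @param validation_fraction Fraction of the training set held out for
#'   validation (per-class stratified), in (0, 0.5).
#' @param seed Integer seed governing shuffling, dropout and the FPA
#'   search.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 5L, max_epochs = 10L,
                         lr_init = 0.05, fpa = fpa_config(),
                         fpa_every_k_steps = 1,
                         early_stop_patience = 3L,
                         validation_fraction = 0.1,
                         seed = 1L) {
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(max_epochs >= 1, "max_epochs must be >= 1")
  assert_that(validation_fraction > 0 && validation_fraction < 0.5,
              "validation_fraction must be in (0, 0.5)")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_init = lr_init, fpa = fpa,
                 fpa_every_k_steps = fpa_every_k_steps,
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# targets matrix (K, N) from a minibatch of soft samples
batch_targets <- function(minibatch) {
  vapply(minibatch, `[[`, numeric(4), "label_vec")
}

#' Minibatch loss and gradient
#'
#' Computes the mean soft-target cross entropy of a minibatch and its
#' gradient with respect to every trainable parameter, including the
#' skip-connection weights. The forward pass runs in training mode
#' (batch statistics, dropout active when configured).
#'
#' @param model A `spect_net`.
#' @param minibatch List of `soft_sample`.
#' @return List with `loss`, `grads` (named list congruent with
#'   `model$params`), `probs`, `state` (updated batch-norm running
#'   statistics) and `dropout_mask` (the mask used, for deterministic
#'   re-evaluation).
#' @export
compute_loss <- function(model, minibatch) {
  x <- stack_images(lapply(minibatch, `[[`, "pixels"))
  targets <- batch_targets(minibatch)
  fw <- nn_forward(model, x, training = TRUE, keep_cache = TRUE)
  probs_t <- t(fw$probs)            # (K, N)
  loss <- cross_entropy_soft(probs_t, targets)
  if (!is.finite(loss)) {
    stop("non-finite loss in compute_loss (forward pass)", call. = FALSE)
  }
  dlogits <- cross_entropy_grad(probs_t, targets)
  grads <- nn_backward(model, fw$cache, dlogits)
  list(loss = loss, grads = grads, probs = fw$probs,
       state = fw$state, dropout_mask = fw$dropout_mask)
}

#' Loss of a trial parameter update
#'
#' Evaluates the minibatch loss at `w - lr * grad` without changing the
#' model: the candidate parameters exist only inside the call, so the
#' model is untouched on exit. Used as the FPA fitness function; with
#' `dropout_mask` fixed and batch statistics recomputed from the same
#' minibatch the evaluation is deterministic in `lr`.
#'
#' @param model A `spect_net`.
#' @param minibatch List of `soft_sample` the gradient was computed on.
#' @param grads Named gradient list from [compute_loss()].
#' @param lr Learning rate of the trial step; `lr = 0` returns the
#'   current loss exactly.
#' @param dropout_mask Optional fixed dropout mask.
#' @return The trial loss (numeric scalar).
#' @export
trial_update_loss <- function(model, minibatch, grads, lr,
                              dropout_mask = NULL) {
  flat <- get_flat(model$params)
  gflat <- get_flat(grads)
  trial <- model
  trial$params <- set_flat(model$params, flat - lr * gflat)
  x <- stack_images(lapply(minibatch, `[[`, "pixels"))
  targets <- batch_targets(minibatch)
  fw <- nn_forward(trial, x, training = TRUE, keep_cache = FALSE,
                   dropout_mask = dropout_mask)
  cross_entropy_soft(t(fw$probs), targets)
}

# stratified index split: returns list(train_idx, val_idx)
stratified_val_split <- function(samples, fraction) {
  groups <- vapply(samples, function(s) {
    if (!is.null(s$class_group)) s$class_group
    else spect_classes()[which.max(s$label_vec)]
  }, character(1))
  counts <- class_tally(samples)
  assert_that(all(counts > 0),
              sprintf("training set has empty classes: %s",
                      paste(names(counts)[counts == 0], collapse = ", ")))
  val <- integer(0)
  for (cl in spect_classes()) {
    idx <- which(groups == cl)
    n_val <- max(1L, floor(fraction * length(idx)))
    val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(samples), val), val = sort(val))
}

# evaluation-mode loss and macro precision over a sample list, chunked
validation_metrics <- function(model, samples, chunk = 100L) {
  n <- length(samples)
  losses <- numeric(0)
  pred <- character(n)
  actual <- character(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    sub <- samples[i:j]
    probs <- predict_proba(model, sub)
    targets <- batch_targets(sub)
    losses <- c(losses, cross_entropy_soft(t(probs), targets) * (j - i + 1L))
    pred[i:j] <- spect_classes()[apply(probs, 1L, which.max)]
    actual[i:j] <- spect_classes()[apply(targets, 2L, which.max)]
    i <- j + 1L
  }
  cm <- confusion_matrix(pred, actual)
  list(loss = sum(losses) / n, macro_precision = macro_precision(cm)$value)
}

#' Train a model with per-minibatch FPA learning-rate search
#'
#' Plain SGD (`w <- w - l * grad`) where, every `fpa_every_k_steps`
#' minibatches, the learning rate `l` is chosen by the flower
#' pollination algorithm to minimize that minibatch's post-update loss.
#' The previously committed rate is seeded into the FPA population, so
#' each committed update is never worse (on its minibatch) than the
#' incumbent rate would have been. A per-class stratified validation
#' subset drives early stopping; the model with the best validation loss
#' is returned.
#'
#' @param model A `spect_net` from [build_network()].
#' @param samples Training set: list of `soft_sample` covering all four
#'   classes.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-validation parameters) and `history`:
#'   `$steps` (one row per step: epoch, step, learning rate, whether FPA
#'   ran, loss before the update, the incumbent-rate trial loss, and the
#'   committed post-update loss) and `$epochs` (validation loss and
#'   macro precision per epoch).
#' @export
train_network <- function(model, samples, config = train_config(),
                          verbose = FALSE) {
  assert_that(length(samples) > 0, "training set is empty")
  set.seed(config$seed)
  sp <- stratified_val_split(samples, config$validation_fraction)
  tr <- samples[sp$train]
  va <- samples[sp$val]

  incumbent <- config$lr_init
  step_no <- 0L
  steps <- list()
  epochs <- list()
  best_val <- Inf
  best_params <- model$params
  best_state <- model$state
  wait <- 0L

  for (ep in seq_len(config$max_epochs)) {
    ord <- sample(length(tr))
    i <- 1L
    while (i <= length(tr)) {
      j <- min(i + config$batch_size - 1L, length(tr))
      mb <- tr[ord[i:j]]
      i <- j + 1L
      step_no <- step_no + 1L

      cl <- compute_loss(model, mb)
      model$state <- cl$state
      gflat <- get_flat(cl$grads)

      use_fpa <- is.finite(config$fpa_every_k_steps) &&
        (step_no - 1L) %% config$fpa_every_k_steps == 0
      inc_loss <- trial_update_loss(model, mb, cl$grads, incumbent,
                                    dropout_mask = cl$dropout_mask)
      if (use_fpa) {
        fit <- function(lr) trial_update_loss(model, mb, cl$grads, lr,
                                              dropout_mask = cl$dropout_mask)
        res <- optimize_learning_rate(fit, config$fpa,
                                      incumbent_lr = incumbent)
        lr_commit <- res$l_best
        loss_after <- res$f_best
        incumbent <- lr_commit
      } else {
        lr_commit <- incumbent
        loss_after <- inc_loss
      }
      if (!is.finite(loss_after)) {
        stop(sprintf("training diverged at step %d (non-finite loss)",
                     step_no), call. = FALSE)
      }
      model$params <- set_flat(model$params,
                               get_flat(model$params) - lr_commit * gflat)
      steps[[step_no]] <- data.frame(
        epoch = ep, step = step_no, lr = lr_commit, fpa = use_fpa,
        loss_before = cl$loss, incumbent_loss = inc_loss,
        loss_after = loss_after)
    }

    vm <- validation_metrics(model, va)
    improved <- vm$loss < best_val - 1e-12
    if (improved) {
      best_val <- vm$loss
      best_params <- model$params
      best_state <- model$state
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    epochs[[ep]] <- data.frame(epoch = ep, val_loss = vm$loss,
                               val_macro_precision = vm$macro_precision,
                               improved = improved)
    if (verbose) {
      message(sprintf("epoch %d: val loss %.4f, val macro precision %.3f%s",
                      ep, vm$loss, vm$macro_precision,
                      if (improved) " *" else ""))
    }
    if (wait >= config$early_stop_patience) break
  }

  model$params <- best_params
  model$state <- best_state
  list(model = model,
       history = list(steps = do.call(rbind, steps),
                      epochs = do.call(rbind, epochs)))
}
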