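# Run configuration: YAML schema, validation with unknown-key rejection,
# and the end-to-end pipeline (generate -> augment -> split -> train ->
# evaluate) plus single-image diagnosis.

default_run_config <- function() {
  list(
    seed = 1L,
    dataset = list(
      counts = list(graves = 50L, hashimoto = 50L, subacute = 50L,
                    normal = 50L),
      image_size = 32L),
    augmentation = list(
      alpha_low = 0.5, alpha_high = 1.0,
      target_per_class = 60L, train_per_class = 42L, test_per_class = 18L,
      split_first = FALSE,
      persist_augmented = FALSE),
    network = list(
      arch = "small", stem_channels = 8L, block_layers = c(3L, 3L),
      growth_rate = 8L, downsample = "dilated_conv", compression = 0.5,
      dropout_rate = 0.2, use_batch_norm = TRUE),
    training = list(
      batch_size = 5L, max_epochs = 5L, lr_init = 0.05,
      fpa_every_k_steps = 1, early_stop_patience = 3L,
      validation_fraction = 0.1,
      fpa = list(n_iterations = 4L, n_pollen = 6L, switch_prob = 0.8,
                 gamma = 0.1, levy_exponent = 1.5,
                 lr_min = 1e-4, lr_max = 0.5)),
    evaluation = list(checkpoint_every = 0L))
}

# merge user values over defaults, erroring on unknown keys
merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !nm %in% c("counts", "block_layers")) {
      assert_that(is.list(user[[nm]]) || is.null(user[[nm]]),
                  sprintf("configuration section '%s' must be a mapping", full))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills every missing field with
#' its default, and rejects unknown keys outright. The resolved
#' configuration fully determines a run together with its seed.
#'
#' @param config Path to a YAML file, or a (possibly partial) list.
#' @return Resolved configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML file path")
  cfg <- merge_config(default_run_config(), config)
  # cross-field validation (fail fast, before any compute)
  mixup_config(cfg$augmentation$alpha_low, cfg$augmentation$alpha_high,
               cfg$augmentation$target_per_class,
               cfg$augmentation$train_per_class,
               cfg$augmentation$test_per_class)
  check_labels(names(cfg$dataset$counts), "class")
  structure(cfg, class = "run_config")
}

config_mixup <- function(cfg) {
  mixup_config(cfg$augmentation$alpha_low, cfg$augmentation$alpha_high,
               cfg$augmentation$target_per_class,
               cfg$augmentation$train_per_class,
               cfg$augmentation$test_per_class)
}

config_network <- function(cfg) {
  n <- cfg$network
  if (identical(n$arch, "clinical")) return(network_config(arch = "clinical"))
  network_config(input_size = cfg$dataset$image_size,
                 stem_channels = n$stem_channels,
                 block_layers = as.integer(unlist(n$block_layers)),
                 growth_rate = n$growth_rate,
                 downsample = n$downsample,
                 compression = n$compression,
                 dropout_rate = n$dropout_rate,
                 use_batch_norm = n$use_batch_norm)
}

config_train <- function(cfg) {
  t <- cfg$training
  f <- t$fpa
  train_config(batch_size = t$batch_size, max_epochs = t$max_epochs,
               lr_init = t$lr_init,
               fpa = fpa_config(f$n_iterations, f$n_pollen, f$switch_prob,
                                f$gamma, f$levy_exponent, f$lr_min, f$lr_max),
               fpa_every_k_steps = t$fpa_every_k_steps,
               early_stop_patience = t$early_stop_patience,
               validation_fraction = t$validation_fraction,
               seed = cfg$seed)
}

#' Balance with mixup and split into train/test in one step
#'
#' By default follows the augment-then-split order: the whole dataset is
#' balanced to the target size, then each class group is randomly
#' partitioned. With `split_first = TRUE` the original images are first
#' partitioned per class (in the train/test proportion) and each side is
#' augmented separately from its own images only, so no original leaks
#' across the split through a mixed sample.
#'
#' @param dataset List of `labeled_image`.
#' @param config A [mixup_config()].
#' @param seed Integer seed.
#' @param split_first Leakage-free variant flag.
#' @return `list(train = ..., test = ...)` of `soft_sample` lists.
#' @export
augment_and_split <- function(dataset, config = mixup_config(), seed = 1,
                              split_first = FALSE) {
  if (!split_first) {
    aug <- augment_to_target(dataset, config, seed = seed)
    return(split_dataset(aug, config, seed = seed + 1L))
  }
  labs <- vapply(dataset, `[[`, character(1), "label")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  frac <- config$train_per_class / config$target_per_class
  tr_idx <- integer(0)
  for (cl in spect_classes()) {
    idx <- which(labs == cl)
    tr_idx <- c(tr_idx, sample(idx, max(1L, round(frac * length(idx)))))
  }
  te_idx <- setdiff(seq_along(dataset), tr_idx)
  cfg_tr <- mixup_config(config$alpha_low, config$alpha_high,
                         config$train_per_class, config$train_per_class - 1L, 1L)
  cfg_te <- mixup_config(config$alpha_low, config$alpha_high,
                         config$test_per_class,
                         max(1L, config$test_per_class - 1L),
                         min(1L, config$test_per_class - 1L))
  list(train = augment_to_target(dataset[tr_idx],
                                 cfg_tr, seed = seed + 1L),
       test = augment_to_target(dataset[te_idx],
                                cfg_te, seed = seed + 2L))
}

#' Persist a soft-labeled dataset as PNGs plus a manifest
#'
#' Like [write_dataset()] but for `soft_sample` lists: the manifest
#' gains four columns holding the label-vector entries plus `origin`.
#'
#' @param samples List of `soft_sample`.
#' @param out_dir Output directory.
#' @param split Split tag column (recycled).
#' @return The manifest data.frame.
#' @export
write_soft_dataset <- function(samples, out_dir, split = "unsplit") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(samples)
  split <- rep_len(split, if (n > 0) n else 0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    fn <- paste0(s$id, ".png")
    png::writePNG(s$pixels, file.path(out_dir, fn))
    lv <- as.list(stats::setNames(s$label_vec,
                                  paste0("p_", spect_classes())))
    rows[[i]] <- data.frame(filename = fn, label = s$class_group,
                            split = split[i], origin = s$origin, lv,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(filename = character(0), label = character(0),
               split = character(0), origin = character(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

log_stage <- function(run_dir, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
      file = file.path(run_dir, "log.txt"), append = TRUE)
}

#' Run the full pipeline: generate, augment, split, train, evaluate
#'
#' Executes the training stage (synthetic data generation, mixup
#' balancing, train/test split, FPA-SGD training) followed by the
#' diagnosis-stage evaluation, writing every artifact needed to
#' re-execute the run into `run_dir`: the resolved configuration, the
#' raw-data manifest, the model checkpoint, the step/epoch training
#' histories, and the JSON/CSV evaluation report.
#'
#' @param config Path to a YAML configuration, or a list (see
#'   [run_config()]).
#' @param run_dir Output directory.
#' @param resume Skip a stage when its outputs already exist.
#' @param verbose Print per-epoch progress.
#' @return Invisibly, a list with `run_dir`, the trained `model`, the
#'   training `history` and the `evaluation` result.
#' @export
run_pipeline <- function(config = list(), run_dir = tempfile("run_"),
                         resume = FALSE, verbose = FALSE) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(run_dir, "resolved_config.yaml"))
  log_stage(run_dir, sprintf("run start (seed %d)", cfg$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  data_dir <- file.path(run_dir, "data")
  dataset <- stage("generate", {
    d <- generate_dataset(cfg$dataset$counts, cfg$dataset$image_size,
                          seed = cfg$seed)
    if (!resume || !file.exists(file.path(data_dir, "manifest.csv"))) {
      write_dataset(d, data_dir)
    }
    log_stage(run_dir, sprintf("generate: %d images", length(d)))
    d
  })

  mix_cfg <- config_mixup(cfg)
  sets <- stage("augment+split", {
    s <- augment_and_split(dataset, mix_cfg, seed = cfg$seed + 100L,
                           split_first = isTRUE(cfg$augmentation$split_first))
    if (isTRUE(cfg$augmentation$persist_augmented)) {
      write_soft_dataset(c(s$train, s$test),
                         file.path(run_dir, "augmented"),
                         split = c(rep("train", length(s$train)),
                                   rep("test", length(s$test))))
    }
    log_stage(run_dir, sprintf("augment+split: %d train / %d test",
                               length(s$train), length(s$test)))
    s
  })

  ckpt <- file.path(run_dir, "checkpoint.rds")
  trained <- stage("train", {
    if (resume && file.exists(ckpt)) {
      readRDS(ckpt)
    } else {
      model <- build_network(config_network(cfg), seed = cfg$seed + 200L)
      tr <- train_network(model, sets$train, config_train(cfg),
                          verbose = verbose)
      saveRDS(tr, ckpt)
      utils::write.csv(tr$history$steps,
                       file.path(run_dir, "history_steps.csv"),
                       row.names = FALSE)
      utils::write.csv(tr$history$epochs,
                       file.path(run_dir, "history_epochs.csv"),
                       row.names = FALSE)
      tr
    }
  })
  log_stage(run_dir, sprintf("train: %d steps", nrow(trained$history$steps)))

  ev <- stage("evaluate", {
    res <- evaluate_model(trained$model, sets$test)
    write_report(res, run_dir)
    res
  })
  log_stage(run_dir, sprintf("evaluate: macro precision %s",
                             fmt_pc(ev$macro$precision)))

  invisible(list(run_dir = run_dir, model = trained$model,
                 history = trained$history, evaluation = ev))
}

#' Diagnose images with a trained model
#'
#' Reads one PNG (or every PNG in a directory), runs the model, and
#' returns one row per image with the predicted class and the four class
#' probabilities. An unreadable file is reported and skipped; the run
#' continues.
#'
#' @param model A `spect_net`, or the path to a pipeline checkpoint
#'   (`checkpoint.rds`).
#' @param path PNG file or directory of PNGs.
#' @param out_csv Optional CSV path for the results.
#' @return data.frame with columns `filename`, `predicted`,
#'   `p_graves`, `p_hashimoto`, `p_subacute`, `p_normal`.
#' @export
diagnose <- function(model, path, out_csv = NULL) {
  if (is.character(model)) {
    obj <- readRDS(model)
    model <- if (inherits(obj, "spect_net")) obj else obj$model
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.png$", full.names = TRUE)
  } else path
  rows <- list()
  for (f in files) {
    px <- tryCatch({
      p <- png::readPNG(f)
      if (length(dim(p)) == 3) p <- p[, , 1]
      p
    }, error = function(e) {
      warning(sprintf("cannot read image %s: %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(px)) next
    probs <- predict_proba(model, px)
    rows[[length(rows) + 1L]] <- data.frame(
      filename = basename(f),
      predicted = spect_classes()[which.max(probs[1L, ])],
      p_graves = probs[1, 1], p_hashimoto = probs[1, 2],
      p_subacute = probs[1, 3], p_normal = probs[1, 4],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(filename = character(0), predicted = character(0),
               p_graves = numeric(0), p_hashimoto = numeric(0),
               p_subacute = numeric(0), p_normal = numeric(0))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
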