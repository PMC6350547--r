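#' Mixup/balancing configuration
#'
#' Controls how the raw dataset is balanced up to a fixed per-class size
#' with mixup and then partitioned into train and test sets.
#'
#' @param alpha_low,alpha_high Bounds of the uniform distribution from
#'   which the mixing coefficient alpha is drawn per generated sample;
#'   must satisfy `0.5 <= alpha_low <= alpha_high <= 1`, so the first
#'   image always dominates the blend.
#' @param target_per_class Per-class size after augmentation (default 2000).
#' @param train_per_class,test_per_class Per-class split sizes; must sum
#'   to `target_per_class` (defaults 1400/600).
#' @return An object of class `mixup_config`.
#' @export
mixup_config <- function(alpha_low = 0.5, alpha_high = 1.0,
                         target_per_class = 2000L,
                         train_per_class = 1400L, test_per_class = 600L) {
  assert_that(alpha_low >= 0.5 && alpha_low <= alpha_high && alpha_high <= 1,
              "alpha bounds must satisfy 0.5 <= alpha_low <= alpha_high <= 1")
  assert_that(train_per_class + test_per_class == target_per_class,
              "train_per_class + test_per_class must equal target_per_class")
  structure(list(alpha_low = alpha_low, alpha_high = alpha_high,
                 target_per_class = as.integer(target_per_class),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class)),
            class = "mixup_config")
}

#' One-hot encode a class label
#'
#' @param label One of `spect_classes()`.
#' @param n_classes Number of classes (fixed at 4 here).
#' @return Numeric probability vector with a single 1 at the class index.
#' @examples
#' one_hot("graves")   # 1 0 0 0
#' @export
one_hot <- function(label, n_classes = 4L) {
  check_labels(label)
  v <- numeric(n_classes)
  v[match(label, spect_classes())] <- 1
  v
}

# internal soft-sample constructor
soft_sample <- function(pixels, label_vec, origin, class_group, id) {
  assert_that(abs(sum(label_vec) - 1) < 1e-9 && all(label_vec >= 0),
              "label_vec must be a probability vector")
  structure(list(pixels = pixels, label_vec = label_vec,
                 origin = origin, class_group = class_group,
                 id = as.character(id)),
            class = "soft_sample")
}

#' Mix two images and their label vectors
#'
#' Forms the convex combination `alpha * x_i + (1 - alpha) * x_j` of two
#' images and likewise of their label vectors, producing a virtual sample
#' with a soft label. With `alpha >= 0.5` the first image dominates, so
#' the mixed label's largest entry is at least 0.5.
#'
#' @param x_i,x_j Pixel matrices of identical dimensions.
#' @param y_i,y_j Label probability vectors of length 4.
#' @param alpha Mixing coefficient in [0.5, 1].
#' @param class_group Class the mixed sample counts toward (the class of
#'   `x_i` under the dominant-component convention).
#' @param id Identifier for the new sample.
#' @return A `soft_sample` with `origin = "mixed"`.
#' @export
mixup_pair <- function(x_i, y_i, x_j, y_j, alpha,
                       class_group = spect_classes()[which.max(y_i)],
                       id = "mixed") {
  assert_that(all(dim(x_i) == dim(x_j)),
              "x_i and x_j must have identical dimensions")
  assert_that(is.numeric(alpha) && length(alpha) == 1 &&
                alpha >= 0.5 && alpha <= 1,
              "alpha must be a single value in [0.5, 1]")
  px <- alpha * x_i + (1 - alpha) * x_j
  lv <- alpha * y_i + (1 - alpha) * y_j
  soft_sample(px, lv, "mixed", class_group, id)
}

# internal: promote a labeled_image to a one-hot soft sample
as_soft <- function(im) {
  soft_sample(im$pixels, one_hot(im$label), "real", im$label, im$id)
}

#' Balance every class up to a target size with mixup
#'
#' All originals are retained as one-hot samples. For each class c with
#' fewer than `target_per_class` originals, virtual samples are generated
#' until the class group reaches the target: the dominant image X_i is
#' drawn uniformly from class c's originals, the partner X_j uniformly
#' from all originals with X_j != X_i, and alpha uniformly from
#' `[alpha_low, alpha_high]`. A mixed sample counts toward the class of
#' its dominant image X_i.
#'
#' @param dataset List of `labeled_image`; every class must be present
#'   and no class may exceed the target.
#' @param config A [mixup_config()].
#' @param seed Integer seed.
#' @return List of `soft_sample`, `4 * target_per_class` long when all
#'   four classes are present, grouped by class.
#' @export
augment_to_target <- function(dataset, config = mixup_config(), seed = 1) {
  labs <- vapply(dataset, `[[`, character(1), "label")
  counts <- class_tally(dataset)
  assert_that(all(counts > 0),
              sprintf("every class needs at least one original; empty: %s",
                      paste(names(counts)[counts == 0], collapse = ", ")))
  assert_that(all(counts <= config$target_per_class),
              "per-class original count must not exceed target_per_class")

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  out <- list()
  for (cl in spect_classes()) {
    idx_c <- which(labs == cl)
    group <- lapply(dataset[idx_c], as_soft)
    n_new <- config$target_per_class - length(idx_c)
    if (n_new > 0) {
      mixed <- vector("list", n_new)
      for (m in seq_len(n_new)) {
        i <- idx_c[sample.int(length(idx_c), 1)]
        repeat {
          j <- sample.int(length(dataset), 1)
          if (j != i) break
        }
        a <- stats::runif(1, config$alpha_low, config$alpha_high)
        mixed[[m]] <- mixup_pair(dataset[[i]]$pixels, one_hot(labs[i]),
                                 dataset[[j]]$pixels, one_hot(labs[j]),
                                 a, class_group = cl,
                                 id = sprintf("%s_mix_%04d", cl, m))
      }
      group <- c(group, mixed)
    }
    out <- c(out, group)
  }
  out
}

#' Split a balanced dataset into train and test sets
#'
#' Within each class group (of exactly `target_per_class` samples) a
#' seeded uniform random partition assigns `train_per_class` samples to
#' the training set and `test_per_class` to the test set. The two sets
#' are disjoint and their union is the input.
#'
#' @param samples List of `soft_sample` from [augment_to_target()].
#' @param config A [mixup_config()].
#' @param seed Integer seed.
#' @return `list(train = ..., test = ...)`.
#' @export
split_dataset <- function(samples, config = mixup_config(), seed = 1) {
  groups <- vapply(samples, `[[`, character(1), "class_group")
  counts <- class_tally(samples)
  assert_that(all(counts == config$target_per_class),
              sprintf("every class group must have exactly %d samples (got %s)",
                      config$target_per_class,
                      paste(counts, collapse = "/")))

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  train <- list(); test <- list()
  for (cl in spect_classes()) {
    idx <- which(groups == cl)
    tr <- sample(idx, config$train_per_class)
    te <- setdiff(idx, tr)
    train <- c(train, samples[tr])
    test <- c(test, samples[te])
  }
  list(train = train, test = test)
}
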