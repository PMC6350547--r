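# Shared fixtures. Everything is generated in code at test time.

tiny_counts <- c(graves = 8L, hashimoto = 8L, subacute = 8L, normal = 8L)

tiny_dataset <- function(seed = 11, size = 32) {
  generate_dataset(tiny_counts, image_size = size, seed = seed)
}

tiny_net_config <- function(...) {
  network_config(input_size = 16L, stem_channels = 4L,
                 block_layers = c(2L, 2L), growth_rate = 3L,
                 dropout_rate = 0, ...)
}

random_minibatch <- function(n = 3, size = 16, seed = 21) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lv <- runif(4); lv <- lv / sum(lv)
    list(pixels = matrix(runif(size * size), size, size), label_vec = lv)
  })
}

# The desk-scale end-to-end run (4 x 200 images, 32x32, small arch) is
# expensive, so it is computed once and shared by the tests that assert
# on different aspects of it.
desk_run_cache <- new.env(parent = emptyenv())

desk_run_config <- function(seed = 42) {
  list(
    seed = seed,
    dataset = list(counts = list(graves = 200L, hashimoto = 200L,
                                 subacute = 200L, normal = 200L),
                   image_size = 32L),
    augmentation = list(target_per_class = 250L, train_per_class = 175L,
                        test_per_class = 75L),
    network = list(arch = "small"),
    training = list(batch_size = 5L, max_epochs = 3L, lr_init = 0.05,
                    early_stop_patience = 2L, validation_fraction = 0.1,
                    fpa = list(n_iterations = 3L, n_pollen = 6L)))
}

desk_run <- function() {
  if (is.null(desk_run_cache$run)) {
    dir <- file.path(tempdir(), "desk_run")
    desk_run_cache$run <- run_pipeline(desk_run_config(), run_dir = dir)
  }
  desk_run_cache$run
}
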