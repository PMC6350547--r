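#' Construct a labeled image
#'
#' A labeled image is the unit of raw data: a square grid of grayscale
#' intensities in [0, 1] plus a hard class label and a unique id.
#'
#' @param pixels Numeric matrix with values in [0, 1]; must be square.
#' @param label One of `spect_classes()`.
#' @param id Unique identifier string.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label, id) {
  assert_that(is.matrix(pixels) && is.numeric(pixels),
              "pixels must be a numeric matrix")
  assert_that(nrow(pixels) == ncol(pixels),
              "pixels must be square (H = W)")
  assert_that(all(is.finite(pixels)) && all(pixels >= 0) && all(pixels <= 1),
              "all intensities must be finite and within [0, 1]")
  check_labels(label)
  structure(list(pixels = pixels, label = label, id = as.character(id)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image %s: %dx%d, label=%s>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$label))
  invisible(x)
}

# Render one thyroid scintigram-like frame: two elliptical lobes either
# side of the midline joined by a faint isthmus, on a low background.
# Class-specific appearance:
#   normal    - moderate, fairly even tracer uptake in normal-sized lobes
#   graves    - enlarged gland with uniformly elevated uptake (diffuse
#               hyperfunction)
#   hashimoto - normal-sized gland with patchy, heterogeneous uptake
#   subacute  - strongly suppressed uptake (the gland barely rises above
#               background)
# Geometry/intensity parameters are drawn from seeded distributions so
# that every image differs while the class signal stays learnable.
render_thyroid <- function(size, label) {
  s <- size
  xs <- matrix(rep(seq_len(s), each = s), nrow = s)  # column index
  ys <- matrix(rep(seq_len(s), times = s), nrow = s) # row index
  cx <- s / 2 + stats::runif(1, -0.02, 0.02) * s
  cy <- s / 2 + stats::runif(1, -0.02, 0.02) * s

  # base lobe geometry in units of image size
  base_a <- 0.11 * s   # semi-axis across
  base_b <- 0.20 * s   # semi-axis along
  sep    <- 0.16 * s   # lobe offset from midline

  scale <- switch(label,
    graves    = stats::runif(1, 1.30, 1.50),
    stats::runif(1, 0.92, 1.08))
  level <- switch(label,
    normal    = stats::runif(1, 0.50, 0.60),
    graves    = stats::runif(1, 0.80, 0.92),
    hashimoto = stats::runif(1, 0.46, 0.56),
    subacute  = stats::runif(1, 0.12, 0.20))
  bg <- stats::runif(1, 0.03, 0.06)

  img <- matrix(bg, s, s)
  tilt <- stats::runif(1, -0.08, 0.08)
  for (side in c(-1, 1)) {
    lx <- cx + side * sep * scale
    ly <- cy + side * tilt * s
    a <- base_a * scale * stats::runif(1, 0.95, 1.05)
    b <- base_b * scale * stats::runif(1, 0.95, 1.05)
    d2 <- ((xs - lx) / a)^2 + ((ys - ly) / b)^2
    # soft-edged ellipse
    lobe <- level * clamp(1.25 - d2, 0, 1)
    img <- pmax(img, lobe)
  }
  # isthmus: faint horizontal bridge between the lobes
  isth <- 0.45 * level *
    clamp(1 - ((ys - cy) / (0.05 * s))^2, 0, 1) *
    clamp(1 - ((xs - cx) / (0.18 * s))^2, 0, 1)
  img <- pmax(img, isth)

  if (label == "hashimoto") {
    # multiplicative patchiness: a few cold and hot blobs inside the gland
    n_patch <- sample(4:7, 1)
    mask <- matrix(1, s, s)
    for (p in seq_len(n_patch)) {
      px <- stats::runif(1, cx - 1.6 * sep, cx + 1.6 * sep)
      py <- stats::runif(1, cy - base_b, cy + base_b)
      pr <- stats::runif(1, 0.04, 0.09) * s
      fac <- if (stats::runif(1) < 0.5) stats::runif(1, 0.35, 0.6)
             else stats::runif(1, 1.4, 1.7)
      pd2 <- ((xs - px)^2 + (ys - py)^2) / pr^2
      mask <- mask * (1 + (fac - 1) * clamp(1 - pd2, 0, 1))
    }
    img <- bg + (img - bg) * mask
  }

  img <- img + stats::rnorm(s * s, 0, 0.03)
  clamp(img, 0, 1)
}

#' Generate a synthetic labeled SPECT-like dataset
#'
#' Draws the requested number of images per class from distinct parametric
#' pattern families (see Details) so that a simple classifier can learn
#' the class signal. Generation is a pure function of
#' `(class_counts, image_size, seed)`.
#'
#' @details Each image shows a stylized anterior thyroid scintigram: two
#' elliptical lobes joined by an isthmus on a dark background, plus
#' additive Gaussian pixel noise. Classes differ in gland size and uptake:
#' normal lobes at moderate intensity, Graves' disease as an enlarged
#' gland with uniformly elevated uptake, Hashimoto disease as patchy
#' heterogeneous uptake, and subacute thyroiditis as strongly suppressed
#' uptake.
#'
#' @param class_counts Named integer vector/list mapping each class in
#'   `spect_classes()` to a count (>= 0). Missing classes default to 0.
#' @param image_size Side length in pixels (>= 16). Default 32; clinical
#'   scale 255 is available by configuration.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return List of `labeled_image`, grouped by class in the fixed class
#'   order.
#' @examples
#' d <- generate_dataset(c(graves = 2, hashimoto = 2, subacute = 2, normal = 2),
#'                       image_size = 32, seed = 1)
#' length(d)
#' @export
generate_dataset <- function(class_counts, image_size = 32, seed = 1) {
  class_counts <- unlist(class_counts)
  check_labels(names(class_counts), "class")
  assert_that(all(class_counts >= 0) && all(class_counts == floor(class_counts)),
              "all class counts must be non-negative integers")
  assert_that(image_size >= 16, "image_size must be >= 16")

  counts <- stats::setNames(rep(0L, 4), spect_classes())
  counts[names(class_counts)] <- as.integer(class_counts)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  out <- vector("list", sum(counts))
  k <- 0L
  for (cl in spect_classes()) {
    for (i in seq_len(counts[[cl]])) {
      k <- k + 1L
      out[[k]] <- labeled_image(render_thyroid(image_size, cl), cl,
                                sprintf("%s_%04d", cl, i))
    }
  }
  out
}

#' Tally a dataset's labels
#'
#' @param images List of `labeled_image` or of soft samples.
#' @return Named integer vector over `spect_classes()`.
#' @export
class_tally <- function(images) {
  labs <- vapply(images, function(im) {
    if (!is.null(im[["class_group"]])) im[["class_group"]]
    else if (!is.null(im[["label"]])) im[["label"]]
    else spect_classes()[which.max(im[["label_vec"]])]
  }, character(1))
  tab <- stats::setNames(rep(0L, 4), spect_classes())
  t0 <- table(factor(labs, levels = spect_classes()))
  tab[names(t0)] <- as.integer(t0)
  tab
}

#' Write a dataset to disk as PNG files plus a CSV manifest
#'
#' Images are written as 8-bit grayscale PNG; the manifest
#' (`manifest.csv`) has columns `filename,label,split`.
#'
#' @param images List of `labeled_image`.
#' @param out_dir Output directory (created if missing).
#' @param split Optional character vector of split tags (recycled);
#'   defaults to `"unsplit"`.
#' @return The manifest as a data.frame (invisibly also written to
#'   `out_dir/manifest.csv`), with attribute `class_counts`.
#' @export
write_dataset <- function(images, out_dir, split = "unsplit") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(images)
  split <- rep_len(split, if (n > 0) n else 0)
  fn <- character(n)
  labs <- character(n)
  for (i in seq_len(n)) {
    im <- images[[i]]
    fn[i] <- paste0(im$id, ".png")
    labs[i] <- im$label
    png::writePNG(im$pixels, file.path(out_dir, fn[i]))
  }
  manifest <- data.frame(filename = fn, label = labs,
                         split = as.character(split),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "class_counts") <- class_tally(images)
  manifest
}

#' Read a dataset back from a CSV manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_dataset()]; PNGs are resolved relative to its directory.
#' @return List of `labeled_image` in manifest order. Pixel values are
#'   reproduced within 8-bit quantization of the originals.
#' @export
read_dataset <- function(manifest_path) {
  assert_that(file.exists(manifest_path),
              sprintf("manifest not found: %s", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(base, man$filename[i])
    if (!file.exists(path)) {
      stop(sprintf("image file referenced by manifest is missing: %s", path),
           call. = FALSE)
    }
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    labeled_image(px, man$label[i], sub("\\.png$", "", man$filename[i]))
  })
}
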