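#' Thyroid classes in their fixed order
#'
#' The four diagnostic categories handled by the framework, in the fixed
#' order used for one-hot encoding, network outputs and confusion matrices:
#' Graves' disease, Hashimoto disease, subacute thyroiditis, normal.
#'
#' @return Character vector of length 4.
#' @export
spect_classes <- function() {
  c("graves", "hashimoto", "subacute", "normal")
}

# internal: validate a label vector against the fixed class set
check_labels <- function(labels, arg = "label") {
  bad <- setdiff(unique(labels), spect_classes())
  if (length(bad) > 0) {
    stop(sprintf("unknown %s: %s (expected one of %s)",
                 arg, paste(bad, collapse = ", "),
                 paste(spect_classes(), collapse = ", ")), call. = FALSE)
  }
  invisible(labels)
}

# internal: clamp numeric values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# internal: stopifnot with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
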