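# Perturbed-image distribution: binary segment masks, black-out composition,
# and batched classifier queries.

#' Classifier adapter
#'
#' Wraps any black-box classifier behind the one contract the explainer
#' needs: a deterministic function mapping a batch of 8-bit RGB images to
#' rows of class probabilities. Single-output (sigmoid) classifiers declare
#' `n_classes = 1`; their output `p` is expanded to `(1 - p, p)` so class 1
#' is always "the positive class".
#'
#' @param predict A function taking a list of images (each height x width x
#'   3, 0..255) and returning a numeric matrix with one row per image.
#' @param n_classes Number of columns `predict` returns (1 for a single
#'   sigmoid output, else >= 2).
#' @return An object of class `"classifier_adapter"`.
#' @examples
#' constant <- classifier_adapter(
#'   function(batch) matrix(c(0.3, 0.7), length(batch), 2, byrow = TRUE),
#'   n_classes = 2)
#' @export
classifier_adapter <- function(predict, n_classes = 2L) {
  if (!is.function(predict)) stop_invalid("predict must be a function")
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop_invalid("n_classes must be >= 1")
  structure(list(predict = predict, n_classes = n_classes),
            class = "classifier_adapter")
}

# Query the adapter on a batch and enforce its contract: non-negative rows
# summing to 1 (after sigmoid expansion).
#' @noRd
predict_proba <- function(classifier, batch) {
  if (!inherits(classifier, "classifier_adapter")) {
    stop_invalid("classifier must be a classifier_adapter")
  }
  p <- classifier$predict(batch)
  if (!is.matrix(p)) p <- matrix(p, nrow = length(batch))
  if (nrow(p) != length(batch) || ncol(p) != classifier$n_classes) {
    stop("adapter contract violated: expected ", length(batch), " x ",
         classifier$n_classes, " output, got ", nrow(p), " x ", ncol(p))
  }
  if (classifier$n_classes == 1L) p <- cbind(1 - p[, 1], p[, 1])
  if (anyNA(p) || min(p) < -1e-9 || max(abs(rowSums(p) - 1)) > 1e-6) {
    stop("adapter contract violated: rows must be non-negative ",
         "probabilities summing to 1")
  }
  unname(p)
}

#' Sample a binary segment-mask matrix
#'
#' Draws the perturbation design: an `n_samples` x `k` binary matrix whose
#' rows say which segments stay visible (1) and which are blacked out (0).
#' Row 1 is always all ones — the unperturbed instance — and the remaining
#' entries are i.i.d. Bernoulli(1/2) from the seeded generator, so the same
#' `(k, n_samples, seed)` always reproduces the same matrix. The default
#' distribution size used throughout is 10,000 samples, which brings
#' repeated-explanation weight variability down to the 1e-4..1e-3 range.
#'
#' @param k Number of segments (columns).
#' @param n_samples Number of perturbations (rows), including the
#'   unperturbed row.
#' @param seed Integer seed for the mask draw.
#' @return An integer 0/1 matrix of class `"mask_matrix"` with attribute
#'   `seed`.
#' @export
sample_masks <- function(k, n_samples, seed = 1L) {
  k <- as.integer(k); n_samples <- as.integer(n_samples)
  if (is.na(k) || k < 1L) stop_invalid("k must be a positive integer")
  if (is.na(n_samples) || n_samples < 1L) {
    stop_invalid("n_samples must be a positive integer")
  }
  m <- with_seed(seed, {
    matrix(sample(c(0L, 1L), (n_samples - 1L) * k, replace = TRUE),
           nrow = n_samples - 1L, ncol = k)
  })
  out <- rbind(matrix(1L, 1L, k), m)
  structure(out, seed = as.integer(seed), class = c("mask_matrix", "matrix"))
}

#' Black out hidden segments
#'
#' Composes one perturbed image: pixels in segments with mask 1 are copied
#' unchanged; pixels in segments with mask 0 are set to black `(0, 0, 0)`.
#' The input image is never modified.
#'
#' @param image An 8-bit RGB array.
#' @param segments A [segment_map()] matching the image dimensions.
#' @param mask_row Binary vector of length `segments$k`.
#' @return The perturbed image (same dimensions and scale as the input).
#' @export
apply_mask <- function(image, segments, mask_row) {
  check_image(image)
  if (!inherits(segments, "segment_map")) {
    stop_invalid("segments must be a segment_map")
  }
  if (!identical(dim(segments$labels), dim(image)[1:2])) {
    stop_shape("segment map dimensions do not match the image")
  }
  if (length(mask_row) != segments$k) {
    stop_shape("mask_row length ", length(mask_row),
               " does not match k = ", segments$k)
  }
  keep <- mask_row[as.integer(segments$labels) + 1L] != 0
  out <- image
  out[which(!keep)] <- 0L                 # recycles across the 3 channels
  out[which(!keep) + length(keep)] <- 0L
  out[which(!keep) + 2L * length(keep)] <- 0L
  out
}

#' Classifier probabilities over the perturbed distribution
#'
#' Composes each mask row into a perturbed image, queries the classifier in
#' batches, and stacks the probability rows. Batching is a memory knob only:
#' results are identical for any `batch_size`.
#'
#' @param image An 8-bit RGB array.
#' @param segments A [segment_map()].
#' @param masks A [sample_masks()] matrix (or any N x k binary matrix).
#' @param classifier A [classifier_adapter()].
#' @param batch_size Images per classifier call.
#' @return An N x C matrix of class probabilities.
#' @export
predict_perturbations <- function(image, segments, masks, classifier,
                                  batch_size = 256L) {
  check_image(image)
  if (ncol(masks) != segments$k) {
    stop_shape("mask matrix has ", ncol(masks), " columns for k = ",
               segments$k)
  }
  n <- nrow(masks)
  starts <- seq(1L, n, by = batch_size)
  out <- NULL
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- lapply(idx, function(i) apply_mask(image, segments, masks[i, ]))
    p <- predict_proba(classifier, batch)
    if (is.null(out)) out <- matrix(NA_real_, n, ncol(p))
    out[idx, ] <- p
  }
  out
}
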