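# Shared fixtures: deterministic images, mock classifiers, and the
# stability-study setup. Everything is generated in code at test time.

# A deterministic non-constant RGB image (smooth gradients), 0..255.
gradient_image <- function(h = 24, w = 24) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- array(0L, dim = c(h, w, 3))
  img[, , 1] <- as.integer(round(255 * r / h))
  img[, , 2] <- as.integer(round(255 * c / w))
  img[, , 3] <- as.integer(round(255 * (r + c) / (h + w)))
  img
}

# Classifier that always returns the same probability row.
constant_classifier <- function(probs = c(0.3, 0.7)) {
  classifier_adapter(function(batch) {
    matrix(probs, nrow = length(batch), ncol = length(probs), byrow = TRUE)
  }, n_classes = length(probs))
}

# The stability study conditions: a fixed class-1 synthetic patch, a fixed
# ~30-segment square-grid segmentation (6 x 6 = 36), and a deterministic
# smooth near-linear classifier with a few informative segments.
stability_setup <- function(patch_seed = 1, coef_seed = 42) {
  patch <- generate_patch(1, synth_params(seed = patch_seed))
  segments <- squaregrid_segments(96, 96, 36)
  coefficients <- gridlime:::with_seed(coef_seed, {
    cf <- stats::runif(36, -0.003, 0.006)
    cf[c(8, 15, 22)] <- c(0.18, 0.15, 0.12)
    cf
  })
  classifier <- smooth_mock_classifier(patch$image, segments, coefficients,
                                       intercept = 0.2, amplitude = 0.01)
  list(image = patch$image, annotation = patch$annotation,
       segments = segments, coefficients = coefficients,
       intercept = 0.2, classifier = classifier)
}

# Independent normal-equations oracle for ordinary least squares.
ols_oracle <- function(masks, targets) {
  X <- cbind(1, as.matrix(masks))
  beta <- solve(crossprod(X), crossprod(X, targets))
  list(intercept = beta[1], weights = beta[-1])
}

# All 2^k binary mask rows (full enumeration), row 1 all ones.
enumerate_masks <- function(k) {
  grid <- as.matrix(expand.grid(rep(list(c(1L, 0L)), k)))
  dimnames(grid) <- NULL
  structure(grid, seed = NA_integer_, class = c("mask_matrix", "matrix"))
}
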