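# The interpretable surrogate: (weighted) least squares of class
# probabilities on the binary segment masks.

#' Fit the linear surrogate
#'
#' Ordinary (or, when `sample_weights` are given, weighted) least squares of
#' the targets on the binary mask columns plus an intercept. The fitted
#' coefficients are the explanation: weight `w_j` is the modelled change in
#' the target when segment `j` is visible rather than blacked out. The fit
#' is the exact minimizer (QR factorization); no regularization or feature
#' selection is applied, so a target that is exactly affine in the mask bits
#' is recovered to machine precision whenever the design has full column
#' rank.
#'
#' @param masks An N x k binary matrix (see [sample_masks()]).
#' @param targets Numeric vector of length N (one probability per row).
#' @param sample_weights Optional non-negative vector of length N.
#' @return A list with `weights` (length k), `intercept`, and `fit_score`
#'   (coefficient of determination on the fitting set; defined as 1 when the
#'   residuals are identically zero).
#' @export
fit_surrogate <- function(masks, targets, sample_weights = NULL) {
  masks <- as.matrix(masks)
  storage.mode(masks) <- "double"
  n <- nrow(masks); k <- ncol(masks)
  if (length(targets) != n) {
    stop_shape("targets length ", length(targets), " does not match ",
               n, " mask rows")
  }
  if (n < k + 1L) {
    stop_invalid("need at least k + 1 = ", k + 1L, " samples, got ", n)
  }
  if (!is.null(sample_weights)) {
    if (length(sample_weights) != n) {
      stop_shape("sample_weights length does not match mask rows")
    }
    if (anyNA(sample_weights) || min(sample_weights) < 0) {
      stop_invalid("sample_weights must be non-negative")
    }
  }
  X <- cbind(`(intercept)` = 1, masks)
  qrX <- qr(if (is.null(sample_weights)) X else X * sqrt(sample_weights))
  if (qrX$rank < ncol(X)) {
    bad <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    stop("singular design: collinear mask columns ",
         paste(bad - 1L, collapse = ", "),
         " (segment indices, 0-based; -1 denotes the intercept)")
  }
  fit <- if (is.null(sample_weights)) {
    stats::lm.fit(X, targets)
  } else {
    stats::lm.wfit(X, targets, w = sample_weights)
  }
  coefs <- fit$coefficients
  w <- if (is.null(sample_weights)) rep(1, n) else sample_weights
  fitted <- drop(X %*% coefs)
  rss <- sum(w * (targets - fitted)^2)
  ybar <- sum(w * targets) / sum(w)
  tss <- sum(w * (targets - ybar)^2)
  fit_score <- if (rss <= 1e-24 || tss == 0) 1 else max(0, 1 - rss / tss)
  list(weights = unname(coefs[-1L]), intercept = unname(coefs[1L]),
       fit_score = fit_score)
}

#' Proximity kernel weights over mask rows
#'
#' The exponential kernel used by the reference LIME implementation, offered
#' for comparability: each perturbation is weighted by
#' `exp(-d^2 / kernel_width^2)` where `d` is the cosine distance between its
#' mask row and the all-ones (unperturbed) row. The default surrogate is
#' unweighted plain regression; enable the kernel through
#' [explanation_for_class()].
#'
#' @param masks An N x k binary matrix.
#' @param kernel_width Positive kernel width (reference default 0.25).
#' @return Non-negative numeric vector of length N.
#' @export
proximity_weights <- function(masks, kernel_width = 0.25) {
  if (kernel_width <= 0) stop_invalid("kernel_width must be > 0")
  masks <- as.matrix(masks)
  k <- ncol(masks)
  m <- rowSums(masks != 0)
  # cosine distance to the all-ones row: 1 - sqrt(m / k); all-zero rows are
  # at distance 1 by convention
  d <- ifelse(m == 0, 1, 1 - sqrt(m / k))
  exp(-d^2 / kernel_width^2)
}

#' Surrogate explanation for one class
#'
#' Fits the linear surrogate on the probability column of the requested
#' class (optionally with proximity-kernel sample weights) and packages the
#' result. For a two-class classifier whose rows sum to one, the weights for
#' class 0 are exactly the negation of the weights for class 1.
#'
#' @param masks A [sample_masks()] matrix.
#' @param probabilities N x C probability matrix (see
#'   [predict_perturbations()]).
#' @param class_index Class to explain, 0-based (matching the classifier's
#'   column order).
#' @param use_kernel Apply [proximity_weights()]? Default off: the surrogate
#'   is plain regression.
#' @param kernel_width Kernel width when `use_kernel` is on.
#' @return An object of class `"lime_explanation"`; see [explain()] for the
#'   methods it supports.
#' @export
explanation_for_class <- function(masks, probabilities, class_index = 1L,
                                  use_kernel = FALSE, kernel_width = 0.25) {
  probabilities <- as.matrix(probabilities)
  if (class_index < 0 || class_index >= ncol(probabilities)) {
    stop_invalid("class_index must be in 0..", ncol(probabilities) - 1L)
  }
  sw <- if (use_kernel) proximity_weights(masks, kernel_width) else NULL
  fit <- fit_surrogate(masks, probabilities[, class_index + 1L],
                       sample_weights = sw)
  new_lime_explanation(
    weights = fit$weights, intercept = fit$intercept,
    fit_score = fit$fit_score, class_index = as.integer(class_index),
    n_samples = nrow(masks), seed = attr(masks, "seed") %||% NA_integer_,
    use_kernel = use_kernel)
}
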