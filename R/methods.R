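# S3 methods for fitted explanation objects.

#' @export
print.lime_explanation <- function(x, ...) {
  cat("Local linear surrogate explanation\n")
  cat(sprintf("  class explained : %d\n", x$class_index))
  cat(sprintf("  segments (k)    : %d\n", length(x$weights)))
  cat(sprintf("  samples / seed  : %d / %s\n", x$n_samples,
              format(x$seed)))
  cat(sprintf("  intercept       : %.5f\n", x$intercept))
  cat(sprintf("  fit score (R^2) : %.5f\n", x$fit_score))
  top <- order(abs(x$weights), decreasing = TRUE)[seq_len(min(5, length(x$weights)))]
  cat("  largest |weights| (segment: weight):\n")
  cat(sprintf("    %d: %+.5f\n", top - 1L, x$weights[top]), sep = "")
  invisible(x)
}

#' @export
summary.lime_explanation <- function(object, ...) {
  w <- object$weights
  structure(list(
    class_index = object$class_index,
    k = length(w),
    n_samples = object$n_samples,
    seed = object$seed,
    intercept = object$intercept,
    fit_score = object$fit_score,
    weight_range = range(w),
    weight_table = data.frame(segment = seq_along(w) - 1L, weight = w)
  ), class = "summary.lime_explanation")
}

#' @export
print.summary.lime_explanation <- function(x, ...) {
  cat(sprintf("Surrogate explanation for class %d: k = %d, n = %d, R^2 = %.5f\n",
              x$class_index, x$k, x$n_samples, x$fit_score))
  cat(sprintf("Weights in [%.5f, %.5f], intercept %.5f\n",
              x$weight_range[1], x$weight_range[2], x$intercept))
  tab <- x$weight_table[order(-abs(x$weight_table$weight)), ]
  print(utils::head(tab, 10), row.names = FALSE)
  invisible(x)
}

#' Surrogate coefficients
#'
#' @param object A `"lime_explanation"`.
#' @param ... Unused.
#' @return Named vector: the intercept followed by one weight per segment
#'   (`seg0`, `seg1`, ...).
#' @export
coef.lime_explanation <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights),
                  c("(intercept)", paste0("seg", seq_along(object$weights) - 1L)))
}

#' Surrogate predictions for segment-visibility patterns
#'
#' Evaluates the fitted linear surrogate `intercept + masks %*% weights` on
#' binary mask rows — the surrogate's approximation of the classifier's
#' probability for the explained class.
#'
#' @param object A `"lime_explanation"`.
#' @param masks Binary matrix (or vector) with one column per segment.
#'   Default: the mask matrix the explanation was fitted on (if retained).
#' @param ... Unused.
#' @return Numeric vector of surrogate probabilities.
#' @export
predict.lime_explanation <- function(object, masks = object$masks, ...) {
  if (is.null(masks)) stop_invalid("masks must be supplied")
  if (is.null(dim(masks))) masks <- matrix(masks, nrow = 1L)
  if (ncol(masks) != length(object$weights)) {
    stop_shape("masks must have one column per segment")
  }
  drop(object$intercept + as.matrix(masks) %*% object$weights)
}

#' @export
fitted.lime_explanation <- function(object, ...) {
  if (is.null(object$masks)) stop_invalid("fitting masks were not retained")
  predict(object, object$masks)
}

#' @export
residuals.lime_explanation <- function(object, ...) {
  if (is.null(object$masks) || is.null(object$probabilities)) {
    stop_invalid("fitting data were not retained")
  }
  object$probabilities[, object$class_index + 1L] - fitted(object)
}

#' @rdname render_heatmap
#' @export
plot.lime_explanation <- function(x, spec = render_spec(1), ...) {
  if (is.null(x$heatmap)) stop_invalid("this explanation carries no heat map")
  show_raster(render_heatmap(x$heatmap, spec),
              main = sprintf("class %d (%s)", x$class_index,
                             x$heatmap$provenance))
}

#' @export
print.squaregrid_explanation <- function(x, ...) {
  cat("Square-grid multi-scale explanation\n")
  cat(sprintf("  class explained : %d\n", x$class_index))
  cat(sprintf("  levels          : %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  samples / seed  : %d / %d\n", x$n_samples, x$seed))
  cat(sprintf("  summed map range: [%.4g, %.4g]\n",
              min(x$heatmap$values), max(x$heatmap$values)))
  invisible(x)
}

#' @rdname render_heatmap
#' @export
plot.squaregrid_explanation <- function(x, spec = render_spec(1), ...) {
  show_raster(render_heatmap(x$heatmap, spec), main = "squaregrid-sum")
}

#' @export
coef.squaregrid_explanation <- function(object, ...) {
  lapply(object$level_explanations, coef)
}
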