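# Internal helpers shared across modules.

#' @noRd
stop_invalid <- function(...) {
  stop(structure(
    class = c("gridlime_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
stop_shape <- function(...) {
  stop(structure(
    class = c("gridlime_shape_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a locally seeded RNG, restoring (or removing) the
# caller's .Random.seed afterwards.  Keeps all randomness explicit: nothing in
# the package touches the global generator state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("seed must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Validate an 8-bit RGB image array (height x width x 3, values 0..255).
#' @noRd
check_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_shape(arg, " must be a height x width x 3 array")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop_invalid(arg, " must contain values in [0, 255]")
  }
  invisible(image)
}

# Round half away from zero, so rendered channel values and grid edges do not
# depend on R's round-half-to-even rule.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
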