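# Synthetic histology-like patches and deterministic mock classifiers, so
# the whole explanation pipeline is testable without any dataset download.

#' Parameters of the synthetic patch generator
#'
#' The generator emulates the visual contrasts that drive explanations of
#' H&E tumor patches: a pink-ish textured background, many small dark-purple
#' round nuclei (normal tissue), and — on tumor patches — a cluster of
#' enlarged, irregularly shaped, lighter-purple nuclei whose union is the
#' annotation mask. It makes no claim of histological realism; it reproduces
#' the size / shape-regularity / lightness contrasts the surrogate keys on.
#'
#' @param height,width Patch dimensions in pixels (canonical 96).
#' @param n_normal_nuclei Count of small round normal nuclei.
#' @param normal_radius Radius of normal nuclei in pixels (near-constant).
#' @param tumor_blob_count Number of enlarged tumor nuclei in the cluster.
#' @param tumor_radius_range Length-2 range of tumor nucleus radii; must lie
#'   strictly above `normal_radius` (enlarged nuclei).
#' @param noise_sd Standard deviation of the background texture noise
#'   (8-bit channel units).
#' @param seed Integer seed; the patch is a pure function of the parameters.
#' @return An object of class `"synth_params"`.
#' @export
synth_params <- function(height = 96L, width = 96L,
                         n_normal_nuclei = 60L, normal_radius = 3,
                         tumor_blob_count = 5L,
                         tumor_radius_range = c(7, 12),
                         noise_sd = 6, seed = 1L) {
  if (height < 1L || width < 1L) stop_invalid("patch dimensions must be >= 1")
  if (length(tumor_radius_range) != 2L ||
      tumor_radius_range[1] > tumor_radius_range[2]) {
    stop_invalid("tumor_radius_range must be a non-decreasing length-2 range")
  }
  if (tumor_radius_range[1] <= normal_radius) {
    stop_invalid("tumor radii must be strictly larger than normal_radius")
  }
  if (2 * max(tumor_radius_range) > min(height, width)) {
    stop_invalid("tumor radius too large for the patch dimensions")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_normal_nuclei = as.integer(n_normal_nuclei),
                 normal_radius = normal_radius,
                 tumor_blob_count = as.integer(tumor_blob_count),
                 tumor_radius_range = tumor_radius_range,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 bg_color = c(230, 180, 200),
                 normal_color = c(90, 40, 110),
                 tumor_color = c(170, 120, 180)),
            class = "synth_params")
}

# 1-based bounds (rows, cols) of the centered 32x32 labelling window.
#' @noRd
central_window <- function(height, width) {
  if (height < 32L || width < 32L) {
    stop_invalid("mask must be at least 32 x 32 to apply the central ",
                 "labelling rule")
  }
  r0 <- floor((height - 32L) / 2)
  c0 <- floor((width - 32L) / 2)
  list(rows = (r0 + 1L):(r0 + 32L), cols = (c0 + 1L):(c0 + 32L))
}

#' Class label implied by an annotation mask
#'
#' The Patch Camelyon labelling rule: a patch is class 1 iff at least one
#' annotated (tumor) pixel falls inside the centered 32x32 window; annotated
#' tissue outside that window does not influence the label. For a 96x96
#' mask the window is rows/columns 32..63 (0-based).
#'
#' @param annotation Binary matrix (nonzero = tumor tissue), at least 32x32.
#' @return `0L` or `1L`.
#' @export
label_from_annotation <- function(annotation) {
  if (!is.matrix(annotation)) stop_shape("annotation must be a matrix")
  win <- central_window(nrow(annotation), ncol(annotation))
  as.integer(any(annotation[win$rows, win$cols] != 0))
}

# Paint a filled disc with an optionally sinusoidally perturbed boundary.
#' @noRd
blob_mask <- function(height, width, center, radius, wobble = NULL) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  dr <- rows - center[1]; dc <- cols - center[2]
  dist <- sqrt(dr^2 + dc^2)
  if (is.null(wobble)) return(dist <= radius)
  theta <- atan2(dr, dc)
  r_theta <- radius * (1 + wobble$amp1 * sin(wobble$k1 * theta + wobble$ph1) +
                           wobble$amp2 * sin(wobble$k2 * theta + wobble$ph2))
  dist <= pmax(r_theta, 1)
}

#' Generate a synthetic tumor/normal patch with its annotation
#'
#' Deterministically (in `params$seed`) renders a patch of the requested
#' class. Class 0: textured background plus small round dark nuclei, empty
#' annotation. Class 1: additionally a cluster of enlarged irregular paler
#' blobs; their union is the annotation, and the cluster is seeded inside
#' the central 32x32 window so [label_from_annotation()] always returns 1.
#'
#' @param target_class `0` or `1`.
#' @param params A [synth_params()].
#' @return A list of class `"synthetic_patch"`: `image` (integer RGB array),
#'   `annotation` (binary matrix) and `label`.
#' @export
generate_patch <- function(target_class, params = synth_params()) {
  if (!target_class %in% c(0L, 1L)) stop_invalid("target_class must be 0 or 1")
  h <- params$height; w <- params$width
  with_seed(params$seed + 1000003L * target_class, {
    img <- array(0, dim = c(h, w, 3))
    for (c in 1:3) {
      img[, , c] <- params$bg_color[c] + stats::rnorm(h * w, 0, params$noise_sd)
    }
    # small, round, dark-purple normal nuclei scattered everywhere
    for (i in seq_len(params$n_normal_nuclei)) {
      ctr <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      rad <- params$normal_radius * stats::runif(1, 0.9, 1.1)
      m <- blob_mask(h, w, ctr, rad)
      jit <- stats::runif(3, -12, 12)
      for (c in 1:3) {
        plane <- img[, , c]
        plane[m] <- params$normal_color[c] + jit[c]
        img[, , c] <- plane
      }
    }
    annotation <- matrix(0L, h, w)
    if (target_class == 1L) {
      win <- central_window(h, w)
      # enlarged, irregular, lighter-purple tumor nuclei clustered so the
      # annotation always touches the central window
      anchor <- c(stats::runif(1, min(win$rows) + 4, max(win$rows) - 4),
                  stats::runif(1, min(win$cols) + 4, max(win$cols) - 4))
      for (i in seq_len(params$tumor_blob_count)) {
        ctr <- if (i == 1L) anchor else
          pmin(pmax(anchor + stats::runif(2, -20, 20), 1), c(h, w))
        rad <- stats::runif(1, params$tumor_radius_range[1],
                            params$tumor_radius_range[2])
        wob <- list(amp1 = stats::runif(1, 0.1, 0.3), k1 = sample(2:4, 1),
                    ph1 = stats::runif(1, 0, 2 * pi),
                    amp2 = stats::runif(1, 0.05, 0.2), k2 = sample(5:7, 1),
                    ph2 = stats::runif(1, 0, 2 * pi))
        m <- blob_mask(h, w, ctr, rad, wob)
        jit <- stats::runif(3, -15, 15)
        for (c in 1:3) {
          plane <- img[, , c]
          plane[m] <- params$tumor_color[c] + jit[c]
          img[, , c] <- plane
        }
        annotation[m] <- 1L
      }
    }
    img <- round_half_up(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    structure(list(image = img, annotation = annotation,
                   label = label_from_annotation(annotation)),
              class = "synthetic_patch")
  })
}

#' @export
print.synthetic_patch <- function(x, ...) {
  cat(sprintf("Synthetic patch: %d x %d, label %d, %d annotated pixels\n",
              nrow(x$annotation), ncol(x$annotation), x$label,
              sum(x$annotation)))
  invisible(x)
}

# Which segments of `image` are fully intact relative to `reference`?
# Returns a logical vector of length k.
#' @noRd
segment_presence <- function(image, reference, segments) {
  pixdiff <- (image[, , 1] != reference[, , 1]) |
             (image[, , 2] != reference[, , 2]) |
             (image[, , 3] != reference[, , 3])
  ndiff <- tabulate(as.integer(segments$labels)[pixdiff] + 1L,
                    nbins = segments$k)
  ndiff == 0L
}

#' @noRd
check_affine_range <- function(intercept, coefficients, slack = 0) {
  lo <- intercept + sum(pmin(coefficients, 0)) - slack
  hi <- intercept + sum(pmax(coefficients, 0)) + slack
  if (lo < 0 || hi > 1) {
    stop_invalid("classifier outputs would leave [0, 1] on the mask cube ",
                 sprintf("(range [%.4g, %.4g])", lo, hi))
  }
}

#' Linear mock classifier (exact-recovery oracle)
#'
#' A deterministic classifier whose class-1 probability is exactly affine in
#' segment visibility: `p1 = intercept + sum_j c_j * [segment j intact]`,
#' with presence detected by exact pixel comparison against the reference
#' image. Because the surrogate fits precisely this functional form, the
#' explanation pipeline must recover `(intercept, coefficients)` to machine
#' precision — the package's strongest internal correctness check.
#'
#' @param image The reference (unperturbed) 8-bit RGB image.
#' @param segments The [segment_map()] the coefficients refer to.
#' @param coefficients Numeric vector of length `segments$k`.
#' @param intercept Baseline probability.
#' @return A [classifier_adapter()] with two softmax-style outputs.
#' @export
linear_mock_classifier <- function(image, segments, coefficients, intercept) {
  check_image(image)
  if (length(coefficients) != segments$k) {
    stop_invalid("coefficients length ", length(coefficients),
                 " does not match k = ", segments$k)
  }
  check_affine_range(intercept, coefficients)
  force(image); force(segments)
  classifier_adapter(function(batch) {
    p1 <- vapply(batch, function(im) {
      present <- segment_presence(im, image, segments)
      intercept + sum(coefficients[present])
    }, numeric(1))
    cbind(1 - p1, p1, deparse.level = 0)
  }, n_classes = 2L)
}

#' Smooth near-linear mock classifier
#'
#' A deterministic classifier that is affine in segment visibility plus a
#' small smooth nonlinearity: `p1 = s + amplitude * sin(2 * pi * s)` with
#' `s = intercept + sum_j c_j * [segment j intact]`. The nonlinear part is
#' what a linear surrogate cannot represent, so it sets the scale of the
#' surrogate's residuals — making this the natural test bed for the
#' reproducibility (stability) of explanation weights across repeated runs.
#'
#' @inheritParams linear_mock_classifier
#' @param amplitude Size of the nonlinearity (default 0.01, small against
#'   informative weights).
#' @return A [classifier_adapter()] with two outputs.
#' @export
smooth_mock_classifier <- function(image, segments, coefficients, intercept,
                                   amplitude = 0.01) {
  check_image(image)
  if (length(coefficients) != segments$k) {
    stop_invalid("coefficients length does not match k")
  }
  check_affine_range(intercept, coefficients, slack = abs(amplitude))
  force(image); force(segments)
  classifier_adapter(function(batch) {
    p1 <- vapply(batch, function(im) {
      present <- segment_presence(im, image, segments)
      s <- intercept + sum(coefficients[present])
      s + amplitude * sin(2 * pi * s)
    }, numeric(1))
    cbind(1 - p1, p1, deparse.level = 0)
  }, n_classes = 2L)
}

#' Tumor-detector mock classifier
#'
#' A smooth deterministic stand-in for a patch classifier that has learned
#' the labelling rule: its tumor probability depends only on how much
#' annotated tissue is visible (not blacked out) inside the central 32x32
#' window: `p1 = logistic(steepness * (visible / 1024 - 1/2))`. Hiding a
#' segment disjoint from the annotation leaves the output unchanged, so
#' explanations against this classifier must localize on the annotation.
#'
#' @param reference_annotation Binary annotation matrix of the patch being
#'   explained.
#' @param steepness Positive logistic slope.
#' @return A [classifier_adapter()] with a single sigmoid output
#'   (`n_classes = 1`), expanded to `(1 - p, p)` by the adapter contract.
#' @export
tumor_detector_classifier <- function(reference_annotation, steepness = 8) {
  if (steepness <= 0) stop_invalid("steepness must be > 0")
  win <- central_window(nrow(reference_annotation), ncol(reference_annotation))
  ann_central <- reference_annotation[win$rows, win$cols] != 0
  classifier_adapter(function(batch) {
    p1 <- vapply(batch, function(im) {
      sub <- im[win$rows, win$cols, , drop = FALSE]
      visible <- (sub[, , 1] != 0) | (sub[, , 2] != 0) | (sub[, , 3] != 0)
      n_vis <- sum(ann_central & visible)
      stats::plogis(steepness * (n_vis / 1024 - 0.5))
    }, numeric(1))
    matrix(p1, ncol = 1)
  }, n_classes = 1L)
}
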