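# Segmentation: squaregrid decomposition, a uniform contract over the three
# classical superpixel algorithms, and cross-algorithm segment-count matching.

#' Segment map
#'
#' A segment map partitions an image into `k` segments: an integer label
#' raster (labels `0..k-1`, every label present) with the image's dimensions.
#' Labels are the atomic units of explanation: perturbations hide whole
#' segments and surrogate weights are per-segment.
#'
#' @param labels Integer matrix (height x width) of segment labels in
#'   `0..k-1`.
#' @param k Number of segments. Defaults to `max(labels) + 1`.
#' @return An object of class `"segment_map"` with elements `labels`
#'   (integer matrix) and `k`.
#' @examples
#' sm <- squaregrid_segments(96, 96, 9)
#' sm$k
#' @export
segment_map <- function(labels, k = max(labels) + 1L) {
  if (!is.matrix(labels)) stop_shape("labels must be a matrix")
  storage.mode(labels) <- "integer"
  k <- as.integer(k)
  if (k < 1L) stop_invalid("k must be >= 1")
  u <- sort(unique(as.integer(labels)))
  if (!identical(u, 0:(k - 1L))) {
    stop_invalid("labels must use every value in 0..k-1 exactly; found ",
                 length(u), " distinct labels for k = ", k)
  }
  structure(list(labels = labels, k = k), class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("Segment map: %d x %d pixels, %d segments\n",
              nrow(x$labels), ncol(x$labels), x$k))
  invisible(x)
}

#' Sizes of each segment, in pixels
#'
#' @param segments A [segment_map()].
#' @return Integer vector of length `k`; element `j + 1` is the pixel count
#'   of segment `j`.
#' @export
segment_sizes <- function(segments) {
  tabulate(as.integer(segments$labels) + 1L, nbins = segments$k)
}

#' Square-grid levels used by the multi-scale explainer
#'
#' The seven grid sizes of the square-grid attribution scheme, from the
#' coarsest (9 squares) to the finest (576 squares). On a canonical 96x96
#' patch every level divides the image evenly.
#'
#' @return `c(9, 16, 36, 64, 144, 256, 576)`.
#' @seealso [squaregrid_segments()], [squaregrid_explain()]
#' @export
default_levels <- function() c(9L, 16L, 36L, 64L, 144L, 256L, 576L)

#' Partition an image frame into a regular grid of squares
#'
#' Divides a `height` x `width` frame into `r` x `r` rectangular blocks
#' (`n_squares = r^2`), labelled `0..n_squares-1` in row-major order
#' (reading order: left to right, top to bottom). When a dimension is
#' divisible by `r` all blocks along it have identical size; otherwise block
#' edges fall at `round(i * dim / r)` so block sizes differ by at most one
#' pixel. The decomposition depends only on the frame size, never on image
#' content.
#'
#' @param height,width Frame dimensions in pixels.
#' @param n_squares Number of blocks; must be a perfect square `r^2` with
#'   `r <= min(height, width)`.
#' @return A [segment_map()].
#' @examples
#' sm <- squaregrid_segments(96, 96, 9)   # 3x3 blocks of exactly 32x32
#' table(sm$labels)
#' @export
squaregrid_segments <- function(height, width, n_squares) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop_invalid("height and width must be >= 1")
  r <- sqrt(as.numeric(n_squares))
  if (length(n_squares) != 1L || is.na(r) || r != floor(r)) {
    stop_invalid("n_squares must be a perfect square; got ", n_squares)
  }
  r <- as.integer(r)
  if (r > min(height, width)) {
    stop_invalid("grid side ", r, " exceeds the smallest image dimension ",
                 min(height, width))
  }
  # half-up rounding keeps edges deterministic when i*dim/r lands on .5
  row_edges <- round_half_up((0:r) * height / r)
  col_edges <- round_half_up((0:r) * width / r)
  row_idx <- rep(0:(r - 1L), times = diff(row_edges))  # grid row per pixel row
  col_idx <- rep(0:(r - 1L), times = diff(col_edges))
  labels <- outer(row_idx, col_idx, function(i, j) i * r + j)
  segment_map(matrix(as.integer(labels), height, width), n_squares)
}

#' Segmentation parameters
#'
#' A parameter bundle for [segment_image()]. Only the fields relevant to
#' `algorithm` are consulted. All three superpixel algorithms share the
#' Gaussian pre-smoothing width `sigma`, default 0.8 (the Felzenszwalb
#' library default, applied uniformly for comparability).
#'
#' @param algorithm One of `"fha"` (Felzenszwalb graph-based), `"slic"`,
#'   `"quickshift"`, or `"squaregrid"`.
#' @param sigma Gaussian pre-smoothing width (all algorithms), default 0.8.
#' @param scale Felzenszwalb observation level (larger gives fewer, larger
#'   segments).
#' @param n_segments Approximate segment count requested from SLIC.
#' @param kernel_size,max_dist,ratio Quickshift parameters: density kernel
#'   size, maximum clustering distance, and the color/space trade-off. The
#'   defaults (5, 10, 0.5) land typical 96x96 patches in the 20-40 segment
#'   range.
#' @param n_squares Square count for `"squaregrid"` (a perfect square).
#' @return An object of class `"segmenter_params"`.
#' @export
segmenter_params <- function(algorithm,
                             sigma = 0.8,
                             scale = 400,
                             n_segments = 30,
                             kernel_size = 5,
                             max_dist = 10,
                             ratio = 0.5,
                             n_squares = 36) {
  algorithm <- match.arg(algorithm, c("fha", "slic", "quickshift", "squaregrid"))
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  if (scale <= 0) stop_invalid("scale must be > 0")
  if (n_segments < 1) stop_invalid("n_segments must be >= 1")
  structure(list(algorithm = algorithm, sigma = sigma, scale = scale,
                 n_segments = as.integer(n_segments),
                 kernel_size = kernel_size, max_dist = max_dist,
                 ratio = ratio, n_squares = as.integer(n_squares)),
            class = "segmenter_params")
}

#' @export
print.segmenter_params <- function(x, ...) {
  extra <- switch(x$algorithm,
    fha        = sprintf("scale = %g", x$scale),
    slic       = sprintf("n_segments = %d", x$n_segments),
    quickshift = sprintf("kernel_size = %g, max_dist = %g, ratio = %g",
                         x$kernel_size, x$max_dist, x$ratio),
    squaregrid = sprintf("n_squares = %d", x$n_squares))
  cat(sprintf("Segmenter: %s (sigma = %g, %s)\n", x$algorithm, x$sigma, extra))
  invisible(x)
}

# Renumber arbitrary backend labels to a contiguous 0..k-1 range, ordered by
# first occurrence in row-major (reading-order) scan.  Preserves the
# partition: two pixels share a label afterwards iff they did before.
#' @noRd
relabel_contiguous <- function(labels) {
  reading <- as.integer(t(labels))            # row-major scan order
  first <- reading[!duplicated(reading)]      # labels by first occurrence
  lut <- integer(max(reading) - min(reading) + 1L)
  lut[first - min(reading) + 1L] <- seq_along(first) - 1L
  out <- matrix(lut[as.integer(labels) - min(reading) + 1L],
                nrow(labels), ncol(labels))
  segment_map(out, length(first))
}

#' Segment an image
#'
#' Uniform contract over the segmentation backends: returns a
#' [segment_map()] whose labels are always renumbered to a contiguous
#' `0..k-1` range in row-major first-occurrence order, regardless of what the
#' backend produced. `"squaregrid"` is computed natively (and ignores image
#' content); `"fha"`, `"slic"` and `"quickshift"` are delegated to
#' scikit-image through a bundled Python helper (see
#' [skimage_available()]).
#'
#' @param image An 8-bit RGB array (height x width x 3, values 0..255).
#' @param params A [segmenter_params()].
#' @return A [segment_map()].
#' @export
segment_image <- function(image, params) {
  check_image(image)
  if (!inherits(params, "segmenter_params")) {
    stop_invalid("params must be a segmenter_params object")
  }
  if (params$algorithm == "squaregrid") {
    return(squaregrid_segments(dim(image)[1], dim(image)[2], params$n_squares))
  }
  raw <- skimage_segment(image, params)
  relabel_contiguous(raw)
}

# Monotone bisection for a integer-valued count as a function of one
# parameter; falls back to a grid scan when the count is not monotone over
# the bracket.  `eval_count` is memoised by the caller.
#' @noRd
bisect_count <- function(eval_count, lo, hi, target, decreasing,
                         integer_param, max_iter = 30L, scan_points = 33L,
                         eval_batch = NULL) {
  sgn <- if (decreasing) -1 else 1
  k_lo <- eval_count(lo); k_hi <- eval_count(hi)
  best <- if (abs(k_lo - target) <= abs(k_hi - target)) {
    list(param = lo, count = k_lo)
  } else list(param = hi, count = k_hi)
  if (k_lo == target) return(list(param = lo, count = k_lo))
  if (k_hi == target) return(list(param = hi, count = k_hi))
  monotone_ok <- sgn * (k_hi - k_lo) >= 0
  if (monotone_ok && (target - k_lo) * (target - k_hi) < 0) {
    a <- lo; b <- hi
    for (i in seq_len(max_iter)) {
      mid <- if (integer_param) floor((a + b) / 2) else (a + b) / 2
      if (mid <= a || mid >= b) break
      k_mid <- eval_count(mid)
      if (abs(k_mid - target) < abs(best$count - target)) {
        best <- list(param = mid, count = k_mid)
      }
      if (k_mid == target) return(list(param = mid, count = k_mid))
      if (sgn * (k_mid - target) < 0) a <- mid else b <- mid
      if (!monotone_ok) break
    }
  }
  # scan fallback: the count was non-monotone or bisection exhausted
  grid <- if (integer_param) {
    unique(floor(seq(lo, hi, length.out = min(scan_points, hi - lo + 1))))
  } else seq(lo, hi, length.out = scan_points)
  ks <- if (is.null(eval_batch)) vapply(grid, eval_count, numeric(1)) else
    eval_batch(grid)
  hit <- which(ks == target)
  if (length(hit)) return(list(param = grid[hit[1]], count = ks[hit[1]]))
  i <- which.min(abs(ks - target))
  if (abs(ks[i] - target) < abs(best$count - target)) {
    best <- list(param = grid[i], count = ks[i])
  }
  best
}

#' Match superpixel counts across segmentation algorithms
#'
#' Comparing explanations across segmenters is only meaningful when all
#' produce the same number of superpixels. Quickshift offers the least
#' control over its count, so it serves as the baseline: its count `k*` is
#' recorded, then Felzenszwalb's `scale` (count decreasing in scale) and
#' SLIC's `n_segments` (count increasing) are searched by monotone bisection
#' (with a grid-scan fallback on non-monotone stretches) for parameters
#' reproducing `k*` exactly. `sigma` is held at the shared default
#' throughout. If no parameter in a range achieves `k*`, the closest count
#' is returned and flagged.
#'
#' @param image An 8-bit RGB array.
#' @param baseline A [segmenter_params()] with `algorithm = "quickshift"`.
#' @param fha_scale_range Numeric length-2: Felzenszwalb `scale` search
#'   interval.
#' @param slic_range Integer length-2: SLIC `n_segments` search interval.
#' @return A list with one entry per algorithm (`quickshift`, `fha`,
#'   `slic`), each containing `params`, `segments`, `k` and (for the tuned
#'   algorithms) `exact`; plus `k_target` and an overall `exact` flag.
#' @export
match_segment_counts <- function(image,
                                 baseline = segmenter_params("quickshift"),
                                 fha_scale_range = c(200, 600),
                                 slic_range = c(10, 80)) {
  check_image(image)
  if (baseline$algorithm != "quickshift") {
    stop_invalid("baseline must use the quickshift algorithm")
  }
  if (length(fha_scale_range) != 2L || diff(fha_scale_range) < 0 ||
      length(slic_range) != 2L || diff(slic_range) < 0) {
    stop_invalid("search ranges must be length-2 non-decreasing vectors")
  }
  base_seg <- segment_image(image, baseline)
  k_target <- base_seg$k

  memo <- new.env(parent = emptyenv())
  eval_for <- function(make_params) {
    function(p) {
      key <- sprintf("%.12g", p)
      if (!is.null(memo[[key]])) return(memo[[key]])
      k <- segment_image(image, make_params(p))$k
      memo[[key]] <- k
      k
    }
  }

  tune <- function(make_params, lo, hi, decreasing, integer_param) {
    rm(list = ls(memo), envir = memo)
    # scan fallback probes many parameters at once through a single
    # backend invocation; counting distinct labels needs no relabeling
    eval_batch <- function(grid) {
      segs <- skimage_segment_batch(image, lapply(grid, make_params))
      vapply(segs, function(m) length(unique(as.vector(m))), numeric(1))
    }
    res <- bisect_count(eval_for(make_params), lo, hi, k_target,
                        decreasing = decreasing,
                        integer_param = integer_param,
                        eval_batch = eval_batch)
    params <- make_params(res$param)
    segs <- segment_image(image, params)
    list(params = params, segments = segs, k = segs$k,
         exact = segs$k == k_target)
  }

  fha <- tune(function(s) segmenter_params("fha", sigma = baseline$sigma,
                                           scale = s),
              fha_scale_range[1], fha_scale_range[2],
              decreasing = TRUE, integer_param = FALSE)
  slic <- tune(function(n) segmenter_params("slic", sigma = baseline$sigma,
                                            n_segments = n),
               as.integer(slic_range[1]), as.integer(slic_range[2]),
               decreasing = FALSE, integer_param = TRUE)

  list(quickshift = list(params = baseline, segments = base_seg, k = k_target),
       fha = fha, slic = slic,
       k_target = k_target, exact = fha$exact && slic$exact)
}
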