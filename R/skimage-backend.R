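# Bridge to the scikit-image superpixel implementations.  Images travel as
# PNG tempfiles, jobs as JSON, label rasters come back as integer CSV grids.

#' Is the scikit-image segmentation backend available?
#'
#' The `"fha"`, `"slic"` and `"quickshift"` algorithms are computed by
#' scikit-image through a bundled Python helper run with `python` from the
#' PATH. `"squaregrid"` never needs it.
#'
#' @return `TRUE` if a usable `python` with scikit-image was found.
#' @export
skimage_available <- function() {
  if (!is.null(.gridlime_env$skimage_ok)) return(.gridlime_env$skimage_ok)
  ok <- FALSE
  if (nzchar(Sys.which("python"))) {
    status <- suppressWarnings(system2(
      "python", c("-c", shQuote("import skimage, numpy, imageio")),
      stdout = FALSE, stderr = FALSE))
    ok <- identical(status, 0L)
  }
  .gridlime_env$skimage_ok <- ok
  ok
}

.gridlime_env <- new.env(parent = emptyenv())

#' @noRd
skimage_script <- function() {
  path <- system.file("python", "segment_backend.py", package = "gridlime")
  if (!nzchar(path)) stop("bundled segment_backend.py not found")
  path
}

# Run one segmentation job; returns the raw (unnormalized) label matrix.
#' @noRd
skimage_segment <- function(image, params) {
  res <- skimage_segment_batch(image, list(params))
  res[[1]]
}

# Run several jobs against the same image in a single python invocation
# (amortizes the interpreter and library startup during parameter searches).
#' @noRd
skimage_segment_batch <- function(image, params_list) {
  if (!skimage_available()) {
    stop("the '", params_list[[1]]$algorithm, "' backend needs python with ",
         "scikit-image on the PATH; see ?skimage_available")
  }
  dir <- tempfile("gridlime_seg_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  img_path <- file.path(dir, "image.png")
  png::writePNG(image / 255, img_path)
  jobs <- lapply(seq_along(params_list), function(i) {
    p <- params_list[[i]]
    list(id = i, algorithm = p$algorithm, sigma = p$sigma, scale = p$scale,
         n_segments = p$n_segments, kernel_size = p$kernel_size,
         max_dist = p$max_dist, ratio = p$ratio)
  })
  spec <- file.path(dir, "jobs.json")
  jsonlite::write_json(list(image = img_path, out_dir = dir, jobs = jobs),
                       spec, auto_unbox = TRUE, digits = NA)
  out <- system2("python", c(skimage_script(), spec),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("segmentation backend failed:\n", paste(out, collapse = "\n"))
  }
  lapply(seq_along(params_list), function(i) {
    f <- file.path(dir, sprintf("labels_%d.csv", i))
    as.matrix(utils::read.csv(f, header = FALSE))
  })
}
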