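# Plain-format I/O: 8-bit PNG/TIFF patches, 8-bit gray masks, full-precision
# CSV grids for heat maps and segment maps, JSON for explanations.

#' Read / write 8-bit RGB patches
#'
#' PNG or TIFF is chosen by file extension. Images are represented in R as
#' integer arrays (height x width x 3, values 0..255); an alpha channel, if
#' present, is dropped on read.
#'
#' @param path File path (`.png`, `.tif` or `.tiff`).
#' @return `read_patch` returns an integer RGB array.
#' @export
read_patch <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid("unsupported image extension: .", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  img <- round_half_up(raw * 255)
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_patch
#' @param image An 8-bit RGB array.
#' @export
write_patch <- function(image, path) {
  check_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(image / 255, path, bits.per.sample = 8L),
    stop_invalid("unsupported image extension: .", ext))
  invisible(path)
}

#' Read / write binary annotation masks
#'
#' Masks are 8-bit single-channel PNGs: 0 marks normal tissue, any nonzero
#' value tumor tissue. Written masks use 0/255.
#'
#' @param path PNG file path.
#' @return `read_annotation` returns a binary integer matrix.
#' @export
read_annotation <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  m <- matrix(as.integer(raw > 0), nrow(raw), ncol(raw))
  m
}

#' @rdname read_annotation
#' @param annotation Binary matrix (nonzero = tumor).
#' @export
write_annotation <- function(annotation, path) {
  png::writePNG(matrix(as.numeric(annotation != 0), nrow(annotation),
                       ncol(annotation)), path)
  invisible(path)
}

# Full-precision decimal text so CSV round trips are exact.
#' @noRd
format_full <- function(x) formatC(x, format = "g", digits = 17)

#' Heat-map CSV round trip
#'
#' Heat maps are written as headerless comma-separated float grids with
#' 17 significant digits, so that writing and re-reading reproduces the
#' in-memory values exactly.
#'
#' @param map A [heat_map()].
#' @param path CSV file path.
#' @export
write_heatmap_csv <- function(map, path) {
  v <- map$values
  lines <- apply(v, 1, function(row) paste(format_full(row), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @param provenance Provenance label for the re-read map.
#' @return `read_heatmap_csv` returns a [heat_map()].
#' @export
read_heatmap_csv <- function(path, provenance = "csv") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  heat_map(m, provenance)
}

#' Segment-map export
#'
#' Segment maps serialize as integer CSV grids (primary, exact) and as
#' single-channel 16-bit TIFF rasters where the pixel value is the label
#' (for viewing in image tools; 16 bits cover any realistic segment count).
#'
#' @param segments A [segment_map()].
#' @param path Output path (`.csv` or `.tif`/`.tiff`).
#' @export
write_segments <- function(segments, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    lines <- apply(segments$labels, 1, paste, collapse = ",")
    writeLines(lines, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (segments$k > 65536L) stop_invalid("too many segments for 16-bit export")
    tiff::writeTIFF(segments$labels / 65535, path, bits.per.sample = 16L)
  } else {
    stop_invalid("unsupported segment-map extension: .", ext)
  }
  invisible(path)
}

#' @rdname write_segments
#' @return `read_segments` returns a [segment_map()].
#' @export
read_segments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  labels <- if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else if (ext %in% c("tif", "tiff")) {
    round_half_up(tiff::readTIFF(path) * 65535)
  } else {
    stop_invalid("unsupported segment-map extension: .", ext)
  }
  dimnames(labels) <- NULL
  segment_map(matrix(as.integer(labels), nrow(labels), ncol(labels)))
}

#' Explanation JSON round trip
#'
#' Serializes the surrogate fit as JSON:
#' `{k, class, intercept, weights, fit_score, seed, n_samples}` at full
#' precision.
#'
#' @param explanation A `"lime_explanation"`.
#' @param path JSON file path.
#' @export
write_explanation_json <- function(explanation, path) {
  jsonlite::write_json(list(
    k = length(explanation$weights),
    class = explanation$class_index,
    intercept = explanation$intercept,
    weights = explanation$weights,
    fit_score = explanation$fit_score,
    seed = explanation$seed,
    n_samples = explanation$n_samples
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_explanation_json
#' @return `read_explanation_json` returns a `"lime_explanation"`.
#' @export
read_explanation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_lime_explanation(weights = as.numeric(x$weights),
                       intercept = x$intercept, fit_score = x$fit_score,
                       class_index = as.integer(x$class),
                       n_samples = as.integer(x$n_samples),
                       seed = as.integer(x$seed))
}
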