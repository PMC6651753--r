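# Rendering: symmetric blue-red diverging maps, annotation overlays,
# color-limit sweeps, and comparison panels.

#' Rendering specification
#'
#' Color convention for attribution maps: a symmetric diverging scale on
#' `[vmin, vmax]` with `vmin = -vmax`; blue marks positive weights (in favor
#' of the explained class), red negative, white zero, and color intensity is
#' proportional to the absolute weight. Values outside the limits clip to
#' full saturation. The default limits are `[-1, 1]`.
#'
#' @param vmax Positive upper color limit.
#' @param vmin Lower limit; must equal `-vmax`.
#' @param overlay_alpha Default opacity for annotation overlays.
#' @return An object of class `"render_spec"`.
#' @export
render_spec <- function(vmax = 1, vmin = -vmax, overlay_alpha = 0.35) {
  if (!is.numeric(vmax) || length(vmax) != 1L || vmax <= 0) {
    stop_invalid("vmax must be a positive number")
  }
  if (vmin != -vmax) {
    stop_invalid("color limits must be symmetric: vmin = -vmax")
  }
  if (overlay_alpha < 0 || overlay_alpha > 1) {
    stop_invalid("overlay_alpha must be in [0, 1]")
  }
  structure(list(vmin = vmin, vmax = vmax, overlay_alpha = overlay_alpha),
            class = "render_spec")
}

# Colormap anchors: white (255,255,255) at 0, saturated blue (0,0,255) at
# +vmax, saturated red (255,0,0) at -vmax, linear in RGB; fixed so renders
# are bit-exact.
#' @noRd
diverging_rgb <- function(t) {
  # t in [-1, 1], positive -> blue
  a <- abs(t)
  r <- ifelse(t >= 0, 1 - a, 1)
  g <- 1 - a
  b <- ifelse(t >= 0, 1, 1 - a)
  list(r = r, g = g, b = b)
}

#' Render a heat map as an RGB raster
#'
#' Maps attributions to 8-bit RGB with the symmetric blue-red convention of
#' [render_spec()]: zero is white, `+vmax` saturated blue, `-vmax` saturated
#' red, linear in between, clipped outside.
#'
#' @param map A [heat_map()].
#' @param spec A [render_spec()].
#' @return An integer RGB array (height x width x 3, 0..255).
#' @export
render_heatmap <- function(map, spec = render_spec(1)) {
  if (!inherits(map, "heat_map")) stop_invalid("map must be a heat_map")
  if (!inherits(spec, "render_spec")) stop_invalid("spec must be a render_spec")
  t <- pmax(-1, pmin(1, map$values / spec$vmax))
  ch <- diverging_rgb(t)
  out <- array(0L, dim = c(nrow(map$values), ncol(map$values), 3L))
  out[, , 1] <- round_half_up(255 * ch$r)
  out[, , 2] <- round_half_up(255 * ch$g)
  out[, , 3] <- round_half_up(255 * ch$b)
  storage.mode(out) <- "integer"
  out
}

#' Overlay a binary annotation in transparent green
#'
#' Blends annotated pixels toward green — the convention for expert tumor
#' annotations: green marks metastatic tissue, untouched pixels normal
#' tissue.
#'
#' @param base An 8-bit RGB array.
#' @param annotation Binary matrix (nonzero = annotated) matching the base
#'   dimensions.
#' @param alpha Overlay opacity in `[0, 1]`.
#' @return An integer RGB array.
#' @export
overlay_annotation <- function(base, annotation, alpha = 0.35) {
  check_image(base, "base")
  if (!identical(dim(annotation), dim(base)[1:2])) {
    stop_shape("annotation dimensions do not match the image")
  }
  if (alpha < 0 || alpha > 1) stop_invalid("alpha must be in [0, 1]")
  green <- c(0, 200, 0)
  out <- base
  sel <- annotation != 0
  for (c in 1:3) {
    plane <- base[, , c]
    plane[sel] <- round_half_up((1 - alpha) * plane[sel] + alpha * green[c])
    out[, , c] <- plane
  }
  storage.mode(out) <- "integer"
  out
}

#' Render a heat map at a sweep of color limits
#'
#' Re-renders one map at several symmetric limits `[-L, L]`. For maps with
#' small weights, tight limits reveal structure that the default `[-1, 1]`
#' scale leaves nearly white; the default sweep spans 0.001 to 0.8.
#'
#' @param map A [heat_map()].
#' @param limits Ascending vector of positive limits.
#' @return A named list of integer RGB arrays, one per limit.
#' @export
limit_sweep <- function(map,
                        limits = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2,
                                   0.4, 0.8)) {
  if (any(limits <= 0)) stop_invalid("limits must be positive")
  if (is.unsorted(limits, strictly = TRUE)) {
    stop_invalid("limits must be strictly ascending")
  }
  out <- lapply(limits, function(L) render_heatmap(map, render_spec(L)))
  names(out) <- vapply(limits, format, character(1))
  out
}

#' Side-by-side comparison panel
#'
#' Composes a horizontal strip: the original patch, the annotation overlay
#' (when given), then each named heat map rendered at `[-1, 1]`, in the
#' given order. Every tile has the width of the input image.
#'
#' @param image An 8-bit RGB array.
#' @param heatmaps Named (ordered) list of [heat_map()]s.
#' @param annotation Optional binary annotation matrix.
#' @param spec A [render_spec()] used for all heat-map tiles.
#' @return An integer RGB array of width `n_tiles * width`.
#' @export
comparison_panel <- function(image, heatmaps, annotation = NULL,
                             spec = render_spec(1)) {
  check_image(image)
  tiles <- list(image)
  if (!is.null(annotation)) {
    tiles <- c(tiles, list(overlay_annotation(image, annotation,
                                              spec$overlay_alpha)))
  }
  for (m in heatmaps) {
    if (!identical(dim(m$values), dim(image)[1:2])) {
      stop_shape("heat map dimensions do not match the image")
    }
    tiles <- c(tiles, list(render_heatmap(m, spec)))
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- array(0L, dim = c(h, w * length(tiles), 3L))
  for (i in seq_along(tiles)) {
    out[, (i - 1L) * w + seq_len(w), ] <- tiles[[i]]
  }
  storage.mode(out) <- "integer"
  out
}

# Display an RGB raster with base graphics.
#' @noRd
show_raster <- function(raster, main = "") {
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = dim(raster)[1] /
                          dim(raster)[2])
  graphics::rasterImage(grDevices::as.raster(raster / 255), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::title(main = main)
  invisible(NULL)
}
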