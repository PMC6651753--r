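# Closed-form trainable-parameter counting for the two reference CNN
# architectures.  Pure integer arithmetic; no deep-learning framework.

#' Layer descriptor
#'
#' A minimal layer description sufficient for closed-form trainable-weight
#' counting and output-shape threading. Fields irrelevant to `kind` are
#' ignored.
#'
#' @param kind One of `"input"`, `"conv"`, `"maxpool"`, `"globalpool"`,
#'   `"flatten"`, `"dense"`, `"dropout"`.
#' @param filters Convolution filter count.
#' @param units Dense layer neuron count.
#' @param kernel Length-2 kernel size (conv) or pool size (maxpool).
#' @param stride Length-2 stride (maxpool; defaults to the pool size).
#' @param padding `"valid"` (no padding) or `"same"` (output keeps the
#'   spatial size, stride-1 convolutions).
#' @param activation Activation label; metadata only, never affects counts.
#' @param rate Dropout rate; metadata only.
#' @return An object of class `"layer_spec"`.
#' @export
layer_spec <- function(kind, filters = NULL, units = NULL, kernel = c(3L, 3L),
                       stride = NULL, padding = c("valid", "same"),
                       activation = NULL, rate = NULL) {
  kind <- match.arg(kind, c("input", "conv", "maxpool", "globalpool",
                            "flatten", "dense", "dropout"))
  padding <- match.arg(padding)
  structure(list(kind = kind, filters = filters, units = units,
                 kernel = kernel, stride = stride %||% kernel,
                 padding = padding, activation = activation, rate = rate),
            class = "layer_spec")
}

#' Architecture descriptor
#'
#' @param layers List of [layer_spec()]s; the first must be the input layer.
#' @param input_shape Length-3 input shape `(height, width, channels)`.
#' @return An object of class `"architecture_spec"`.
#' @export
architecture_spec <- function(layers, input_shape = c(96L, 96L, 3L)) {
  if (length(layers) < 1L || layers[[1]]$kind != "input") {
    stop_invalid("the first layer must be the input layer")
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "architecture_spec")
}

#' Parameter count and output shape of one layer
#'
#' Standard counting formulas: a convolution holds
#' `kh * kw * c_in * filters + filters` weights, a dense layer
#' `n_in * units + units`; pooling, flatten and dropout hold none. Shape
#' threading: `"valid"` convolutions shrink each spatial dimension by
#' `kernel - 1`, `"same"` preserves it; max pooling maps a dimension to
#' `floor(dim / stride)`; global pooling reduces to the channel vector.
#'
#' @param spec A [layer_spec()].
#' @param in_shape Integer input shape (length 3 spatial+channel, or length
#'   1 after flattening).
#' @return List with `params` (integer count) and `out_shape`.
#' @export
layer_forward <- function(spec, in_shape) {
  in_shape <- as.integer(in_shape)
  if (any(in_shape < 1L)) stop_shape("input shape must be positive")
  switch(spec$kind,
    input = list(params = 0L, out_shape = in_shape),
    conv = {
      if (length(in_shape) != 3L) stop_shape("conv expects a 3-d input")
      kh <- spec$kernel[1]; kw <- spec$kernel[2]
      out_sp <- if (spec$padding == "valid") {
        if (kh > in_shape[1] || kw > in_shape[2]) {
          stop_shape("kernel ", kh, "x", kw, " exceeds input ",
                     in_shape[1], "x", in_shape[2], " under valid padding")
        }
        c(in_shape[1] - kh + 1L, in_shape[2] - kw + 1L)
      } else in_shape[1:2]
      list(params = as.integer(kh * kw * in_shape[3] * spec$filters +
                                 spec$filters),
           out_shape = as.integer(c(out_sp, spec$filters)))
    },
    maxpool = {
      if (length(in_shape) != 3L) stop_shape("maxpool expects a 3-d input")
      list(params = 0L,
           out_shape = as.integer(c(in_shape[1] %/% spec$stride[1],
                                    in_shape[2] %/% spec$stride[2],
                                    in_shape[3])))
    },
    globalpool = {
      if (length(in_shape) != 3L) stop_shape("globalpool expects a 3-d input")
      list(params = 0L, out_shape = in_shape[3])
    },
    flatten = list(params = 0L, out_shape = as.integer(prod(in_shape))),
    dropout = list(params = 0L, out_shape = in_shape),
    dense = {
      if (length(in_shape) != 1L) {
        stop_shape("dense expects a flat input; add flatten or globalpool")
      }
      list(params = as.integer(in_shape * spec$units + spec$units),
           out_shape = as.integer(spec$units))
    })
}

#' Total trainable parameters of an architecture
#'
#' Threads shapes through the layer list and sums the per-layer counts.
#'
#' @param arch An [architecture_spec()].
#' @return Integer total of trainable weights.
#' @examples
#' model_param_count(model1_spec())   # 1661186
#' model_param_count(vgg19_spec())    # 20024897
#' @export
model_param_count <- function(arch) {
  shape <- arch$input_shape
  total <- 0
  for (layer in arch$layers) {
    step <- layer_forward(layer, shape)
    total <- total + step$params
    shape <- step$out_shape
  }
  as.integer(total)
}

#' Reference architecture: the custom 9-convolution CNN ("Model1")
#'
#' Three valid-padding 3x3 convolution blocks (32, 64, 128 filters; three
#' convolutions each) with 2x2 max pooling, then a flatten, a 256-unit dense
#' layer and a 2-way softmax head, on 96x96x3 input. Valid padding is the
#' reading uniquely consistent with the published total of 1,661,186
#' trainable weights.
#'
#' @return An [architecture_spec()].
#' @export
model1_spec <- function() {
  conv <- function(f) layer_spec("conv", filters = f, kernel = c(3L, 3L),
                                 padding = "valid", activation = "relu")
  pool <- layer_spec("maxpool", kernel = c(2L, 2L))
  architecture_spec(list(
    layer_spec("input"),
    conv(32L), conv(32L), conv(32L), pool,
    layer_spec("dropout", rate = 0.3),
    conv(64L), conv(64L), conv(64L), pool,
    conv(128L), conv(128L), conv(128L), pool,
    layer_spec("flatten"),
    layer_spec("dense", units = 256L, activation = "relu"),
    layer_spec("dropout", rate = 0.3),
    layer_spec("dense", units = 2L, activation = "softmax")
  ), input_shape = c(96L, 96L, 3L))
}

#' Reference architecture: VGG19 convolutional trunk with a sigmoid head
#'
#' The sixteen same-padding 3x3 VGG19 convolutions in five blocks (64, 128,
#' 256, 512, 512 filters) with stride-2 2x2 max pooling, followed by a
#' global average pooling to the 512-vector and a single sigmoid unit. The
#' published layer list jumps straight from the last pooling to the dense
#' head; a flatten there would contradict the published 20,024,897 total,
#' while a 512-input head (512 + 1 = 513 parameters) matches it exactly, so
#' the global-pooling reduction is adopted.
#'
#' @return An [architecture_spec()].
#' @export
vgg19_spec <- function() {
  conv <- function(f) layer_spec("conv", filters = f, kernel = c(3L, 3L),
                                 padding = "same", activation = "relu")
  pool <- layer_spec("maxpool", kernel = c(2L, 2L), stride = c(2L, 2L))
  architecture_spec(list(
    layer_spec("input"),
    conv(64L), conv(64L), pool,
    conv(128L), conv(128L), pool,
    conv(256L), conv(256L), conv(256L), conv(256L), pool,
    conv(512L), conv(512L), conv(512L), conv(512L), pool,
    conv(512L), conv(512L), conv(512L), conv(512L), pool,
    layer_spec("globalpool"),
    layer_spec("dense", units = 1L, activation = "sigmoid")
  ), input_shape = c(96L, 96L, 3L))
}
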