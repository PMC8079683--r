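# Declarative architecture specifications for the three baseline networks.
#
# A spec is data: an ordered list of layer descriptions plus an input shape.
# Builders in model.R turn a spec into a runnable network; the closed-form
# parameter count and the shape arithmetic here are independent of that
# engine, so the two can be cross-checked against each other.

layer_conv <- function(width, k = 3L, stride = 1L) {
  stopifnot(width > 0, k %in% c(1L, 3L, 7L), stride %in% c(1L, 2L))
  list(kind = "conv", width = as.integer(width), k = as.integer(k),
       stride = as.integer(stride))
}
layer_bn <- function() list(kind = "batch_norm")
layer_relu <- function() list(kind = "relu")
layer_maxpool <- function() list(kind = "maxpool")
layer_avgpool <- function() list(kind = "avgpool")
layer_flatten <- function() list(kind = "flatten")
layer_gap <- function() list(kind = "global_avg_pool")
layer_fc <- function(width) list(kind = "fc", width = as.integer(width))
layer_sigmoid <- function() list(kind = "sigmoid")
layer_res_block <- function(width, projection = FALSE, stride = 1L) {
  list(kind = "residual_block", width = as.integer(width),
       block_type = if (projection) "projection_skip" else "identity_skip",
       stride = as.integer(stride), pre_activation = TRUE)
}
layer_dense_block <- function(n_layers, growth = 32L, bottleneck = TRUE) {
  list(kind = "dense_block", n_layers = as.integer(n_layers),
       growth = as.integer(growth), bottleneck = isTRUE(bottleneck))
}
layer_transition <- function(compression = 0.5) {
  list(kind = "transition", compression = compression)
}

new_arch_spec <- function(name, layers, input_shape = c(256L, 256L, 1L)) {
  spec <- structure(list(name = name, input_shape = as.integer(input_shape),
                         layers = layers),
                    class = "arch_spec")
  spec_shapes(spec)  # validates pooling arithmetic
  spec
}

#' VGG-style ConvNet specification
#'
#' Fourteen 3x3 convolutions in width-doubling pairs
#' (16, 16, 32, 32, ..., 1024, 1024), each followed by batch normalization
#' and ReLU, with 2x2 max pooling after every pair, then flatten,
#' FC(512), FC(256) and a single logistic output unit. For 256x256 input the
#' seven pooling stages leave a 2x2 spatial map at the flatten.
#'
#' @param input_shape Integer vector `(height, width, channels)`.
#' @return An `arch_spec`.
#' @export
convnet_spec <- function(input_shape = c(256L, 256L, 1L)) {
  widths <- rep(c(16L, 32L, 64L, 128L, 256L, 512L, 1024L), each = 2L)
  layers <- list()
  for (i in seq_along(widths)) {
    layers <- c(layers, list(layer_conv(widths[i]), layer_bn(), layer_relu()))
    if (i %% 2L == 0L) layers <- c(layers, list(layer_maxpool()))
  }
  layers <- c(layers, list(layer_flatten(),
                           layer_fc(512L), layer_relu(),
                           layer_fc(256L), layer_relu(),
                           layer_fc(1L), layer_sigmoid()))
  new_arch_spec("convnet", layers, input_shape)
}

#' Full pre-activation ResNet specification
#'
#' A stem convolution followed by `n_blocks` residual blocks of two kinds:
#' identity-skip blocks, which preserve width and spatial size, and
#' projection-skip blocks with stride-2 downsampling placed at every width
#' change. Inside every block the ordering is BN -> ReLU -> conv
#' (full pre-activation). The reference layout distributes the blocks over
#' up to five stages with widths 16, 32, 64, 128, 256; the default 25 blocks
#' give five stages of five.
#'
#' @param n_blocks Total number of residual blocks (default 25).
#' @param input_shape Integer vector `(height, width, channels)`.
#' @param stage_widths Channel widths available to the stages.
#' @return An `arch_spec`.
#' @export
resnet_spec <- function(n_blocks = 25L, input_shape = c(256L, 256L, 1L),
                        stage_widths = c(16L, 32L, 64L, 128L, 256L)) {
  assert_that(n_blocks >= 1, "resnet_spec: n_blocks must be >= 1")
  n_stages <- min(length(stage_widths), n_blocks)
  per_stage <- diff(floor(seq(0, n_blocks, length.out = n_stages + 1)))
  widths <- stage_widths[seq_len(n_stages)]
  layers <- list(layer_conv(widths[1L]))
  for (s in seq_len(n_stages)) {
    for (b in seq_len(per_stage[s])) {
      first <- b == 1L
      if (s == 1L) {
        layers <- c(layers, list(layer_res_block(widths[s])))
      } else if (first) {
        layers <- c(layers, list(layer_res_block(widths[s], projection = TRUE,
                                                 stride = 2L)))
      } else {
        layers <- c(layers, list(layer_res_block(widths[s])))
      }
    }
  }
  layers <- c(layers, list(layer_bn(), layer_relu(), layer_gap(),
                           layer_fc(1L), layer_sigmoid()))
  new_arch_spec("resnet", layers, input_shape)
}

#' DenseNet-169 configuration
#'
#' Dense-connectivity configuration with block sizes 6/12/32/32 and growth
#' rate 32: inside a dense block, layer l receives the concatenated feature
#' maps of all preceding layers. Each dense layer is a bottleneck
#' (1x1 conv to 4x growth) followed by a 3x3 conv; compressing transitions
#' (1x1 conv + 2x2 average pooling) separate the blocks. The first
#' convolution takes a single grayscale channel. By the standard depth
#' convention (initial conv + 2 convs per dense layer + 3 transition convs +
#' classifier) the configuration is 169 layers deep.
#'
#' @param input_shape Integer vector `(height, width, channels)`.
#' @param growth Growth rate (feature maps added per dense layer).
#' @param block_sizes Dense-layer counts of the four blocks.
#' @return An `arch_spec`.
#' @export
densenet_spec <- function(input_shape = c(256L, 256L, 1L), growth = 32L,
                          block_sizes = c(6L, 12L, 32L, 32L)) {
  layers <- list(layer_conv(2L * growth, k = 7L, stride = 2L),
                 layer_bn(), layer_relu(), layer_maxpool())
  for (i in seq_along(block_sizes)) {
    layers <- c(layers, list(layer_dense_block(block_sizes[i], growth)))
    if (i < length(block_sizes)) layers <- c(layers, list(layer_transition()))
  }
  layers <- c(layers, list(layer_bn(), layer_relu(), layer_gap(),
                           layer_fc(1L), layer_sigmoid()))
  new_arch_spec("densenet", layers, input_shape)
}

#' Shape arithmetic for a specification
#'
#' Tracks `(height, width, channels)` (or flat unit count) through every
#' layer and errors if pooling exhausts the spatial extent.
#'
#' @param spec An `arch_spec`.
#' @return List of per-layer output shapes.
#' @export
spec_shapes <- function(spec) {
  shp <- spec$input_shape  # c(h, w, c) while spatial; single number when flat
  out <- vector("list", length(spec$layers))
  pool_halve <- function(shp, what) {
    if (shp[1] < 2 || shp[2] < 2) {
      stop(sprintf("%s would exhaust the spatial extent (%dx%d)",
                   what, shp[1], shp[2]), call. = FALSE)
    }
    c(shp[1] %/% 2L, shp[2] %/% 2L, shp[3])
  }
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    shp <- switch(ly$kind,
      conv = c(as.integer(ceiling(shp[1] / ly$stride)),
               as.integer(ceiling(shp[2] / ly$stride)), ly$width),
      batch_norm = shp,
      relu = shp,
      sigmoid = shp,
      maxpool = pool_halve(shp, "max pooling"),
      avgpool = pool_halve(shp, "average pooling"),
      flatten = prod(shp),
      global_avg_pool = shp[3],
      fc = ly$width,
      residual_block = c(as.integer(ceiling(shp[1] / ly$stride)),
                         as.integer(ceiling(shp[2] / ly$stride)), ly$width),
      dense_block = c(shp[1], shp[2], shp[3] + ly$n_layers * ly$growth),
      transition = pool_halve(c(shp[1], shp[2],
                                as.integer(floor(shp[3] * ly$compression))),
                              "transition pooling"),
      stop(sprintf("unknown layer kind: %s", ly$kind))
    )
    if (ly$kind == "residual_block" && ly$block_type == "identity_skip" &&
        ly$width != out_channels(if (i == 1) spec$input_shape else out[[i - 1]])) {
      stop("identity_skip residual block must preserve channel width",
           call. = FALSE)
    }
    out[[i]] <- shp
  }
  out
}

out_channels <- function(shp) if (length(shp) == 3L) shp[3] else shp

#' Spatial side of the feature map entering the classifier
#'
#' For a 256-pixel input and `p` pooling stages this is exactly
#' `256 / 2^p`.
#'
#' @param spec An `arch_spec`.
#' @return Integer side length of the last spatial feature map.
#' @export
spec_output_side <- function(spec) {
  shapes <- spec_shapes(spec)
  side <- spec$input_shape[1]
  for (s in shapes) if (length(s) == 3L) side <- s[1]
  as.integer(side)
}

#' Count trainable parameters of a specification (closed form)
#'
#' A `k x k` convolution with `c_in -> c_out` contributes
#' `k^2 * c_in * c_out + c_out`; batch normalization contributes `4c`
#' (scale, shift, and the two tracked moments); a fully connected layer with
#' `n_in -> n_out` contributes `n_in * n_out + n_out`. Composite blocks are
#' expanded into these primitives.
#'
#' @param spec An `arch_spec`.
#' @param kinds Optional character vector restricting the count to certain
#'   layer kinds (e.g. `"conv"` for the convolutional stack only).
#'   Composite blocks are counted when their kind is included.
#' @return Total parameter count (double, exact for these magnitudes).
#' @export
count_parameters <- function(spec, kinds = NULL) {
  keep <- function(kind) is.null(kinds) || kind %in% kinds
  total <- 0
  shp <- spec$input_shape
  cin <- out_channels(shp)
  flat <- NULL  # unit count once spatial structure is gone
  conv_p <- function(k, ci, co) k * k * ci * co + co
  bn_p <- function(c) 4 * c
  for (ly in spec$layers) {
    switch(ly$kind,
      conv = {
        if (keep("conv")) total <- total + conv_p(ly$k, cin, ly$width)
        shp <- c(ceiling(shp[1] / ly$stride), ceiling(shp[2] / ly$stride),
                 ly$width)
        cin <- ly$width
      },
      batch_norm = if (keep("batch_norm")) total <- total + bn_p(cin),
      maxpool = , avgpool = {
        shp <- c(shp[1] %/% 2, shp[2] %/% 2, shp[3])
      },
      flatten = flat <- prod(shp),
      global_avg_pool = flat <- cin,
      fc = {
        if (keep("fc")) total <- total + flat * ly$width + ly$width
        flat <- ly$width
      },
      residual_block = {
        if (keep("residual_block")) {
          w <- ly$width
          total <- total + bn_p(cin) + conv_p(3, cin, w) +
            bn_p(w) + conv_p(3, w, w)
          if (ly$block_type == "projection_skip") {
            total <- total + conv_p(1, cin, w)
          }
        }
        shp <- c(ceiling(shp[1] / ly$stride), ceiling(shp[2] / ly$stride),
                 ly$width)
        cin <- ly$width
      },
      dense_block = {
        if (keep("dense_block")) {
          g <- ly$growth
          for (l in seq_len(ly$n_layers)) {
            ci <- cin + (l - 1L) * g
            if (ly$bottleneck) {
              total <- total + bn_p(ci) + conv_p(1, ci, 4 * g) +
                bn_p(4 * g) + conv_p(3, 4 * g, g)
            } else {
              total <- total + bn_p(ci) + conv_p(3, ci, g)
            }
          }
        }
        cin <- cin + ly$n_layers * ly$growth
        shp[3] <- cin
      },
      transition = {
        co <- floor(cin * ly$compression)
        if (keep("transition")) total <- total + bn_p(cin) + conv_p(1, cin, co)
        cin <- co
        shp <- c(shp[1] %/% 2, shp[2] %/% 2, co)
      },
      relu = , sigmoid = NULL,
      stop(sprintf("unknown layer kind: %s", ly$kind))
    )
  }
  total
}

#' Depth of a specification by the weighted-layer convention
#'
#' Counts parameterized convolutional and fully connected layers, the
#' convention by which architectures like DenseNet-169 are named: composite
#' blocks contribute their internal convolutions (2 per bottlenecked dense
#' layer, 2 per residual block plus 1 for a projection skip, 1 per
#' transition).
#'
#' @param spec An `arch_spec`.
#' @return Integer depth.
#' @export
spec_depth <- function(spec) {
  d <- 0L
  for (ly in spec$layers) {
    d <- d + switch(ly$kind,
      conv = 1L, fc = 1L,
      residual_block = if (ly$block_type == "projection_skip") 3L else 2L,
      dense_block = if (ly$bottleneck) 2L * ly$n_layers else ly$n_layers,
      transition = 1L,
      0L)
  }
  d
}

#' Number of layers of a given kind in a specification
#' @param spec An `arch_spec`.
#' @param kind Layer kind, e.g. `"conv"` or `"residual_block"`.
#' @return Integer count.
#' @export
count_layers <- function(spec, kind) {
  sum(vapply(spec$layers, function(ly) ly$kind == kind, logical(1)))
}

#' Serialize / read an architecture specification
#'
#' Human-readable YAML with one entry per layer (kind, filter size, stride,
#' width), mirroring how such architectures are tabulated.
#'
#' @param spec An `arch_spec`.
#' @param path Output / input file path.
#' @return `path` invisibly / an `arch_spec`.
#' @export
write_arch_spec <- function(spec, path) {
  yaml::write_yaml(list(name = spec$name,
                        input_shape = as.integer(spec$input_shape),
                        layers = spec$layers), path)
  invisible(path)
}

#' @rdname write_arch_spec
#' @export
read_arch_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  new_arch_spec(raw$name, raw$layers, as.integer(raw$input_shape))
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %s: input %s, %d layers, depth %d, %s parameters\n",
              x$name, paste(x$input_shape, collapse = "x"),
              length(x$layers), spec_depth(x),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Desk-scale convolutional specification
#'
#' A small ConvNet-style spec (conv-BN-ReLU-pool stages followed by a
#' global-average-pooling head into a single logistic unit) for fast
#' experiments and tests at reduced input sizes. The GAP head makes the
#' classic classifier-weight CAM applicable.
#'
#' @param widths Channel widths of the stages (one pooling per stage).
#' @param input_shape Integer vector `(height, width, channels)`.
#' @param head `"gap"` (global average pooling, default) or `"flatten"`
#'   (flatten + FC, exercising the gradient CAM path).
#' @return An `arch_spec`.
#' @export
small_convnet_spec <- function(widths = c(8L, 16L),
                               input_shape = c(32L, 32L, 1L),
                               head = c("gap", "flatten")) {
  head <- match.arg(head)
  layers <- list()
  for (w in widths) {
    layers <- c(layers, list(layer_conv(w), layer_bn(), layer_relu(),
                             layer_maxpool()))
  }
  layers <- c(layers, if (head == "gap") {
    list(layer_gap(), layer_fc(1L), layer_sigmoid())
  } else {
    list(layer_flatten(), layer_fc(16L), layer_relu(),
         layer_fc(1L), layer_sigmoid())
  })
  new_arch_spec("small_convnet", layers, input_shape)
}

#' Default training batch size for a model tag
#'
#' 32 for every architecture except the dense model, which trains with 16
#' because of its memory footprint.
#'
#' @param name Model tag, e.g. `"convnet"`, `"resnet"`, `"densenet"`.
#' @return Integer batch size.
#' @export
default_batch_size <- function(name) {
  if (grepl("dense", tolower(name))) 16L else 32L
}
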