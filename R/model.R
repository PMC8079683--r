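# Turning an architecture spec into a runnable model, plus the uniform
# TrainableModel wrapper: forward to probabilities, parameter enumeration,
# and a feature tap exposing the final convolutional maps for CAM.

#' Build a runnable model from an architecture specification
#'
#' Instantiates every layer with seeded fan-in-scaled random initialization.
#' The returned model maps a preprocessed image batch to positive-class
#' probabilities and exposes the final convolutional feature maps through
#' [feature_tap()].
#'
#' @param spec An `arch_spec`.
#' @param seed Integer seed for weight initialization.
#' @param input_shape Optional `(height, width, channels)` override, e.g. to
#'   run a reference architecture at a desk-scale input size.
#' @return A `trainable_model`.
#' @export
build_model <- function(spec, seed = 1L, input_shape = NULL) {
  if (!is.null(input_shape)) {
    spec <- new_arch_spec(spec$name, spec$layers, input_shape)
  }
  spec_shapes(spec)  # errors if pooling exhausts the spatial extent
  layers <- with_seed(seed, {
    cin <- spec$input_shape[3]
    flat <- NULL
    side <- spec$input_shape[1:2]
    lapply(spec$layers, function(ly) {
      built <- switch(ly$kind,
        conv = nn_conv_layer(cin, ly$width, ly$k, ly$stride),
        batch_norm = nn_bn_layer(cin),
        relu = nn_simple_layer("relu"),
        sigmoid = nn_simple_layer("sigmoid"),
        maxpool = nn_simple_layer("maxpool"),
        avgpool = nn_simple_layer("avgpool"),
        flatten = nn_simple_layer("flatten"),
        global_avg_pool = nn_simple_layer("gap"),
        fc = nn_fc_layer(flat, ly$width),
        residual_block = nn_res_block(cin, ly$width,
                                      ly$block_type == "projection_skip",
                                      ly$stride),
        dense_block = nn_dense_block(cin, ly$n_layers, ly$growth,
                                     ly$bottleneck),
        transition = nn_transition(cin, ly$compression),
        stop(sprintf("unknown layer kind: %s", ly$kind))
      )
      switch(ly$kind,
        conv = , residual_block = {
          cin <<- ly$width
          side <<- ceiling(side / ly$stride)
        },
        maxpool = , avgpool = side <<- side %/% 2L,
        dense_block = cin <<- cin + ly$n_layers * ly$growth,
        transition = {
          cin <<- built$cout
          side <<- side %/% 2L
        },
        flatten = flat <<- prod(side) * cin,
        global_avg_pool = flat <<- cin,
        fc = flat <<- ly$width,
        NULL
      )
      built
    })
  })
  shapes <- spec_shapes(spec)
  spatial <- vapply(shapes, function(s) length(s) == 3L, logical(1))
  tap_index <- max(which(spatial))
  structure(list(layers = layers, spec = spec,
                 input_shape = spec$input_shape,
                 tap_index = tap_index, seed = seed),
            class = "trainable_model")
}

model_forward <- function(model, x, training = FALSE, want_caches = FALSE) {
  caches <- if (want_caches) vector("list", length(model$layers)) else NULL
  tap <- NULL
  for (i in seq_along(model$layers)) {
    r <- nn_fwd(model$layers[[i]], x, training)
    x <- r$out
    if (want_caches) caches[[i]] <- r$cache
    if (i == model$tap_index) tap <- x
  }
  list(out = x, caches = caches, tap = tap)
}

# Backpropagate through layers [stop_after + 1, from]; gradients are written
# into the layer environments; returns the gradient flowing out of layer
# stop_after + 1.
model_backward <- function(model, caches, dout, stop_after = 0L) {
  for (i in rev(seq_len(length(model$layers)))) {
    if (i <= stop_after) break
    dout <- nn_bwd(model$layers[[i]], dout, caches[[i]])
  }
  dout
}

as_batch_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x), 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Positive-class probabilities for an image batch
#'
#' @param model A `trainable_model` (or a `trained_model`, whose network is
#'   used).
#' @param x A single image matrix, an `(n, h, w)` array, or an
#'   `(n, h, w, 1)` array of preprocessed images in `[0, 1]`.
#' @return Numeric vector of probabilities in `[0, 1]`, one per image.
#' @export
predict_proba <- function(model, x) {
  model <- as_trainable(model)
  as.vector(model_forward(model, as_batch_array(x))$out)
}

#' Final convolutional feature maps (and classifier weights) for CAM
#'
#' @param model A `trainable_model` or `trained_model`.
#' @param x Image batch (see [predict_proba()]).
#' @return List with `features` (an `(n, h, w, c)` array tapped after the
#'   last spatial layer), `prob` (forward probabilities) and, when the head
#'   is global-average-pooling into a single linear unit, `classifier_weights`
#'   (length-`c` vector).
#' @export
feature_tap <- function(model, x) {
  model <- as_trainable(model)
  fw <- model_forward(model, as_batch_array(x))
  head_types <- vapply(model$layers[(model$tap_index + 1L):length(model$layers)],
                       function(l) l$type, character(1))
  cw <- NULL
  if (identical(head_types, c("gap", "fc", "sigmoid"))) {
    cw <- as.vector(model$layers[[model$tap_index + 2L]]$W)
  }
  list(features = fw$tap, prob = as.vector(fw$out), classifier_weights = cw)
}

as_trainable <- function(model) {
  if (inherits(model, "trained_model")) model$model else model
}

#' Enumerate the parameters of a built model
#'
#' Counts every weight tensor held by the network (convolution and linear
#' weights and biases; batch-norm scale, shift and tracked moments), the
#' independent counterpart of the closed-form [count_parameters()].
#'
#' @param model A `trainable_model`.
#' @param kinds Optional restriction, e.g. `"conv"` for convolution layers
#'   only (top-level convolutions, as in the spec's conv-stack count).
#' @return Total number of parameters.
#' @export
n_parameters <- function(model, kinds = NULL) {
  model <- as_trainable(model)
  layers <- if (is.null(kinds)) {
    model$layers
  } else {
    model$layers[vapply(model$layers, function(l) {
      map <- c(conv = "conv", fc = "fc", bn = "batch_norm",
               res_block = "residual_block", dense_block = "dense_block",
               transition = "transition")
      !is.na(map[l$type]) && map[l$type] %in% kinds
    }, logical(1))]
  }
  total <- 0
  for (ly in param_layers(layers)) {
    for (p in PARAM_NAMES[[ly$type]]) total <- total + length(get(p, ly))
    if (ly$type == "bn") total <- total + length(ly$run_mean) + length(ly$run_var)
  }
  total
}

#' Snapshot / restore model weights
#'
#' @param model A `trainable_model`.
#' @return `get_weights` returns a plain list of numeric arrays (including
#'   batch-norm running statistics); `set_weights` writes such a list back
#'   and returns the model invisibly.
#' @export
get_weights <- function(model) {
  model <- as_trainable(model)
  out <- list()
  for (ly in param_layers(model$layers)) {
    snap <- lapply(PARAM_NAMES[[ly$type]], function(p) get(p, ly))
    names(snap) <- PARAM_NAMES[[ly$type]]
    if (ly$type == "bn") {
      snap$run_mean <- ly$run_mean
      snap$run_var <- ly$run_var
    }
    out[[length(out) + 1L]] <- snap
  }
  out
}

#' @rdname get_weights
#' @param weights A list previously returned by `get_weights`.
#' @export
set_weights <- function(model, weights) {
  model <- as_trainable(model)
  players <- param_layers(model$layers)
  stopifnot(length(players) == length(weights))
  for (i in seq_along(players)) {
    for (p in names(weights[[i]])) assign(p, weights[[i]][[p]], envir = players[[i]])
  }
  invisible(model)
}

#' Deep-copy a model
#'
#' Layers are environments (mutable in place); cloning gives an independent
#' copy, e.g. to initialize per-region fine-tuning from an overall model.
#'
#' @param model A `trainable_model`.
#' @return An independent `trainable_model`.
#' @export
clone_model <- function(model) {
  was_trained <- inherits(model, "trained_model")
  net <- as_trainable(model)
  clone_layer <- function(ly) {
    e <- new.env(parent = emptyenv())
    for (nm in ls(ly, all.names = TRUE)) {
      v <- get(nm, envir = ly)
      assign(nm, v, envir = e)
    }
    if (!is.null(e$sub)) e$sub <- lapply(e$sub, clone_layer)
    if (!is.null(e$proj)) e$proj <- clone_layer(e$proj)
    if (!is.null(e$units)) e$units <- lapply(e$units, function(u) lapply(u, clone_layer))
    e
  }
  out <- net
  out$layers <- lapply(net$layers, clone_layer)
  if (was_trained) {
    model$model <- out
    model
  } else {
    out
  }
}

#' @export
print.trainable_model <- function(x, ...) {
  cat(sprintf("<trainable_model> %s: input %s, %s parameters, tap at layer %d\n",
              x$spec$name, paste(x$input_shape, collapse = "x"),
              format(n_parameters(x), big.mark = ","), x$tap_index))
  invisible(x)
}
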