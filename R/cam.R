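# Class activation maps: localizing the evidence behind a prediction from
# the final convolutional feature maps.
#
# Two weighting schemes sit behind one operation. When the classifier head
# is global-average-pooling into a single linear unit, the classic scheme
# applies: channel weights are the classifier weights themselves. For any
# other head (e.g. a flatten + FC stack) the weights are gradient-based:
# the spatial mean of the logit's gradient with respect to each feature map.
# The scheme actually used is recorded in the heatmap's `method` field.

#' Compute a class activation map
#'
#' Combines the final convolutional feature maps with class-specific channel
#' weights, rectifies negative contributions, upsamples bilinearly to the
#' input extent and min-max normalizes to `[0, 1]` (a constant map becomes
#' all zeros).
#'
#' @param model A `trainable_model` or `trained_model`.
#' @param image A single preprocessed image (matrix in `[0, 1]`).
#' @param target_class 1 (abnormal, default) or 0; for class 0 the channel
#'   weights are negated, localizing evidence for the complement.
#' @param method `"auto"` (classifier weights when the head permits,
#'   gradient otherwise), `"weights"`, or `"gradient"`.
#' @return A `cam_heatmap`: list with `grid` (matrix, same extent as the
#'   input, values in `[0, 1]`), `method`, and `predicted_prob`.
#' @export
compute_cam <- function(model, image, target_class = 1L,
                        method = c("auto", "weights", "gradient")) {
  method <- match.arg(method)
  net <- as_trainable(model)
  assert_that(!is.null(net$tap_index), "model does not expose a feature tap")
  stopifnot(is.matrix(image), target_class %in% c(0L, 1L))
  x <- as_batch_array(image)
  tap <- feature_tap(net, x)
  if (method == "auto") {
    method <- if (!is.null(tap$classifier_weights)) "weights" else "gradient"
  }
  f <- tap$features[1L, , , , drop = TRUE]
  if (length(dim(f)) == 2L) dim(f) <- c(dim(f), 1L)
  nch <- dim(f)[3]
  if (method == "weights") {
    assert_that(!is.null(tap$classifier_weights),
                "classifier-weight CAM requires a GAP + linear head")
    w <- tap$classifier_weights
  } else {
    # gradient of the pre-sigmoid logit w.r.t. the tapped feature maps,
    # averaged over space (the sigmoid layer is excluded from the backward
    # pass so the weighting is probability-scale free)
    fw <- model_forward(net, x, training = FALSE, want_caches = TRUE)
    nl <- length(net$layers)
    from <- if (net$layers[[nl]]$type == "sigmoid") nl - 1L else nl
    d <- matrix(1, 1L, 1L)
    for (i in rev(seq(net$tap_index + 1L, from))) {
      d <- nn_bwd(net$layers[[i]], d, fw$caches[[i]])
    }
    dtap <- d  # (1, h, w, c)
    w <- apply(array(dtap, dim(dtap)[2:4]), 3, mean)
  }
  if (target_class == 0L) w <- -w
  fm <- matrix(f, prod(dim(f)[1:2]), nch)
  cam <- matrix(fm %*% w, dim(f)[1], dim(f)[2])
  cam <- pmax(cam, 0)
  cam <- resize_bilinear(cam, nrow(image), ncol(image))
  rng <- range(cam)
  grid <- if (diff(rng) < 1e-12) {
    matrix(0, nrow(image), ncol(image))
  } else {
    (cam - rng[1]) / diff(rng)
  }
  structure(list(grid = grid, method = method,
                 predicted_prob = tap$prob[1L]),
            class = "cam_heatmap")
}

#' Overlay a heatmap on a grayscale image
#'
#' Pixelwise affine blend `out = (1 - alpha) * gray + alpha * colormap(heat)`.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param heatmap A `cam_heatmap` (or a plain matrix in `[0, 1]`) of the
#'   same extent.
#' @param alpha Heatmap opacity in `[0, 1]`.
#' @param palette Colour palette name passed to [grDevices::hcl.colors()].
#' @return An `(h, w, 3)` RGB array in `[0, 1]`, writable as PNG.
#' @export
overlay <- function(image, heatmap, alpha = 0.5, palette = "Inferno") {
  heat <- if (inherits(heatmap, "cam_heatmap")) heatmap$grid else heatmap
  assert_that(all(dim(image) == dim(heat)),
              "image and heatmap shapes do not match")
  stopifnot(alpha >= 0, alpha <= 1)
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, palette))
  cm <- ramp(as.vector(heat)) / 255
  out <- array(0, c(dim(image), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * image +
      alpha * matrix(cm[, ch], nrow(image), ncol(image))
  }
  out
}

#' Write CAM artifacts for one image
#'
#' Writes a side-by-side PNG (original | overlay) and the raw heatmap as a
#' grayscale PNG.
#'
#' @param image Preprocessed image matrix in `[0, 1]`.
#' @param heatmap A `cam_heatmap`.
#' @param prefix Output path prefix; writes `<prefix>_overlay.png` and
#'   `<prefix>_heatmap.png`.
#' @param alpha Overlay opacity.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cam <- function(image, heatmap, prefix, alpha = 0.5) {
  ov <- overlay(image, heatmap, alpha = alpha)
  side <- array(0, c(nrow(image), 2L * ncol(image), 3L))
  for (ch in 1:3) {
    side[, seq_len(ncol(image)), ch] <- image
    side[, ncol(image) + seq_len(ncol(image)), ch] <- ov[, , ch]
  }
  p1 <- paste0(prefix, "_overlay.png")
  p2 <- paste0(prefix, "_heatmap.png")
  png::writePNG(clip01(side), target = p1)
  png::writePNG(clip01(heatmap$grid), target = p2)
  invisible(c(p1, p2))
}

#' @export
print.cam_heatmap <- function(x, ...) {
  cat(sprintf("<cam_heatmap> %dx%d, method %s, predicted prob %.3f\n",
              nrow(x$grid), ncol(x$grid), x$method, x$predicted_prob))
  invisible(x)
}
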