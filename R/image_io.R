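# Image ingestion, preprocessing and augmentation.
#
# On-disk interchange is 8-bit grayscale PNG (color PNGs are collapsed by
# luminance). In memory an image is a plain numeric matrix; raw images use the
# [0, 255] scale and preprocessed images the [0, 1] scale.

#' Read a grayscale image
#'
#' Reads a PNG file and returns a numeric matrix on the raw `[0, 255]` scale.
#' Color images are converted by the Rec. 601 luminance weights; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix (rows = image height) with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  assert_that(file.exists(path), sprintf("image file not found: %s", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    a <- if (nc >= 3L) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  a * 255
}

#' Write a grayscale image
#'
#' @param pixels Numeric matrix in `[0, 1]` (values are clipped).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  png::writePNG(clip01(pixels), target = path)
  invisible(path)
}

#' Bilinear resize
#'
#' Plain bilinear interpolation with no aspect-ratio preservation, matching
#' the preprocessing convention of resizing every radiograph to a square.
#'
#' @param pixels Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_bilinear <- function(pixels, out_h, out_w) {
  stopifnot(is.matrix(pixels), out_h >= 1, out_w >= 1)
  h <- nrow(pixels); w <- ncol(pixels)
  if (h == out_h && w == out_w) return(pixels)
  # pixel-center alignment: output center maps to input coordinate
  ry <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  ry <- pmin(pmax(ry, 0), h - 1); rx <- pmin(pmax(rx, 0), w - 1)
  y0 <- floor(ry); x0 <- floor(rx)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ry - y0; fx <- rx - x0
  i00 <- pixels[y0 + 1, x0 + 1, drop = FALSE]
  i01 <- pixels[y0 + 1, x1 + 1, drop = FALSE]
  i10 <- pixels[y1 + 1, x0 + 1, drop = FALSE]
  i11 <- pixels[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  i00 * (1 - wy) * (1 - wx) + i01 * (1 - wy) * wx +
    i10 * wy * (1 - wx) + i11 * wy * wx
}

#' Preprocess a raw radiograph
#'
#' Resizes to a fixed square and maps intensities by the fixed scale
#' `v / 255` (not per-image min-max), so a constant image stays constant.
#' Values outside `[0, 255]` are clipped with a warning.
#'
#' Input already on the `[0, 1]` scale (every value at most 1) is resized
#' but not rescaled again, which makes the operation idempotent.
#'
#' @param pixels Numeric matrix on the raw `[0, 255]` scale.
#' @param size Output side length in pixels; 256 is the reference size,
#'   smaller sizes support desk-scale experiments.
#' @return `size` x `size` matrix with values in `[0, 1]`.
#' @export
preprocess_image <- function(pixels, size = 256L) {
  assert_that(is.matrix(pixels) && nrow(pixels) >= 1 && ncol(pixels) >= 1,
              "preprocess_image: empty or non-matrix input")
  if (any(pixels < 0 | pixels > 255)) {
    warning("pixel values outside [0, 255]; clipping", call. = FALSE)
    pixels <- pmin(pmax(pixels, 0), 255)
  }
  already <- max(pixels) <= 1
  out <- resize_bilinear(pixels, size, size)
  if (already) out else out / 255
}

#' Rotate an image about its center
#'
#' Inverse-mapped bilinear rotation; exposed corners are filled with 0
#' (black, matching radiograph borders).
#'
#' @param pixels Numeric matrix.
#' @param theta_deg Rotation angle in degrees (counter-clockwise).
#' @return Matrix of the same shape.
#' @export
rotate_image <- function(pixels, theta_deg) {
  h <- nrow(pixels); w <- ncol(pixels)
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  # inverse map: rotate output coordinates by -theta into the source frame
  sy <- cy - sin(th) * xx + cos(th) * yy
  sx <- cx + cos(th) * xx + sin(th) * yy
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  px <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- numeric(length(r))
    v[ok] <- pixels[cbind(r[ok], c[ok])]
    v
  }
  v <- px(y0, x0) * (1 - fy) * (1 - fx) + px(y0, x0 + 1) * (1 - fy) * fx +
    px(y0 + 1, x0) * fy * (1 - fx) + px(y0 + 1, x0 + 1) * fy * fx
  matrix(v, h, w)
}

#' Randomly augment a preprocessed image
#'
#' Applies a random sequence of one to three distinct transformations drawn
#' from horizontal flip, vertical flip, and rotation by an angle uniform in
#' `[-30, 30]` degrees. The number of transformations is uniform on
#' `{1, 2, 3}` and they are sampled without replacement in random order.
#'
#' @param pixels Preprocessed matrix in `[0, 1]`.
#' @param seed Optional integer seed; when given the augmentation is a pure
#'   function of `(pixels, seed)`.
#' @return Augmented matrix, same shape, values in `[0, 1]`, with the
#'   applied transformation sequence in attribute `ops` and the rotation
#'   angle (degrees, `NA` if no rotation was drawn) in attribute `angle`.
#' @export
augment_image <- function(pixels, seed = NULL) {
  with_seed(seed, {
    k <- sample.int(3L, 1L)
    ops <- sample(c("hflip", "vflip", "rotate"), k)
    angle <- NA_real_
    for (op in ops) {
      pixels <- switch(op,
        hflip = pixels[, rev(seq_len(ncol(pixels))), drop = FALSE],
        vflip = pixels[rev(seq_len(nrow(pixels))), , drop = FALSE],
        rotate = {
          angle <- stats::runif(1, -30, 30)
          rotate_image(pixels, angle)
        }
      )
    }
    structure(clip01(pixels), ops = ops, angle = angle)
  })
}
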