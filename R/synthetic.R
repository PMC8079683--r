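# Seeded generator of radiograph-like multi-view studies, planted
# abnormality signals with ground-truth bounding boxes, and controlled
# prediction tables with analytically known separability.
#
# The images caricature — and do not claim clinical realism for — the three
# broad abnormality families of upper-extremity radiographs: a dark break
# across the bone ridge (fracture-like line discontinuity), a bright ellipse
# (implanted hardware), and a high-frequency patch (degenerative texture
# roughening).

#' Region signal specification
#'
#' @param region Region name.
#' @param signal_family One of `"line_discontinuity"`, `"bright_implant"`,
#'   `"texture_roughening"`.
#' @param snr Signal amplitude in units of the background pixel-noise
#'   standard deviation; must be positive.
#' @param lesion_size_range Pixel bounds (min, max) of the lesion extent.
#' @return A `region_signal_spec` list.
#' @export
region_signal_spec <- function(region,
                               signal_family = c("bright_implant",
                                                 "line_discontinuity",
                                                 "texture_roughening"),
                               snr = 4, lesion_size_range = c(8L, 16L)) {
  signal_family <- match.arg(signal_family)
  stopifnot(snr > 0, length(lesion_size_range) == 2L,
            lesion_size_range[1] <= lesion_size_range[2])
  structure(list(region = region, signal_family = signal_family, snr = snr,
                 lesion_size_range = as.integer(lesion_size_range)),
            class = "region_signal_spec")
}

#' Generator configuration
#'
#' Defaults state the desk-scale world: seven regions, each with
#' 40 abnormal + 60 normal training images, 20 + 30 validation and
#' 20 + 30 test, grouped into studies of 1-4 views, rendered at 64x64
#' (the 256x256 reference size is a parameter away).
#'
#' @param regions List of [region_signal_spec()]s; by default the seven
#'   upper-extremity regions with the three signal families cycled.
#' @param n_train,n_validation,n_test Per-region image counts
#'   `c(abnormal, normal)`; matched exactly, not in expectation.
#' @param image_size Square image side in pixels.
#' @param noise_sd Background pixel-noise standard deviation.
#' @param max_views Maximum views per study (views are 1..max_views).
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(regions = NULL,
                             n_train = c(abnormal = 40L, normal = 60L),
                             n_validation = c(abnormal = 20L, normal = 30L),
                             n_test = c(abnormal = 20L, normal = 30L),
                             image_size = 64L, noise_sd = 0.05,
                             max_views = 4L, seed = 1L) {
  if (is.null(regions)) {
    fams <- rep(c("bright_implant", "line_discontinuity",
                  "texture_roughening"), length.out = 7L)
    regions <- lapply(seq_along(UPPER_EXTREMITY_REGIONS), function(i) {
      region_signal_spec(UPPER_EXTREMITY_REGIONS[i], fams[i])
    })
  }
  stopifnot(length(regions) >= 1L, image_size >= 16L, noise_sd > 0,
            max_views >= 1L)
  total <- sum(n_train) + sum(n_validation) + sum(n_test)
  assert_that(total > 0, "config generates zero images")
  structure(list(regions = regions,
                 n_train = n_train, n_validation = n_validation,
                 n_test = n_test, image_size = as.integer(image_size),
                 noise_sd = noise_sd, max_views = as.integer(max_views),
                 seed = as.integer(seed)),
            class = "generator_config")
}

gaussian_blur <- function(mat, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (o in -half:half) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      m[cbind(idx[ok], j[ok])] <- m[cbind(idx[ok], j[ok])] + k[o + half + 1]
    }
    m / rowSums(m)  # renormalize at the borders
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

# Smooth bone-like ridge plus correlated and pixel noise; values in [0, 1].
# Draws from the current RNG stream.
synth_background <- function(size, noise_sd = 0.05) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  cx <- size / 2 + stats::runif(1, -0.08, 0.08) * size
  bend <- stats::runif(1, -0.06, 0.06) * size
  phase <- stats::runif(1, 0, 2 * pi)
  center <- cx + bend * sin(rows / size * pi + phase)
  width <- size * stats::runif(1, 0.22, 0.32)
  ridge <- 0.2 + 0.55 * exp(-((cols - center) / width)^2)
  slow <- gaussian_blur(matrix(stats::rnorm(size^2), size, size), size / 8) *
    0.3
  clip01(ridge + slow + stats::rnorm(size^2, sd = noise_sd))
}

draw_lesion_params <- function(spec, size) {
  len <- stats::runif(1, spec$lesion_size_range[1], spec$lesion_size_range[2])
  margin <- ceiling(len / 2) + 2L
  assert_that(2L * margin < size, "lesion larger than image")
  list(center = c(stats::runif(1, margin, size - margin),
                  stats::runif(1, margin, size - margin)),
       len = len,
       angle = stats::runif(1, 0, pi),
       aspect = stats::runif(1, 0.4, 0.8))
}

#' Plant an abnormality signal into an image
#'
#' Injects the region's signal family at a random (or given) location with
#' amplitude `snr * noise_sd` and returns the modified image together with
#' the tight bounding box of the modified pixels.
#'
#' @param image Matrix in `[0, 1]` (preprocessed scale).
#' @param spec A [region_signal_spec()].
#' @param noise_sd Background noise level the SNR is measured against.
#' @param params Optional lesion parameters (from a previous call) so that
#'   several views of one study share the same underlying lesion; small
#'   positional jitter is applied per view.
#' @return List with `image`, `box` (`c(r0, c0, r1, c1)`, 1-based,
#'   inclusive) and `params`.
#' @export
plant_abnormality <- function(image, spec, noise_sd = 0.05, params = NULL) {
  size <- nrow(image)
  if (is.null(params)) params <- draw_lesion_params(spec, size)
  amp <- spec$snr * noise_sd
  ctr <- params$center + stats::runif(2, -1, 1)
  ctr <- pmin(pmax(ctr, params$len / 2 + 2), size - params$len / 2 - 2)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (rows - ctr[1]) * cos(params$angle) + (cols - ctr[2]) * sin(params$angle)
  v <- -(rows - ctr[1]) * sin(params$angle) + (cols - ctr[2]) * cos(params$angle)
  half <- params$len / 2
  delta <- switch(spec$signal_family,
    bright_implant = {
      m <- (u / half)^2 + (v / (half * params$aspect))^2
      amp * exp(-pmax(m - 1, 0) * 4) * (m <= 1.6)
    },
    line_discontinuity = {
      inside <- abs(u) <= half & abs(v) <= 1.5
      -amp * 1.2 * inside * exp(-(v / 1.5)^2)
    },
    texture_roughening = {
      inside <- abs(u) <= half & abs(v) <= half
      patt <- matrix(stats::rnorm(size^2), size, size)
      amp * 1.2 * patt * inside
    }
  )
  out <- clip01(image + delta)
  changed <- which(abs(delta) > 1e-9, arr.ind = TRUE)
  assert_that(nrow(changed) > 0, "lesion produced no pixel change")
  box <- c(min(changed[, 1]), min(changed[, 2]),
           max(changed[, 1]), max(changed[, 2]))
  list(image = out, box = box, params = params)
}

# Partition n images into studies of 1..max_views views, exactly covering n.
partition_views <- function(n, max_views) {
  sizes <- integer(0)
  while (n > 0L) {
    v <- min(sample.int(max_views, 1L), n)
    sizes <- c(sizes, v)
    n <- n - v
  }
  sizes
}

#' Generate a synthetic radiograph-study dataset
#'
#' Writes grayscale PNG images, the standard CSV manifest and a bounding-box
#' CSV (`image_id, r0, c0, r1, c1`; abnormal images only) under `dir`.
#' Fully reproducible: the same config (including its seed) produces
#' byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return List with `manifest` (a `radcal_manifest`), `boxes` (data.frame),
#'   and the file paths `manifest_path`, `boxes_path`, `image_dir`.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "generator_config"))
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  boxes <- list()
  counter <- 0L
  patient <- 0L
  for (spec in config$regions) {
    for (split in SPLITS) {
      counts <- switch(split, train = config$n_train,
                       validation = config$n_validation,
                       test = config$n_test)
      for (label in c(1L, 0L)) {
        n_img <- unname(counts[[if (label == 1L) "abnormal" else "normal"]])
        if (n_img == 0L) next
        sizes <- with_seed(derive_seed(config$seed, counter * 7919L + 1L),
                           partition_views(n_img, config$max_views))
        counter <- counter + 1L
        for (s in seq_along(sizes)) {
          patient <- patient + 1L
          study_id <- sprintf("%s_p%05d_s1", tolower(spec$region), patient)
          study_seed <- derive_seed(config$seed, patient * 104729L)
          params <- if (label == 1L) {
            with_seed(study_seed, draw_lesion_params(spec, config$image_size))
          } else NULL
          for (vw in seq_len(sizes[s])) {
            counter <- counter + 1L
            image_id <- sprintf("%s_v%d", study_id, vw)
            res <- with_seed(derive_seed(study_seed, vw), {
              img <- synth_background(config$image_size, config$noise_sd)
              if (label == 1L) {
                plant_abnormality(img, spec, config$noise_sd, params)
              } else {
                list(image = img, box = NULL)
              }
            })
            path <- file.path(img_dir, paste0(image_id, ".png"))
            write_image(res$image, path)
            rows[[length(rows) + 1L]] <- data.frame(
              image_id = image_id, path = path,
              patient_id = sprintf("p%05d", patient), study_id = study_id,
              region = spec$region, label = label, split = split,
              stringsAsFactors = FALSE)
            if (label == 1L) {
              boxes[[length(boxes) + 1L]] <- data.frame(
                image_id = image_id, r0 = res$box[1], c0 = res$box[2],
                r1 = res$box[3], c1 = res$box[4])
            }
          }
        }
      }
    }
  }
  manifest <- as_manifest(do.call(rbind, rows),
                          region_set = vapply(config$regions,
                                              function(s) s$region,
                                              character(1)))
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(image_id = character(), r0 = integer(), c0 = integer(),
               r1 = integer(), c1 = integer())
  manifest_path <- file.path(dir, "manifest.csv")
  boxes_path <- file.path(dir, "boxes.csv")
  write_manifest(manifest, manifest_path)
  utils::write.csv(boxes, boxes_path, row.names = FALSE, quote = FALSE)
  list(manifest = manifest, boxes = boxes, manifest_path = manifest_path,
       boxes_path = boxes_path, image_dir = img_dir)
}

#' Matched-filter oracle score for a signal family
#'
#' A model-free detector used to certify that generated datasets are
#' learnable: difference-of-Gaussians blob contrast for bright implants
#' (negated for dark line breaks) and residual high-frequency energy for
#' texture roughening.
#'
#' @param image Matrix in `[0, 1]`.
#' @param signal_family Signal family name.
#' @return Scalar score; higher means more abnormal.
#' @export
matched_filter_score <- function(image, signal_family) {
  switch(signal_family,
    bright_implant = max(gaussian_blur(image, 1.5) - gaussian_blur(image, 4)),
    line_discontinuity = max(-gaussian_blur(image - gaussian_blur(image, 3), 1)),
    texture_roughening =
      max(gaussian_blur((image - gaussian_blur(image, 1.5))^2, 2)),
    stop(sprintf("unknown signal family: %s", signal_family))
  )
}

#' Analytic AUC of the binormal separability model
#'
#' Scores for normal studies are `N(-d/2, 1)` and for abnormal studies
#' `N(+d/2, 1)`; probabilities are the logistic transform of the scores
#' (rank-preserving), so the AUC is exactly `pnorm(d / sqrt(2))`, and the
#' 0.5 probability threshold sits at the midpoint of the two classes.
#'
#' @param d Separability (difference of class means in SD units).
#' @return AUC in `[0.5, 1)` for `d >= 0`.
#' @export
auc_from_separability <- function(d) stats::pnorm(d / sqrt(2))

#' @rdname auc_from_separability
#' @param auc Target AUC.
#' @export
separability_for_auc <- function(auc) sqrt(2) * stats::qnorm(auc)

#' Synthesize a controlled prediction table
#'
#' Draws study-level probabilities for several models from the binormal
#' separability model, so evaluation and ensembling can be exercised without
#' any training. Class prevalence is matched by exact counts.
#'
#' @param skill data.frame with columns `model`, `region`, `separability`
#'   (`d >= 0`; analytic AUC is `pnorm(d / sqrt(2))`).
#' @param n_studies Studies per region.
#' @param prevalence Abnormal fraction per region.
#' @param seed Integer seed.
#' @return Prediction table (`study_id`, `region`, `true_label`, `model_id`,
#'   `prob`).
#' @export
synth_prediction_table <- function(skill, n_studies = 60L, prevalence = 0.5,
                                   seed = 1L) {
  req <- c("model", "region", "separability")
  assert_that(all(req %in% names(skill)),
              "skill needs columns model, region, separability")
  assert_that(all(skill$separability >= 0), "separability must be >= 0")
  n_ab <- round(n_studies * prevalence)
  assert_that(n_ab >= 2L && n_studies - n_ab >= 2L,
              "need at least 2 studies per class per region")
  regions <- unique(skill$region)
  models <- unique(skill$model)
  rows <- list()
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    y <- c(rep(1L, n_ab), rep(0L, n_studies - n_ab))
    ids <- sprintf("%s_s%04d", tolower(r), seq_len(n_studies))
    for (mi in seq_along(models)) {
      m <- models[mi]
      d <- skill$separability[skill$model == m & skill$region == r]
      assert_that(length(d) == 1L,
                  sprintf("skill must have one row for model %s, region %s",
                          m, r))
      z <- with_seed(derive_seed(seed, ri * 1009L + mi),
                     stats::rnorm(n_studies, mean = d * (y - 0.5)))
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = ids, region = r, true_label = y, model_id = m,
        prob = stats::plogis(z), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
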