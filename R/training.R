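# Class-weighted loss and the training loop: Adam updates, early stopping on
# training-loss convergence, checkpointing on validation performance, and
# per-region fine-tuning from an overall model's weights.

#' Per-region class weights for the weighted cross-entropy loss
#'
#' Weights are inversely proportional to the class counts of the region's
#' training images: with `|N_t|` normal and `|A_t|` abnormal images of region
#' `t`, the abnormal-class weight is `w1 = |N_t| / (|N_t| + |A_t|)` and the
#' normal-class weight `w0 = |A_t| / (|N_t| + |A_t|)`; they sum to 1 exactly.
#'
#' @param manifest A `radcal_manifest`.
#' @param region Region name.
#' @param split Split on which counts are taken (default `train`).
#' @return List with `region`, `w0`, `w1`, `n_normal`, `n_abnormal`.
#' @export
compute_class_weights <- function(manifest, region, split = "train") {
  df <- as.data.frame(manifest)
  df <- df[df$region == region & df$split == split, , drop = FALSE]
  n_ab <- sum(df$label == 1L)
  n_no <- sum(df$label == 0L)
  if (n_ab == 0L || n_no == 0L) {
    stop(sprintf("class weights undefined for region %s: %d abnormal, %d normal",
                 region, n_ab, n_no), call. = FALSE)
  }
  list(region = region, w0 = n_ab / (n_no + n_ab), w1 = n_no / (n_no + n_ab),
       n_normal = n_no, n_abnormal = n_ab)
}

class_weight_table <- function(manifest, split = "train") {
  regions <- unique(as.data.frame(manifest)$region[
    as.data.frame(manifest)$split == split])
  out <- lapply(regions, compute_class_weights, manifest = manifest,
                split = split)
  names(out) <- regions
  out
}

#' Region-weighted cross-entropy loss
#'
#' The sum over instances of
#' `- w1^t * y * ln p - w0^t * (1 - y) * ln(1 - p)`, where `t` is each
#' instance's region and `(w0^t, w1^t)` its region's class weights.
#' Probabilities are clipped to `[1e-7, 1 - 1e-7]` before the logarithm.
#' With all weights equal to 1 this is the standard (summed) cross-entropy.
#'
#' @param probs Positive-class probabilities.
#' @param labels Binary labels (0 = normal, 1 = abnormal).
#' @param weights Named list of per-region weights as returned by
#'   [class_weight_table()], or a single `list(w0 =, w1 =)` applied to all
#'   instances.
#' @param regions Per-instance region tags (required when `weights` is a
#'   per-region table).
#' @param reduce `"sum"` (the formula as stated) or `"mean"` (used per batch
#'   during optimization so the learning rate decouples from batch size).
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights = list(w0 = 1, w1 = 1),
                                   regions = NULL, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  assert_that(length(probs) == length(labels),
              "probs and labels must have the same length")
  if (!is.null(regions)) {
    assert_that(length(regions) == length(probs),
                "regions must match probs in length")
    w0 <- vapply(regions, function(r) weights[[r]]$w0, numeric(1))
    w1 <- vapply(regions, function(r) weights[[r]]$w1, numeric(1))
  } else {
    w0 <- rep(weights$w0, length(probs))
    w1 <- rep(weights$w1, length(probs))
  }
  p <- clip_prob(probs)
  terms <- -w1 * labels * log(p) - w0 * (1 - labels) * log(1 - p)
  if (reduce == "sum") sum(terms) else mean(terms)
}

#' Training configuration
#'
#' Adam hyper-parameters default to first/second-moment decay rates 0.9 and
#' 0.999 with learning rate 0.001; training runs for at most `max_epochs`
#' epochs with early stopping once the relative training-loss improvement
#' stays below `min_delta` for `patience` consecutive epochs, and the
#' checkpoint returned is the epoch with the best validation metric.
#'
#' @param batch_size Mini-batch size (32 by convention, 16 for the dense
#'   model; see [default_batch_size()]).
#' @param max_epochs Maximum number of epochs (reference value 100).
#' @param learning_rate,beta1,beta2 Adam hyper-parameters.
#' @param min_delta,patience Early-stopping criterion on the training loss.
#' @param checkpoint_metric `"auc"` (study-level validation AUC) or
#'   `"accuracy"`.
#' @param image_size Square input side in pixels (256 reference; smaller for
#'   desk-scale runs).
#' @param restore_best Restore the best-validation-epoch checkpoint at the
#'   end of training (the standard behaviour). Set to `FALSE` to keep the
#'   final epoch's weights, e.g. when training to saturation on purpose.
#' @param augment Apply random augmentation to training batches.
#' @param seed Integer seed governing shuffling and augmentation.
#' @param verbose Print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, max_epochs = 100L,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         min_delta = 1e-4, patience = 5L,
                         checkpoint_metric = c("auc", "accuracy"),
                         image_size = 256L, restore_best = TRUE,
                         augment = TRUE, seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            max_epochs >= 0, batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 min_delta = min_delta, patience = as.integer(patience),
                 checkpoint_metric = match.arg(checkpoint_metric),
                 image_size = as.integer(image_size),
                 restore_best = isTRUE(restore_best),
                 augment = isTRUE(augment), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Stream one epoch of image batches
#'
#' Returns an iterator over the records of one split in a per-epoch shuffled
#' order. Images are loaded from disk one batch at a time (never more than a
#' batch of pixels in memory), preprocessed, and optionally augmented; the
#' last batch may be short. Identical seeds give identical orders.
#'
#' @param manifest A `radcal_manifest`.
#' @param batch_size Batch size.
#' @param seed Integer seed for the shuffle (and the augmentation stream).
#' @param augment Apply random augmentation.
#' @param split Which split to stream (default `train`).
#' @param image_size Preprocessing target side.
#' @return List with `n_batches`, `n`, and `next_batch()`, which returns
#'   `list(x, y, region, study_id)` with `x` an `(b, s, s, 1)` array, or
#'   `NULL` after the last batch.
#' @export
batch_stream <- function(manifest, batch_size, seed = 1L, augment = FALSE,
                         split = "train", image_size = 64L) {
  df <- as.data.frame(manifest)
  df <- df[df$split == split, , drop = FALSE]
  assert_that(nrow(df) > 0, sprintf("no records in split '%s'", split))
  order_idx <- with_seed(derive_seed(seed, 1L), sample.int(nrow(df)))
  df <- df[order_idx, , drop = FALSE]
  n <- nrow(df)
  n_batches <- ceiling(n / batch_size)
  b <- 0L
  next_batch <- function() {
    if (b >= n_batches) return(NULL)
    b <<- b + 1L
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    x <- array(0, c(length(idx), image_size, image_size, 1L))
    for (j in seq_along(idx)) {
      img <- preprocess_image(read_image(df$path[idx[j]]), size = image_size)
      if (augment) img <- augment_image(img, seed = derive_seed(seed, idx[j] * 7L + b))
      x[j, , , 1L] <- img
    }
    list(x = x, y = df$label[idx], region = df$region[idx],
         study_id = df$study_id[idx])
  }
  list(n_batches = n_batches, n = n, next_batch = next_batch)
}

validation_metric <- function(model, manifest, config, split = "validation",
                              metric = config$checkpoint_metric) {
  preds <- predict_manifest(model, manifest, split = split,
                            image_size = config$image_size,
                            batch_size = config$batch_size)
  sp <- study_predictions(preds)
  if (metric == "auc" && length(unique(sp$true_label)) == 2L) {
    roc_auc(sp$prob, sp$true_label)
  } else {
    mean(classify_study(sp$prob) == sp$true_label)
  }
}

#' Train a model with the region-weighted loss
#'
#' Runs Adam on the weighted cross-entropy (batch mean), with per-region
#' class weights computed on the training split, per-epoch reshuffling from
#' a seed derived from `(config$seed, epoch)`, early stopping once the
#' relative training-loss improvement is below `config$min_delta` for
#' `config$patience` consecutive epochs, and checkpointing on the validation
#' metric: the returned model carries the weights of the best validation
#' epoch.
#'
#' @param spec An `arch_spec` (or an already built `trainable_model`, whose
#'   weights are the starting point — used for fine-tuning).
#' @param manifest A `radcal_manifest` with train and validation splits.
#' @param config A [train_config()].
#' @param region_filter Optional subset of regions to train on.
#' @return A `trained_model`: list with `model`, `history` (data.frame of
#'   `epoch`, `train_loss`, `val_metric`), `best_epoch`, `config`,
#'   `class_weights` and `trained_regions`.
#' @export
train_model <- function(spec, manifest, config = train_config(),
                        region_filter = NULL) {
  df <- as.data.frame(manifest)
  if (!is.null(region_filter)) {
    df <- df[df$region %in% region_filter, , drop = FALSE]
    manifest <- as_manifest(df, region_set = attr(manifest, "region_set"))
  }
  assert_that(sum(df$split == "train") > 0, "empty training split")
  assert_that(sum(df$split == "validation") > 0, "empty validation split")
  model <- if (inherits(spec, "trainable_model")) {
    clone_model(spec)
  } else {
    build_model(spec, seed = config$seed,
                input_shape = c(config$image_size, config$image_size, 1L))
  }
  cw <- class_weight_table(manifest, split = "train")
  players <- param_layers(model$layers)
  adam_init(players)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_metric = numeric())
  best <- list(metric = -Inf, epoch = 0L, weights = get_weights(model))
  step <- 0L
  stall <- 0L
  prev_loss <- NA_real_
  for (epoch in seq_len(config$max_epochs)) {
    stream <- batch_stream(manifest, config$batch_size,
                           seed = derive_seed(config$seed, epoch),
                           augment = config$augment, split = "train",
                           image_size = config$image_size)
    epoch_loss <- 0
    n_seen <- 0L
    while (!is.null(bt <- stream$next_batch())) {
      fw <- model_forward(model, bt$x, training = TRUE, want_caches = TRUE)
      p <- clip_prob(as.vector(fw$out))
      w0 <- vapply(bt$region, function(r) cw[[r]]$w0, numeric(1))
      w1 <- vapply(bt$region, function(r) cw[[r]]$w1, numeric(1))
      nb <- length(p)
      loss <- mean(-w1 * bt$y * log(p) - w0 * (1 - bt$y) * log(1 - p))
      dLdp <- (w0 * (1 - bt$y) / (1 - p) - w1 * bt$y / p) / nb
      model_backward(model, fw$caches, matrix(dLdp, nb, 1L))
      step <- step + 1L
      adam_step(players, step, lr = config$learning_rate,
                beta1 = config$beta1, beta2 = config$beta2)
      epoch_loss <- epoch_loss + loss * nb
      n_seen <- n_seen + nb
    }
    epoch_loss <- epoch_loss / n_seen
    vm <- validation_metric(model, manifest, config)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_metric = vm))
    if (config$verbose) {
      rc_log(sprintf("epoch %d: train loss %.5f, val %s %.4f", epoch,
                     epoch_loss, config$checkpoint_metric, vm))
    }
    if (vm > best$metric) {
      best <- list(metric = vm, epoch = epoch, weights = get_weights(model))
    }
    if (!is.na(prev_loss)) {
      rel_impr <- (prev_loss - epoch_loss) / max(abs(prev_loss), 1e-12)
      stall <- if (rel_impr < config$min_delta) stall + 1L else 0L
      if (stall >= config$patience) break
    }
    prev_loss <- epoch_loss
  }
  if (isTRUE(config$restore_best %||% TRUE)) set_weights(model, best$weights)
  structure(list(model = model, history = history,
                 best_epoch = if (nrow(history)) best$epoch else 0L,
                 config = config, class_weights = cw,
                 trained_regions = sort(unique(df$region[df$split == "train"]))),
            class = "trained_model")
}

#' Fine-tune an overall model on one region
#'
#' Initializes from the overall model's weights (a deep copy; the overall
#' model is untouched) and continues training on the region's records only,
#' checkpointing on the region's validation subset. With `max_epochs = 0`
#' the result is an exact copy of the overall model.
#'
#' @param overall A `trained_model` trained on all regions.
#' @param manifest A `radcal_manifest`.
#' @param region Region to calibrate on.
#' @param config A [train_config()].
#' @return A `trained_model` restricted to `region`.
#' @export
fine_tune_region <- function(overall, manifest, region,
                             config = overall$config) {
  stopifnot(inherits(overall, "trained_model"))
  df <- as.data.frame(manifest)
  assert_that(region %in% df$region,
              sprintf("region %s absent from manifest", region))
  if (config$max_epochs == 0L) {
    out <- clone_model(overall)
    out$history <- data.frame(epoch = integer(), train_loss = numeric(),
                              val_metric = numeric())
    out$best_epoch <- 0L
    out$trained_regions <- region
    return(out)
  }
  train_model(overall$model, manifest, config = config,
              region_filter = region)
}

#' Image- and study-level predictions for a manifest split
#'
#' @param model A `trainable_model` or `trained_model`.
#' @param manifest A `radcal_manifest`.
#' @param split Split to predict on.
#' @param image_size Preprocessing target side.
#' @param batch_size Prediction batch size.
#' @return data.frame with one row per image: `image_id`, `study_id`,
#'   `region`, `true_label`, `prob`.
#' @export
predict_manifest <- function(model, manifest, split = "test",
                             image_size = 64L, batch_size = 32L) {
  df <- as.data.frame(manifest)
  df <- df[df$split == split, , drop = FALSE]
  assert_that(nrow(df) > 0, sprintf("no records in split '%s'", split))
  net <- as_trainable(model)
  probs <- numeric(nrow(df))
  for (start in seq(1L, nrow(df), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(df))
    x <- array(0, c(length(idx), image_size, image_size, 1L))
    for (j in seq_along(idx)) {
      x[j, , , 1L] <- preprocess_image(read_image(df$path[idx[j]]),
                                       size = image_size)
    }
    probs[idx] <- predict_proba(net, x)
  }
  data.frame(image_id = df$image_id, study_id = df$study_id,
             region = df$region, true_label = df$label, prob = probs,
             stringsAsFactors = FALSE)
}

#' Aggregate image-level predictions to study level
#'
#' A study's abnormality probability is the mean of its views' positive-class
#' probabilities.
#'
#' @param preds data.frame from [predict_manifest()].
#' @return data.frame with one row per study: `study_id`, `region`,
#'   `true_label`, `prob`.
#' @export
study_predictions <- function(preds) {
  agg <- stats::aggregate(prob ~ study_id + region + true_label, data = preds,
                          FUN = mean)
  agg[order(agg$study_id), , drop = FALSE]
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(paste0("<trained_model> %s: %d epoch(s), best epoch %d ",
                     "(val %s %.4f), regions: %s\n"),
              x$model$spec$name, nrow(x$history), x$best_epoch,
              x$config$checkpoint_metric,
              if (nrow(x$history)) max(x$history$val_metric) else NA_real_,
              paste(x$trained_regions, collapse = ", ")))
  invisible(x)
}
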