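# Ensembling: the Res+Dense probability-averaging rule and the calibrated
# per-region learner designation (best validation performance in at least
# two of three metrics) with routed prediction.

#' Average two models' probabilities (Res+Dense rule)
#'
#' The ensemble probability is the mean of the two scores and the label is
#' 1 iff their sum reaches 1 (boundary inclusive), which is identical to
#' thresholding the mean at 0.5.
#'
#' @param p_r,p_d Probabilities in `[0, 1]` (vectorized).
#' @return List with `prob` and integer `label`.
#' @export
average_predict <- function(p_r, p_d) {
  stopifnot(length(p_r) == length(p_d),
            all(p_r >= 0 & p_r <= 1), all(p_d >= 0 & p_d <= 1))
  list(prob = (p_r + p_d) / 2, label = as.integer(p_r + p_d >= 1))
}

#' Designate a learner per region from validation metrics
#'
#' For each region, the candidate that is strictly best (beyond a small
#' tolerance) in at least two of the three validation metrics (AUC,
#' accuracy, kappa) is designated. Exact ties within a metric award the win
#' to no one. If no candidate collects two wins, the tie-break is highest
#' AUC, then first in candidate order.
#'
#' @param validation_metrics data.frame with columns `model`, `region`,
#'   `auc`, `accuracy`, `kappa`; candidate order is the order of first
#'   appearance in `model`.
#' @param tol Tolerance below which two metric values are considered tied.
#' @return data.frame (`region`, `model`) with the full per-candidate metric
#'   triplets attached as attribute `provenance`.
#' @export
designate_learners <- function(validation_metrics, tol = 1e-9) {
  req <- c("model", "region", "auc", "accuracy", "kappa")
  missing_cols <- setdiff(req, names(validation_metrics))
  assert_that(length(missing_cols) == 0,
              sprintf("validation metrics missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  vm <- as.data.frame(validation_metrics)
  candidates <- unique(vm$model)
  assert_that(length(candidates) >= 2, "need at least two candidate models")
  regions <- unique(vm$region)
  metrics <- c("auc", "accuracy", "kappa")
  rows <- list()
  for (r in regions) {
    vr <- vm[vm$region == r, , drop = FALSE]
    for (m in candidates) {
      for (met in metrics) {
        v <- vr[[met]][vr$model == m]
        if (length(v) != 1L || is.na(v)) {
          stop(sprintf("missing validation metric: model %s, region %s, %s",
                       m, r, met), call. = FALSE)
        }
      }
    }
    vr <- vr[match(candidates, vr$model), , drop = FALSE]
    wins <- integer(length(candidates))
    for (met in metrics) {
      v <- vr[[met]]
      best <- max(v)
      leaders <- which(v > best - tol)
      if (length(leaders) == 1L) wins[leaders] <- wins[leaders] + 1L
    }
    pick <- which(wins >= 2L)
    if (length(pick) == 0L) {
      # fallback: highest AUC, ties broken by candidate order
      auc_best <- max(vr$auc)
      pick <- which(vr$auc > auc_best - tol)[1L]
    } else {
      pick <- pick[1L]
    }
    rows[[length(rows) + 1L]] <- data.frame(region = r,
                                            model = candidates[pick],
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- vm
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Write / read a selection table as CSV
#'
#' The per-candidate validation triplets used for designation travel with
#' the table.
#'
#' @param selection A `selection_table`.
#' @param path File path.
#' @return `path` invisibly / a `selection_table`.
#' @export
write_selection <- function(selection, path) {
  prov <- attr(selection, "provenance")
  merged <- merge(as.data.frame(selection), prov, by = "region")
  names(merged)[names(merged) == "model.x"] <- "designated_model"
  names(merged)[names(merged) == "model.y"] <- "candidate"
  utils::write.csv(merged[order(merged$region, merged$candidate), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  sel <- unique(df[, c("region", "designated_model")])
  names(sel)[2] <- "model"
  prov <- df[, c("candidate", "region", "auc", "accuracy", "kappa")]
  names(prov)[1] <- "model"
  rownames(sel) <- NULL
  attr(sel, "provenance") <- prov
  class(sel) <- c("selection_table", "data.frame")
  sel
}

#' Routed prediction with the calibrated ensemble
#'
#' Routes all views of a study to the learner designated for its region,
#' averages the view probabilities, and thresholds at 0.5.
#'
#' @param study List with `region` and `images`, an `(n_views, s, s, 1)`
#'   array (or a single matrix) of preprocessed views.
#' @param selection A `selection_table` from [designate_learners()].
#' @param region_models Named list `region -> model` of fine-tuned models
#'   (`trainable_model` or `trained_model`).
#' @return List with `prob`, `label` and `model_id` (provenance of the
#'   routing).
#' @export
calibrated_predict <- function(study, selection, region_models) {
  region <- study$region
  sel <- as.data.frame(selection)
  assert_that(region %in% sel$region,
              sprintf("no designated learner for region %s", region))
  model_id <- sel$model[sel$region == region][1L]
  assert_that(region %in% names(region_models),
              sprintf("no fine-tuned model supplied for region %s", region))
  model <- region_models[[region]]
  probs <- predict_proba(model, as_batch_array(study$images))
  p <- study_probability(probs)
  list(prob = p, label = classify_study(p), model_id = model_id)
}

#' Calibrated predictions for a manifest split
#'
#' @param manifest A `radcal_manifest`.
#' @param selection A `selection_table`.
#' @param region_models Named list `region -> model` of fine-tuned models.
#' @param split Split to predict on.
#' @param image_size Preprocessing target side.
#' @return Study-level prediction table (`study_id`, `region`, `true_label`,
#'   `model_id = "calibrated"`, `prob`) with per-study routing recorded in
#'   column `routed_model`.
#' @export
predict_calibrated <- function(manifest, selection, region_models,
                               split = "test", image_size = 64L) {
  df <- as.data.frame(manifest)
  df <- df[df$split == split, , drop = FALSE]
  assert_that(nrow(df) > 0, sprintf("no records in split '%s'", split))
  sel <- as.data.frame(selection)
  rows <- list()
  for (st in split(df, df$study_id)) {
    region <- st$region[1L]
    x <- array(0, c(nrow(st), image_size, image_size, 1L))
    for (j in seq_len(nrow(st))) {
      x[j, , , 1L] <- preprocess_image(read_image(st$path[j]),
                                       size = image_size)
    }
    res <- calibrated_predict(list(region = region, images = x),
                              selection, region_models)
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = st$study_id[1L], region = region,
      true_label = st$label[1L], model_id = "calibrated",
      prob = res$prob, routed_model = res$model_id,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
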