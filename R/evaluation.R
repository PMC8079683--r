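# Study-level decisioning and the five evaluation metrics (ROC-AUC,
# accuracy, precision, recall, Cohen's kappa), plus percent-change tables
# against a baseline model.

#' Study-level abnormality probability
#'
#' The arithmetic mean of the positive-class probabilities of all views in
#' the study.
#'
#' @param view_probs Non-empty numeric vector of per-view probabilities.
#' @return Scalar probability.
#' @export
study_probability <- function(view_probs) {
  assert_that(length(view_probs) > 0, "study has no view probabilities")
  mean(view_probs)
}

#' Threshold a study probability into a label
#'
#' The boundary is inclusive: a probability of exactly 0.5 is classified
#' abnormal.
#'
#' @param prob Probabilities in `[0, 1]` (vectorized).
#' @param threshold Decision threshold (default 0.5).
#' @return Integer labels in `{0, 1}`.
#' @export
classify_study <- function(prob, threshold = 0.5) {
  as.integer(prob >= threshold)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with ties
#' counted half.
#'
#' @param scores Numeric scores (higher = more abnormal).
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  assert_that(length(scores) == length(labels),
              "scores and labels must have the same length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  assert_that(n_pos > 0 && n_neg > 0,
              "roc_auc requires both classes to be present")
  r <- rank(scores)  # midranks give half credit to tied pairs
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores,labels As in [roc_auc()].
#' @return data.frame of `threshold`, `fpr`, `tpr` over all distinct scores.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- t(vapply(th, function(t0) {
    pred <- scores >= t0
    c(fpr = sum(pred & labels == 0L) / max(sum(labels == 0L), 1L),
      tpr = sum(pred & labels == 1L) / max(sum(labels == 1L), 1L))
  }, numeric(2)))
  data.frame(threshold = th, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

#' Accuracy, precision and recall from binary predictions
#'
#' Precision with zero positive predictions is reported as 0 with a warning
#' (the strict formula is undefined there).
#'
#' @param preds,labels Binary vectors of equal length.
#' @return List with `accuracy`, `precision`, `recall`.
#' @export
confusion_metrics <- function(preds, labels) {
  assert_that(length(preds) == length(labels) && length(preds) > 0,
              "preds and labels must be non-empty and of equal length")
  preds <- as.integer(preds); labels <- as.integer(labels)
  tp <- sum(preds == 1L & labels == 1L)
  tn <- sum(preds == 0L & labels == 0L)
  fp <- sum(preds == 1L & labels == 0L)
  fn <- sum(preds == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) {
    warning("no positive predictions; precision reported as 0", call. = FALSE)
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  list(accuracy = (tp + tn) / length(preds), precision = precision,
       recall = recall)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement and `p_e` the chance agreement from the two marginal
#' distributions. When both vectors are constant and identical (`p_e = 1`,
#' perfect agreement) kappa is defined as 1.
#'
#' @param preds,labels Binary vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(preds, labels) {
  assert_that(length(preds) == length(labels) && length(preds) > 0,
              "preds and labels must be non-empty and of equal length")
  preds <- as.integer(preds); labels <- as.integer(labels)
  n <- length(preds)
  p_o <- mean(preds == labels)
  p_e <- mean(preds == 1L) * mean(labels == 1L) +
    mean(preds == 0L) * mean(labels == 0L)
  if (p_e >= 1 - 1e-15) {
    if (p_o >= 1 - 1e-15) return(1)
    stop("kappa undefined: chance agreement is 1 but agreement is imperfect",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Percent change against a baseline score
#'
#' `100 * (p_m - p_base) / p_base`, rounded half away from zero to the
#' nearest integer percent (the convention used when such improvements are
#' tabulated).
#'
#' @param p_m Model score.
#' @param p_base Baseline score; must be positive.
#' @param digits `0` for integer percent (default); `NA` for unrounded.
#' @return Percent change.
#' @export
percent_change <- function(p_m, p_base, digits = 0) {
  assert_that(all(p_base > 0), "percent_change requires a positive baseline")
  delta <- 100 * (p_m - p_base) / p_base
  if (is.na(digits)) return(delta)
  if (digits == 0) round_half_away(delta) else round(delta, digits)
}

metric_row <- function(probs, labels) {
  preds <- classify_study(probs)
  if (length(unique(labels)) < 2L) {
    return(list(auc = NA_real_, accuracy = NA_real_, precision = NA_real_,
                recall = NA_real_, kappa = NA_real_))
  }
  cm <- withCallingHandlers(confusion_metrics(preds, labels),
                            warning = function(w) invokeRestart("muffleWarning"))
  list(auc = roc_auc(probs, labels), accuracy = cm$accuracy,
       precision = cm$precision, recall = cm$recall,
       kappa = cohens_kappa(preds, labels))
}

#' Evaluate a prediction table
#'
#' Computes the five metrics for every model, overall and per region, and a
#' percent-change table of each model's overall metrics against a baseline
#' model. Regions where only one class is present are reported with `NA`
#' metrics rather than dropped.
#'
#' @param table Prediction table: data.frame with columns `study_id`,
#'   `region`, `true_label`, `model_id`, `prob` (one row per study and
#'   model).
#' @param baseline `model_id` of the baseline for the percent-change table.
#' @return List with `metrics` (data.frame `model_id`, `scope`, `auc`,
#'   `accuracy`, `precision`, `recall`, `kappa`) and `delta` (data.frame
#'   `model_id`, `metric`, `delta_pct`).
#' @export
evaluate <- function(table, baseline = NULL) {
  req <- c("study_id", "region", "true_label", "model_id", "prob")
  missing_cols <- setdiff(req, names(table))
  assert_that(length(missing_cols) == 0,
              sprintf("prediction table is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  models <- unique(table$model_id)
  if (!is.null(baseline)) {
    assert_that(baseline %in% models,
                sprintf("unknown baseline model: %s", baseline))
  }
  assert_that(length(unique(table$true_label)) == 2L,
              "evaluate requires both classes overall")
  scopes <- c("overall", sort(unique(table$region)))
  rows <- list()
  for (m in models) {
    tm <- table[table$model_id == m, , drop = FALSE]
    for (sc in scopes) {
      ts <- if (sc == "overall") tm else tm[tm$region == sc, , drop = FALSE]
      mr <- metric_row(ts$prob, ts$true_label)
      rows[[length(rows) + 1L]] <- data.frame(model_id = m, scope = sc,
                                              as.data.frame(mr))
    }
  }
  metrics <- do.call(rbind, rows)
  delta <- NULL
  if (!is.null(baseline)) {
    ov <- metrics[metrics$scope == "overall", , drop = FALSE]
    base <- ov[ov$model_id == baseline, , drop = FALSE]
    drows <- list()
    for (m in models) {
      mm <- ov[ov$model_id == m, , drop = FALSE]
      for (met in c("auc", "accuracy", "precision", "recall", "kappa")) {
        drows[[length(drows) + 1L]] <- data.frame(
          model_id = m, metric = met,
          delta_pct = percent_change(mm[[met]], base[[met]]))
      }
    }
    delta <- do.call(rbind, drows)
  }
  list(metrics = metrics, delta = delta)
}
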