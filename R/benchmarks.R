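# Published reference numbers for the public MURA musculoskeletal radiograph
# benchmark, shipped as plain CSV so worked examples (dataset bookkeeping,
# percent-change tables, learner designation) run without the dataset.

extdata_csv <- function(name, ...) {
  path <- system.file("extdata", name, package = "radcal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, ...)
}

#' Published MURA image counts per region and split
#'
#' Abnormal/normal image counts of the seven upper-extremity regions in the
#' train, validation and test splits of the public MURA benchmark. Totals
#' are derived by summation, not stored.
#'
#' @return data.frame with columns `region`, `split`, `abnormal`, `normal`.
#' @export
mura_image_counts <- function() extdata_csv("mura_image_counts.csv")

#' Reference overall test scores of the five models on MURA
#'
#' Overall test-set scores (AUC, accuracy, precision, recall, Cohen's kappa)
#' reported for the three baselines, the probability-averaging Res+Dense
#' ensemble, and the calibrated per-region ensemble; used as the worked
#' example for [percent_change()] tables.
#'
#' @return data.frame with columns `model`, `metric`, `score`.
#' @export
mura_overall_scores <- function() extdata_csv("mura_overall_scores.csv")

#' Reference per-region validation metrics of the three baselines on MURA
#'
#' AUC, accuracy and Cohen's kappa of ConvNet, ResNet and DenseNet on the
#' MURA validation split, per region — the input of the 2-of-3 designation
#' rule ([designate_learners()]).
#'
#' @return data.frame with columns `model`, `region`, `auc`, `accuracy`,
#'   `kappa`.
#' @export
mura_validation_metrics <- function() extdata_csv("mura_validation_metrics.csv")
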