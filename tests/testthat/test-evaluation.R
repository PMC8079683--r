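test_that("study probability is the view mean and the threshold is inclusive", {
  expect_equal(study_probability(c(0.6, 0.8)), 0.7)
  expect_equal(study_probability(0.42), 0.42)
  expect_equal(study_probability(c(0, 1, 0.5, 0.5)), 0.5)
  expect_error(study_probability(numeric(0)), "no view")
  expect_equal(classify_study(c(0.7, 0.49, 0.5)), c(1L, 0L, 1L))
})

test_that("roc_auc equals brute-force pair enumeration", {
  brute <- function(scores, labels) {
    sp <- scores[labels == 1]; sn <- scores[labels == 0]
    mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
  }
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)  # all ties
  set.seed(41)
  for (i in 1:20) {
    n <- 200L
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(stats::runif(n), 1)   # coarse grid forces ties
    expect_equal(roc_auc(scores, labels), brute(scores, labels))
  }
  expect_error(roc_auc(1:3 / 4, c(1, 1, 1)), "both classes")
})

test_that("roc_auc invariances hold", {
  set.seed(42)
  labels <- rep(c(0, 1), 25)
  scores <- stats::runif(50)              # continuous, tie-free a.s.
  a <- roc_auc(scores, labels)
  expect_equal(a + roc_auc(-scores, labels), 1)
  # invariant under strictly increasing transforms
  expect_equal(roc_auc(stats::qlogis(scores), labels), a)
  expect_equal(roc_auc(exp(3 * scores), labels), a)
})

test_that("confusion metrics and their conventions", {
  preds <- rep(c(1, 0, 1, 0), c(40, 40, 10, 10))
  labels <- rep(c(1, 0, 0, 1), c(40, 40, 10, 10))
  cm <- confusion_metrics(preds, labels)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$precision, 0.8)
  expect_equal(cm$recall, 0.8)
  expect_warning(cm0 <- confusion_metrics(c(0, 0), c(1, 0)), "precision")
  expect_equal(cm0$precision, 0)
  expect_equal(cm0$recall, 0)
  cmp <- confusion_metrics(labels, labels)
  expect_equal(unlist(cmp), c(accuracy = 1, precision = 1, recall = 1))
})

test_that("Cohen's kappa matches the p_o/p_e closed form", {
  labels <- rep(c(1, 0, 0, 1), c(40, 40, 10, 10))
  preds <- rep(c(1, 0, 1, 0), c(40, 40, 10, 10))
  expect_equal(cohens_kappa(preds, labels), 0.6)       # p_o=.8, p_e=.5
  expect_equal(cohens_kappa(labels, labels), 1.0)
  expect_equal(cohens_kappa(1 - rep(c(0, 1), 10), rep(c(0, 1), 10)), -1.0)
  # random confusion matrices against an independent marginal computation
  set.seed(7)
  for (i in 1:25) {
    cts <- stats::rmultinom(1, 200, stats::runif(4, 0.05, 1))[, 1]
    preds <- rep(c(1, 0, 1, 0), cts)
    labels <- rep(c(1, 1, 0, 0), cts)
    tab <- table(factor(preds, 0:1), factor(labels, 0:1)) / 200
    p_o <- sum(diag(tab)); p_e <- sum(rowSums(tab) * colSums(tab))
    expect_close(cohens_kappa(preds, labels), (p_o - p_e) / (1 - p_e),
                 tol = 1e-12)
  }
  # both raters constant and identical (p_e = 1, perfect): defined as 1;
  # with any disagreement the marginals move and p_e drops below 1, so the
  # chance-corrected value is computable (here 0)
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)
  expect_equal(cohens_kappa(rep(1, 5), c(1, 1, 1, 1, 0)), 0)
  # invariant to consistently swapping both vectors' class labels
  set.seed(8)
  p <- stats::rbinom(100, 1, 0.5); l <- stats::rbinom(100, 1, 0.5)
  expect_equal(cohens_kappa(p, l), cohens_kappa(1 - p, 1 - l))
})

test_that("percent change reproduces the published improvement figures", {
  expect_equal(percent_change(0.74, 0.63), 17)
  expect_equal(percent_change(0.93, 0.86), 8)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(percent_change(0.93, 0.88), 6)
  expect_error(percent_change(0.5, 0), "positive")
  # half-away-from-zero, not banker's rounding (0.125 is exact in binary)
  expect_equal(percent_change(1.125, 1), 13)
  expect_equal(percent_change(0.875, 1), -13)
})

test_that("evaluate reports per-model, per-scope metrics and deltas", {
  tbl <- data.frame(study_id = sprintf("s%02d", 1:20),
                    region = rep(c("Elbow", "Wrist"), each = 10),
                    true_label = rep(c(1, 0), 10),
                    model_id = "m1",
                    prob = rep(c(0.9, 0.1), 10))
  res <- evaluate(tbl, baseline = "m1")
  ov <- res$metrics[res$metrics$scope == "overall", ]
  expect_equal(unlist(ov[, c("auc", "accuracy", "precision", "recall",
                             "kappa")]),
               c(auc = 1, accuracy = 1, precision = 1, recall = 1, kappa = 1))
  expect_true(all(res$delta$delta_pct == 0))            # baseline vs itself
  expect_error(evaluate(tbl, baseline = "nope"), "unknown baseline")
  # a single-class region is reported as NA, not dropped
  tbl2 <- rbind(tbl, data.frame(study_id = sprintf("x%02d", 1:4),
                                region = "Hand", true_label = 1,
                                model_id = "m1", prob = 0.8))
  res2 <- evaluate(tbl2)
  hand <- res2$metrics[res2$metrics$scope == "Hand", ]
  expect_true(all(is.na(hand[, c("auc", "kappa")])))
  # overall on a one-region table equals that region's row
  one <- tbl[tbl$region == "Elbow", ]
  r1 <- evaluate(one)
  m <- r1$metrics
  expect_equal(m[m$scope == "overall", -(1:2)], m[m$scope == "Elbow", -(1:2)],
               ignore_attr = TRUE)
})

test_that("empirical AUC of the synthetic score model matches the closed form", {
  d <- separability_for_auc(0.9)
  tbl <- synth_prediction_table(
    data.frame(model = "m", region = "R1", separability = d),
    n_studies = 5000L, seed = 99L)
  a <- roc_auc(tbl$prob, tbl$true_label)
  expect_true(a >= 0.88 && a <= 0.92)
  expect_equal(auc_from_separability(d), 0.9)
  # no-signal case
  tbl0 <- synth_prediction_table(
    data.frame(model = "m", region = "R1", separability = 0),
    n_studies = 2000L, seed = 100L)
  expect_lt(abs(roc_auc(tbl0$prob, tbl0$true_label) - 0.5), 0.03)
})

test_that("roc_curve brackets the unit square and is monotone", {
  set.seed(12)
  scores <- stats::runif(60); labels <- rep(c(0, 1), 30)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})
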