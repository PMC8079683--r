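test_that("class weights are the closed-form rational values and sum to 1", {
  m <- as_manifest(make_manifest_df(1734L, 2584L))
  cw <- compute_class_weights(m, "Elbow")
  expect_equal(cw$w1, 2584 / 4318)
  expect_equal(cw$w0, 1734 / 4318)
  expect_equal(cw$w0 + cw$w1, 1)
  # balanced region
  mb <- as_manifest(make_manifest_df(100L, 100L, "Hand"))
  cwb <- compute_class_weights(mb, "Hand")
  expect_equal(cwb$w0, 0.5)
  expect_equal(cwb$w1, 0.5)
  # a class with zero instances is an error
  mz <- as_manifest(make_manifest_df(5L, 0L, "Wrist"))
  expect_error(compute_class_weights(mz, "Wrist"), "undefined")
  # property: weights from random manifests always sum to 1 exactly
  set.seed(31)
  for (i in 1:20) {
    mm <- as_manifest(make_manifest_df(sample(1:500, 1), sample(1:500, 1),
                                       "Finger"))
    cwi <- compute_class_weights(mm, "Finger")
    expect_identical(cwi$w0 + cwi$w1, 1)
  }
})

test_that("weighted cross-entropy evaluates the stated formula", {
  expect_close(weighted_cross_entropy(0.5, 1, list(w0 = 1, w1 = 0.5)),
               0.5 * log(2))
  expect_close(weighted_cross_entropy(0.5, 1,
                                      list(w0 = 1734 / 4318, w1 = 2584 / 4318)),
               (2584 / 4318) * log(2))
  # perfect prediction costs at most the clipping floor
  expect_lt(weighted_cross_entropy(c(1, 0), c(1, 0), list(w0 = 1, w1 = 1)),
            1e-6)
  expect_error(weighted_cross_entropy(c(0.5, 0.5), 1), "length")
})

test_that("unit weights reduce the loss to standard cross-entropy", {
  set.seed(17)
  for (i in 1:10) {
    n <- 50L
    p <- stats::runif(n, 0.01, 0.99)
    y <- stats::rbinom(n, 1, 0.5)
    ours <- weighted_cross_entropy(p, y, list(w0 = 1, w1 = 1))
    # independent implementation of plain summed cross-entropy
    ref <- -sum(y * log(p) + (1 - y) * log(1 - p))
    expect_close(ours, ref, tol = 1e-10)
  }
  # monotonicity: for y = 1 the loss strictly decreases in p
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) {
    weighted_cross_entropy(p, 1, list(w0 = 1, w1 = 1))
  }, numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_true(all(ls >= 0))
})

test_that("per-region weighting routes each instance through its region", {
  m <- as_manifest(rbind(make_manifest_df(10L, 30L, "Elbow"),
                         make_manifest_df(20L, 20L, "Wrist")))
  cw <- radcal:::class_weight_table(m)
  p <- c(0.3, 0.8); y <- c(1, 1); regions <- c("Elbow", "Wrist")
  got <- weighted_cross_entropy(p, y, cw, regions)
  expect_close(got, -(30 / 40) * log(0.3) - (20 / 40) * log(0.8), 1e-12)
})

test_that("training reduces the loss and is reproducible", {
  ds <- tiny_dataset()
  drops <- vapply(1:3, function(s) {
    tc <- train_config(batch_size = 8L, max_epochs = 3L, image_size = 24L,
                       learning_rate = 0.003, augment = FALSE, seed = s,
                       verbose = FALSE)
    tm <- train_model(tiny_spec(), ds$manifest, tc)
    tm$history$train_loss[3] - tm$history$train_loss[1]
  }, numeric(1))
  expect_lt(stats::median(drops), 0)     # 3-seed median guards stochastic slack

  tc <- train_config(batch_size = 8L, max_epochs = 2L, image_size = 24L,
                     augment = TRUE, seed = 9L, verbose = FALSE)
  t1 <- train_model(tiny_spec(), ds$manifest, tc)
  t2 <- train_model(tiny_spec(), ds$manifest, tc)
  expect_identical(t1$history, t2$history)
  expect_identical(get_weights(t1), get_weights(t2))
})

test_that("early stopping and checkpointing honour their contracts", {
  ds <- tiny_dataset()
  # a learning rate of ~0 freezes the loss up to batch-composition noise;
  # with a generous min_delta the loss counts as converged from epoch 2 on,
  # and patience 2 stops the run after epoch 3
  tc <- train_config(batch_size = 8L, max_epochs = 10L, image_size = 24L,
                     learning_rate = 1e-12, patience = 2L, min_delta = 0.5,
                     augment = FALSE, seed = 1L, verbose = FALSE)
  tm <- train_model(tiny_spec(), ds$manifest, tc)
  expect_equal(nrow(tm$history), 3L)
  # best_epoch is the argmax of the validation history
  tc2 <- train_config(batch_size = 8L, max_epochs = 4L, image_size = 24L,
                      learning_rate = 0.003, augment = FALSE, seed = 2L,
                      verbose = FALSE)
  tm2 <- train_model(tiny_spec(), ds$manifest, tc2)
  expect_equal(tm2$best_epoch, which.max(tm2$history$val_metric))
})

test_that("fine-tuning starts from the overall weights and trains one region only", {
  ds <- tiny_dataset()
  tc <- train_config(batch_size = 8L, max_epochs = 2L, image_size = 24L,
                     learning_rate = 0.003, augment = FALSE, seed = 3L,
                     verbose = FALSE)
  overall <- train_model(tiny_spec(), ds$manifest, tc)
  # zero-epoch fine-tune is an exact copy
  tc0 <- tc; tc0$max_epochs <- 0L
  ft0 <- fine_tune_region(overall, ds$manifest, "Elbow", tc0)
  x <- array(stats::runif(2 * 24 * 24), c(2L, 24L, 24L, 1L))
  expect_identical(predict_proba(ft0, x), predict_proba(overall, x))
  # a real fine-tune trains on the region's records only, and leaves the
  # overall model untouched
  p_before <- predict_proba(overall, x)
  tc1 <- tc; tc1$max_epochs <- 1L
  ft <- fine_tune_region(overall, ds$manifest, "Elbow", tc1)
  expect_identical(ft$trained_regions, "Elbow")
  expect_identical(predict_proba(overall, x), p_before)
  expect_error(fine_tune_region(overall, ds$manifest, "Femur"), "absent")
})

test_that("region fine-tuning preserves or improves the region's validation AUC", {
  # seeded synthetic experiment, 3-seed median, tolerance 0.02
  ds <- tiny_dataset()
  deltas <- vapply(1:3, function(s) {
    tc <- train_config(batch_size = 8L, max_epochs = 3L, image_size = 24L,
                       learning_rate = 0.003, augment = FALSE, seed = s,
                       verbose = FALSE)
    overall <- train_model(tiny_spec(), ds$manifest, tc)
    region_auc <- function(tm) {
      preds <- predict_manifest(tm, ds$manifest, split = "validation",
                                image_size = 24L)
      sp <- study_predictions(preds[preds$region == "Elbow", ])
      roc_auc(sp$prob, sp$true_label)
    }
    tcf <- tc; tcf$max_epochs <- 3L
    ft <- fine_tune_region(overall, ds$manifest, "Elbow", tcf)
    region_auc(ft) - region_auc(overall)
  }, numeric(1))
  expect_gte(stats::median(deltas), -0.02)
})
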