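test_that("load_manifest counts rows by class and validates the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_manifest_df(2L, 1L)
  write.csv(df, path, row.names = FALSE)
  m <- load_manifest(path)
  counts <- manifest_counts(m)
  expect_equal(counts$abnormal, 2L)
  expect_equal(counts$normal, 1L)

  # missing column named in the error
  bad <- df[, setdiff(names(df), "region")]
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_manifest(path), "region")

  # label outside {0,1} cited with its row number
  df2 <- make_manifest_df(3L, 2L)
  df2$label[5] <- 2L
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_manifest(path), "row\\(s\\).*5")

  # duplicate image id
  df3 <- make_manifest_df(2L, 2L)
  df3$image_id[2] <- df3$image_id[1]
  write.csv(df3, path, row.names = FALSE)
  expect_error(load_manifest(path), "duplicate image_id")
})

test_that("a manifest mirroring the published Elbow training counts returns them", {
  m <- as_manifest(make_manifest_df(1734L, 2584L))
  counts <- manifest_counts(m, split = "train")
  expect_equal(counts$abnormal[counts$region == "Elbow"], 1734L)
  expect_equal(counts$normal[counts$region == "Elbow"], 2584L)
  cw <- compute_class_weights(m, "Elbow")
  expect_equal(cw$w1, 2584 / 4318)
  expect_equal(cw$w0, 1734 / 4318)
})

test_that("write_manifest round-trips the rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- as_manifest(rbind(make_manifest_df(3L, 2L, "Elbow"),
                         make_manifest_df(2L, 4L, "Wrist", "test")))
  write_manifest(m, path)
  m2 <- load_manifest(path)
  expect_equal(as.data.frame(m2), as.data.frame(m), ignore_attr = TRUE)
})

test_that("manifest validation enforces study consistency", {
  df <- make_manifest_df(2L, 2L)
  df$study_id <- "same_study"         # mixes labels within one study
  expect_error(as_manifest(df), "inconsistent label")
})

test_that("scan_mura_tree parses the public layout", {
  root <- withr::local_tempdir()
  mk <- function(rel) {
    p <- file.path(root, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_image(matrix(0.5, 8, 8), p)
  }
  mk("train/XR_ELBOW/patient001/study1_positive/image1.png")
  mk("train/XR_ELBOW/patient001/study1_positive/image2.png")
  mk("train/XR_WRIST/patient002/study2_negative/image1.png")
  mk("train/XR_WRIST/patient002/study2_negative/image2.png")
  mk("train/XR_WRIST/patient003/study1_oddsuffix/image1.png")
  expect_warning(m <- scan_mura_tree(root), "suffix")
  df <- as.data.frame(m)
  expect_equal(nrow(df), 4L)
  expect_equal(length(unique(df$study_id)), 2L)
  expect_equal(unique(df$label[df$region == "Elbow"]), 1L)
  expect_equal(unique(df$label[df$region == "Wrist"]), 0L)
  expect_equal(unique(df$split), "train")

  mk("train/XR_SKULL/patient004/study1_positive/image1.png")
  expect_error(suppressWarnings(scan_mura_tree(root)), "unknown region")
  w <- capture_warnings(m2 <- scan_mura_tree(root, on_unknown_region = "skip"))
  expect_true(any(grepl("unknown region", w)))
  expect_equal(nrow(as.data.frame(m2)), 4L)
})

test_that("preprocess_image maps [0,255] to [0,1] at a fixed 256x256", {
  expect_equal(preprocess_image(matrix(255, 4, 4))[1, 1], 1.0)
  expect_equal(preprocess_image(matrix(0, 4, 4))[1, 1], 0.0)
  out <- preprocess_image(matrix(runif(512 * 132, 0, 255), 512, 132))
  expect_equal(dim(out), c(256L, 256L))
  expect_true(all(out >= 0 & out <= 1))
  # fixed scale, not per-image min-max: constant image stays constant
  expect_equal(unique(as.vector(preprocess_image(matrix(100, 7, 9), 16L))),
               100 / 255)
  # idempotent on already-normalized input of the target size
  once <- preprocess_image(matrix(runif(64 * 64, 0, 255), 64, 64), 64L)
  expect_equal(preprocess_image(once, 64L), once)
  expect_warning(preprocess_image(matrix(c(-3, 260, 100, 10), 2, 2), 2L),
                 "clipping")
  expect_error(preprocess_image(numeric(0)), "empty")
})

test_that("augmentation is seeded, bounded, and range-preserving", {
  img <- preprocess_image(matrix(runif(32 * 32, 0, 255), 32, 32), 32L)
  a1 <- augment_image(img, seed = 11L)
  a2 <- augment_image(img, seed = 11L)
  expect_identical(a1, a2)
  # flips are involutions; rotation by 0 is the identity
  expect_identical(img[, rev(seq_len(ncol(img)))][, rev(seq_len(ncol(img)))],
                   img)
  expect_equal(rotate_image(img, 0), img, tolerance = 1e-12)
  # sampler contract over 300 seeded draws: 1-3 distinct ops, angle in
  # [-30, 30], output in [0, 1]
  for (s in seq_len(300)) {
    a <- augment_image(img, seed = s)
    ops <- attr(a, "ops")
    expect_true(length(ops) %in% 1:3 && !anyDuplicated(ops))
    ang <- attr(a, "angle")
    if ("rotate" %in% ops) expect_true(ang >= -30 && ang <= 30)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(dim(a), dim(img))
  }
})

test_that("batch_stream shuffles per epoch, covers every record once", {
  ds <- tiny_dataset()
  df <- as.data.frame(ds$manifest)
  n_train <- sum(df$split == "train")
  st <- batch_stream(ds$manifest, batch_size = 3L, seed = 5L,
                     image_size = 24L)
  sizes <- integer(0); labels <- integer(0); ids <- character(0)
  while (!is.null(b <- st$next_batch())) {
    sizes <- c(sizes, dim(b$x)[1])
    labels <- c(labels, b$y)
    ids <- c(ids, b$study_id)
    expect_true(all(b$x >= 0 & b$x <= 1))
  }
  expect_equal(sizes, c(rep(3L, n_train %/% 3L),
                        if (n_train %% 3L) n_train %% 3L))
  # epoch coverage: label multiset equals the split's labels
  expect_equal(sort(labels), sort(df$label[df$split == "train"]))
  # same seed, same order
  st2 <- batch_stream(ds$manifest, batch_size = 3L, seed = 5L,
                      image_size = 24L)
  b1 <- st2$next_batch()
  st3 <- batch_stream(ds$manifest, batch_size = 3L, seed = 5L,
                      image_size = 24L)
  expect_identical(st3$next_batch()$study_id, b1$study_id)
  expect_error(batch_stream(ds$manifest, 4L, split = "nosuch"), "no records")
})

test_that("default batch size is 32, or 16 for the dense model", {
  expect_equal(default_batch_size("convnet"), 32L)
  expect_equal(default_batch_size("resnet"), 32L)
  expect_equal(default_batch_size("densenet"), 16L)
})
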