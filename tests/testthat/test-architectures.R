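test_that("the ConvNet spec matches its published table", {
  spec <- convnet_spec()
  convs <- Filter(function(l) l$kind == "conv", spec$layers)
  expect_length(convs, 14L)
  widths <- vapply(convs, function(l) l$width, integer(1))
  expect_equal(widths, rep(c(16L, 32L, 64L, 128L, 256L, 512L, 1024L),
                           each = 2L))
  expect_equal(widths[13], 1024L)
  expect_true(all(vapply(convs, function(l) {
    l$k == 3L && l$stride == 1L
  }, logical(1))))
  expect_equal(count_layers(spec, "maxpool"), 7L)
  expect_equal(count_layers(spec, "batch_norm"), 14L)  # one per conv
  # every conv is immediately followed by batch normalization
  kinds <- vapply(spec$layers, function(l) l$kind, character(1))
  expect_true(all(kinds[which(kinds == "conv") + 1L] == "batch_norm"))
  # 256 / 2^7 = 2 at the flatten
  expect_equal(spec_output_side(spec), 2L)
})

test_that("pooling arithmetic gives side 256 / 2^p", {
  for (p in c(3L, 5L, 7L)) {
    spec <- small_convnet_spec(widths = rep(4L, p),
                               input_shape = c(256L, 256L, 1L))
    expect_equal(spec_output_side(spec), as.integer(256 / 2^p))
  }
  # pooling that exhausts the spatial extent is a build error
  expect_error(small_convnet_spec(widths = rep(4L, 3L),
                                  input_shape = c(4L, 4L, 1L)),
               "exhaust")
})

test_that("count_parameters implements the closed form", {
  one_conv <- radcal:::new_arch_spec("t", list(radcal:::layer_conv(16L)),
                                     c(8L, 8L, 1L))
  expect_equal(count_parameters(one_conv), 9 * 1 * 16 + 16)
  empty <- radcal:::new_arch_spec("e", list(), c(8L, 8L, 1L))
  expect_equal(count_parameters(empty), 0)
  # the 14-layer conv stack of the reference ConvNet, weights + biases
  expect_equal(count_parameters(convnet_spec(), kinds = "conv"), 18876272)
})

test_that("count_parameters agrees with enumeration of a built model", {
  spec <- tiny_spec()
  model <- build_model(spec, seed = 4L)
  expect_equal(n_parameters(model), count_parameters(spec))
  expect_equal(n_parameters(model, kinds = "conv"),
               count_parameters(spec, kinds = "conv"))
  # and for a spec with residual + dense blocks
  mixed <- radcal:::new_arch_spec("mix", list(
    radcal:::layer_conv(4L),
    radcal:::layer_res_block(8L, projection = TRUE, stride = 2L),
    radcal:::layer_res_block(8L),
    radcal:::layer_dense_block(2L, 3L),
    radcal:::layer_transition(),
    radcal:::layer_gap(), radcal:::layer_fc(1L), radcal:::layer_sigmoid()),
    c(16L, 16L, 1L))
  expect_equal(n_parameters(build_model(mixed, seed = 1L)),
               count_parameters(mixed))
})

test_that("the ResNet spec has 25 pre-activation blocks with projections at width changes", {
  spec <- resnet_spec()
  blocks <- Filter(function(l) l$kind == "residual_block", spec$layers)
  expect_length(blocks, 25L)
  expect_true(all(vapply(blocks, function(b) isTRUE(b$pre_activation),
                         logical(1))))
  widths <- vapply(blocks, function(b) b$width, integer(1))
  proj <- vapply(blocks, function(b) b$block_type == "projection_skip",
                 logical(1))
  # a projection block exactly where the width changes
  expect_equal(which(proj), which(c(FALSE, diff(widths) != 0)))
  expect_error(resnet_spec(0L), "n_blocks")
})

test_that("identity residual blocks are the identity when the branch is zeroed", {
  spec <- radcal:::new_arch_spec("rb", list(
    radcal:::layer_conv(4L), radcal:::layer_res_block(4L)), c(12L, 12L, 1L))
  model <- build_model(spec, seed = 9L)
  x <- array(stats::runif(2 * 12 * 12), c(2L, 12L, 12L, 1L))
  h <- radcal:::nn_fwd(model$layers[[1]], x)$out      # block input
  blk <- model$layers[[2]]
  out <- radcal:::nn_fwd(blk, h)$out
  expect_equal(dim(out), dim(h))                      # identity skip: shape
  # force the residual branch to zero: M(x) = F(x) + x becomes x
  last_conv <- blk$sub[[6]]
  last_conv$W[] <- 0; last_conv$b[] <- 0
  expect_equal(radcal:::nn_fwd(blk, h)$out, h, tolerance = 1e-12)
})

test_that("the DenseNet configuration is 169 layers deep with dense connectivity", {
  spec <- densenet_spec()
  expect_equal(spec_depth(spec), 169L)
  blocks <- Filter(function(l) l$kind == "dense_block", spec$layers)
  expect_equal(vapply(blocks, function(b) b$n_layers, integer(1)),
               c(6L, 12L, 32L, 32L))
  expect_true(all(vapply(blocks, function(b) b$growth == 32L, logical(1))))
  # first conv consumes one grayscale channel
  expect_equal(spec$input_shape[3], 1L)
  # connectivity arithmetic on a built block: layer l of a block receives
  # cin + (l-1) * growth channels
  cin <- 5L; g <- 3L
  blk <- radcal:::nn_dense_block(cin, 4L, g)
  for (l in 1:4) expect_equal(blk$units[[l]][[1]]$c, cin + (l - 1L) * g)
  x <- array(stats::runif(2 * 8 * 8 * cin), c(2L, 8L, 8L, cin))
  out <- radcal:::nn_fwd(blk, x, training = TRUE)$out
  expect_equal(dim(out)[4], cin + 4L * g)
  # the block's output prefix is the untouched input (concatenation)
  expect_equal(out[, , , seq_len(cin)], x[, , , seq_len(cin)])
})

test_that("built models are seeded, probabilistic, and expose the feature tap", {
  spec <- tiny_spec()
  m1 <- build_model(spec, seed = 21L)
  m2 <- build_model(spec, seed = 21L)
  m3 <- build_model(spec, seed = 22L)
  x <- array(stats::runif(3 * 24 * 24), c(3L, 24L, 24L, 1L))
  p1 <- predict_proba(m1, x)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict_proba(m2, x))
  expect_false(identical(p1, predict_proba(m3, x)))
  tap <- feature_tap(m1, x)
  expect_equal(dim(tap$features), c(3L, 6L, 6L, 8L))   # 24 / 2^2, last width
  expect_length(tap$classifier_weights, 8L)
  # the reference ConvNet at full input size taps a 2x2 map
  full <- build_model(convnet_spec(), seed = 1L)
  tap2 <- feature_tap(full, matrix(stats::runif(256 * 256), 256L, 256L))
  expect_equal(dim(tap2$features)[2:3], c(2L, 2L))
})

test_that("architecture specs serialize to YAML and back", {
  path <- withr::local_tempfile(fileext = ".yaml")
  spec <- resnet_spec(n_blocks = 5L, input_shape = c(32L, 32L, 1L),
                      stage_widths = c(4L, 8L))
  write_arch_spec(spec, path)
  spec2 <- read_arch_spec(path)
  expect_equal(spec2$name, spec$name)
  expect_equal(spec2$input_shape, spec$input_shape)
  expect_equal(length(spec2$layers), length(spec$layers))
  expect_equal(count_parameters(spec2), count_parameters(spec))
})
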