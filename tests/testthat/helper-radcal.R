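# Shared fixtures, all built in code at test time.

# minimal in-memory manifest (no images on disk; for counting/weight tests)
make_manifest_df <- function(n_ab, n_no, region = "Elbow", split = "train",
                             offset = 0L) {
  n <- n_ab + n_no
  data.frame(
    image_id = sprintf("%s_%s_i%05d", tolower(region), split, offset + seq_len(n)),
    path = "unused.png",
    patient_id = sprintf("p%05d", offset + seq_len(n)),
    study_id = sprintf("%s_%s_s%05d", tolower(region), split, offset + seq_len(n)),
    region = region,
    label = rep(c(1L, 0L), c(n_ab, n_no)),
    split = split,
    stringsAsFactors = FALSE)
}

# one small synthetic dataset on disk, shared across tests in a session
.radcal_test_cache <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (!is.null(.radcal_test_cache$ds)) return(.radcal_test_cache$ds)
  dir <- file.path(tempdir(), "radcal_tiny_ds")
  cfg <- generator_config(
    regions = list(
      region_signal_spec("Elbow", "bright_implant", snr = 5,
                         lesion_size_range = c(5L, 8L)),
      region_signal_spec("Wrist", "line_discontinuity", snr = 5,
                         lesion_size_range = c(5L, 8L))),
    n_train = c(abnormal = 10L, normal = 10L),
    n_validation = c(abnormal = 4L, normal = 4L),
    n_test = c(abnormal = 4L, normal = 4L),
    image_size = 24L, seed = 123L)
  ds <- generate_dataset(cfg, dir)
  .radcal_test_cache$ds <- ds
  ds
}

# tiny spec that trains in seconds at 24 px
tiny_spec <- function(size = 24L) {
  small_convnet_spec(widths = c(6L, 8L), input_shape = c(size, size, 1L))
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max abs diff %.3g <= %.3g",
                              max(abs(object - expected)), tol))
}
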