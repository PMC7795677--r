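test_that("min-max normalization matches the affine formula and guards degenerate input", {
  expect_equal(minmax_normalize(c(0, 2, 4)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(c(7, 7, 7)), "constant")
  expect_equal(out, c(0, 0, 0))
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(100, sd = runif(1, 0.1, 10))
    expect_equal(minmax_normalize(x), (x - min(x)) / (max(x) - min(x)),
                 tolerance = 1e-12)
  }
  # idempotence
  x <- runif(50)
  expect_equal(minmax_normalize(minmax_normalize(x)), minmax_normalize(x),
               tolerance = 1e-12)
  expect_error(minmax_normalize(1), "length")
})

test_that("low-pass filtering passes the band and attenuates above cutoff", {
  lp <- filter_spec("lowpass", cutoff = 2)
  slow <- sine_wave(0.5, 32, 20)
  fast <- sine_wave(10, 32, 20)
  expect_gt(amplitude_ratio(filter_channel(slow, 32, lp), slow), 0.95)
  expect_lt(amplitude_ratio(filter_channel(fast, 32, lp), fast), 0.10)
  expect_length(filter_channel(slow, 32, lp), length(slow))
  expect_error(filter_channel(slow, 2, lp), "Nyquist")
})

test_that("elliptic band-pass confines white noise to the pass band", {
  set.seed(7)
  x <- rnorm(4 * 3600)  # one hour at 4 Hz: the band is very low frequency
  y <- filter_channel(x, 4, filter_spec("elliptic_bandpass", lo = 0.005, hi = 0.1))
  spec <- stats::spec.pgram(stats::ts(y, frequency = 4), plot = FALSE, taper = 0)
  inband <- spec$freq >= 0.004 & spec$freq <= 0.12
  expect_lt(sum(spec$spec[!inband]) / sum(spec$spec), 0.05)
})

test_that("band edges above Nyquist are clipped, collapsed bands skip filtering", {
  x <- sine_wave(1, 64, 5)
  expect_warning(y <- filter_channel(x, 64, filter_spec("butter_bandpass", lo = 30, hi = 200)),
                 "clipped")
  expect_length(y, length(x))
  expect_warning(z <- filter_channel(x, 4, filter_spec("butter_bandpass", lo = 30, hi = 200)),
                 "collapsed|clipped")
  expect_equal(z, x)
})

test_that("linear resampling follows the output grid and round-trips", {
  expect_equal(resample_linear(c(0, 1), 1, 4), c(0, 0.25, 0.5, 0.75, 1))
  x <- runif(64)
  expect_identical(resample_linear(x, 32, 32), x)
  ramp <- seq(0, 1, length.out = 33)
  up <- resample_linear(ramp, 4, 32)
  down <- resample_linear(up, 32, 4)
  expect_equal(down, ramp, tolerance = 1e-9)
  expect_error(resample_linear(5, 1, 2), "2 samples")
})

test_that("decimation keeps the last point of each block", {
  expect_equal(downsample_decimate(1:10, 10, 5), c(2, 4, 6, 8, 10))
  expect_equal(downsample_decimate(1:7, 8, 8), 1:7)
  expect_error(downsample_decimate(1:10, 10, 3), "resample_linear")
  # trial of 2,451,650 samples at 1000 Hz decimated to the 20 Hz annotation
  # rate yields exactly the annotation sample count; at 50 Hz, floor(N/20)
  expect_equal(length(downsample_decimate(numeric(2451650), 1000, 20)), 49033)
  expect_equal(length(downsample_decimate(numeric(2451650), 1000, 50)), 122582)
})

test_that("decimation composes across divisible rates", {
  set.seed(3)
  x <- rnorm(1200)
  expect_equal(downsample_decimate(downsample_decimate(x, 64, 32), 32, 8),
               downsample_decimate(x, 64, 8))
})

test_that("segmentation produces fixed-length contiguous windows and drops the tail", {
  mat <- matrix(runif(81 * 50 * 2), 81 * 50, 2)  # 81 s at 50 Hz
  seg <- segment_instances(mat, 2, 50)
  expect_equal(dim(seg$data), c(40, 100, 2))
  expect_equal(seg$start_s, seq(0, 78, by = 2))
  # values preserved in order for the first window
  expect_equal(seg$data[1, , 1], mat[1:100, 1])
  expect_equal(dim(segment_instances(mat, 2, 32)$data)[2], 64)
  expect_warning(empty <- segment_instances(mat[1:10, , drop = FALSE], 2, 50), "shorter")
  expect_equal(dim(empty$data)[1], 0)
})

test_that("label discretization follows the 1-9 scale mapping", {
  expect_equal(as.character(discretize_labels(4.2, 5, "binary", "valence")), "low")
  expect_equal(as.character(discretize_labels(5.0, 5, "binary", "valence")), "high")
  expect_equal(as.character(discretize_labels(5, 6.0, "three_class", "arousal")), "high")
  expect_equal(as.character(discretize_labels(5, 2.9, "three_class", "arousal")), "low")
  expect_equal(as.character(discretize_labels(5, 3.0, "three_class", "arousal")), "neutral")
  expect_equal(as.character(discretize_labels(7, 3, "four_quadrant")), "HL")
  expect_equal(as.character(discretize_labels(3, 8, "four_quadrant")), "LH")
  expect_warning(out <- discretize_labels(c(0.5, 9.5), c(5, 5), "binary", "valence"),
                 "clamped")
  expect_equal(as.character(out), c("low", "high"))
})

test_that("window means use half-open windows on the annotation grid", {
  ann <- rep(c(2, 8), each = 20)  # 1 s at 20 Hz each
  expect_equal(window_means(ann, 20, c(0, 1), 1), c(2, 8))
  expect_equal(window_means(ann, 20, 0, 2), 5)
  expect_equal(window_means(ann, 20, 0.5, 1), (10 * 2 + 10 * 8) / 20)
  expect_true(is.na(window_means(ann, 20, 2, 1)))  # beyond the trace
})

test_that("the full preprocessing pipeline conserves instance counts and bounds", {
  inst <- tiny_instances()
  cfg <- tiny_config()
  n_expected <- cfg$n_subjects * cfg$n_stimuli * floor(cfg$trial_seconds / 2)
  expect_equal(nrow(inst$index), n_expected)
  expect_equal(dim(inst$m1)[1], n_expected)
  expect_equal(dim(inst$m2)[1], n_expected)
  expect_true(all(inst$m1 >= 0 & inst$m1 <= 1))
  expect_true(all(inst$m2 >= 0 & inst$m2 <= 1))
  expect_equal(dim(inst$m1)[2], 64)  # 2 s at 32 Hz
  expect_false(any(is.na(inst$index$v_mean)))
  expect_true(all(inst$index$v_mean >= 1 & inst$index$v_mean <= 9))
})

test_that("dataset CSV round-trip preserves signals and labels", {
  dir <- file.path(tempdir(), "emofuse_io_test")
  unlink(dir, recursive = TRUE)
  ds <- generate_dataset(tiny_config(), out_dir = dir)
  expect_error(write_dataset(ds, dir), "overwrite")
  files <- list.files(dir)
  expect_equal(sum(grepl("csv$", files)), 3 * 2)
  expect_true("manifest.yaml" %in% files)
  ds2 <- read_dataset(dir)
  expect_equal(length(ds2$recordings), length(ds$recordings))
  i1 <- preprocess_dataset(ds)
  i2 <- preprocess_dataset(ds2)
  expect_equal(i2$m1, i1$m1, tolerance = 1e-6)
  expect_equal(i2$index$v_mean, i1$index$v_mean, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
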