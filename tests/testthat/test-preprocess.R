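make_tone <- function(freq, fs = 500, dur = 30, nch = 2, offset = 0) {
  t <- seq_len(dur * fs) / fs
  recording(matrix(rep(sin(2 * pi * freq * t) + offset, each = nch),
                   nrow = nch), fs_hz = fs)
}

central_rms <- function(rec, trim = 2500) {
  n <- ncol(rec$data)
  sqrt(mean(rec$data[1, (trim + 1):(n - trim)]^2))
}

test_that("mean removal zeroes every channel mean", {
  rec <- recording(matrix(5, 2, 1000), fs_hz = 500)
  expect_true(all(remove_mean(rec)$data == 0))

  t <- seq_len(5000) / 500
  rec <- recording(rbind(sin(2 * pi * 10 * t) + 3, cos(2 * pi * 7 * t)), 500)
  out <- remove_mean(rec)
  expect_equal(out$data[1, ], sin(2 * pi * 10 * t), tolerance = 1e-3)
  expect_lt(max(abs(rowMeans(out$data))),
            1e-9 * max(apply(out$data, 1, sd)) + 1e-12)
  # already centred input is unchanged
  expect_equal(remove_mean(out)$data, out$data, tolerance = 1e-12)
})

test_that("the notch filter suppresses the line frequency only", {
  line <- make_tone(50)
  expect_lt(central_rms(notch_filter(line, 50)), 0.01)

  passband <- make_tone(10)
  out <- notch_filter(passband, 50)
  expect_equal(central_rms(out), sqrt(0.5), tolerance = 0.01)
  # zero phase: the passband tone comes out aligned, not delayed
  expect_lt(central_rms(recording(out$data - passband$data, 500)), 0.02)

  near <- make_tone(45)
  expect_gt(central_rms(notch_filter(near, 50)) / sqrt(0.5), 10^(-1 / 20))

  zero <- recording(matrix(0, 2, 5000), 500)
  expect_true(all(abs(notch_filter(zero, 50)$data) < 1e-12))
  expect_error(notch_filter(make_tone(10, fs = 90), f0 = 50), "Nyquist")
})

test_that("the band-pass filter meets its stop- and passband contract", {
  slow <- make_tone(0.2)
  expect_lt(central_rms(bandpass_filter(slow, 1, 70)) / sqrt(0.5),
            10^(-40 / 20))

  mid <- make_tone(20)
  expect_equal(central_rms(bandpass_filter(mid, 1, 70)), sqrt(0.5),
               tolerance = 0.06)

  fast <- make_tone(90)
  expect_lt(central_rms(bandpass_filter(fast, 1, 70)) / sqrt(0.5),
            10^(-40 / 20))

  zero <- recording(matrix(0, 2, 5000), 500)
  expect_true(all(abs(bandpass_filter(zero)$data) < 1e-12))
  expect_error(bandpass_filter(make_tone(10), 70, 1), "lo")
})

test_that("filters are linear and commute with scaling", {
  set.seed(4)
  rec <- recording(matrix(rnorm(2 * 8000), 2), 500)
  a <- 3.7
  scaled_first <- notch_filter(recording(a * rec$data, 500), 50)
  filtered_first <- notch_filter(rec, 50)
  expect_equal(scaled_first$data, a * filtered_first$data, tolerance = 1e-10)
})

test_that("segmentation arithmetic matches the recording protocol", {
  rec <- recording(matrix(rnorm(19 * 150000), 19), fs_hz = 500)
  ep <- segment_epochs(rec, 5)
  expect_equal(dim(ep$epochs), c(60, 19, 2500))

  short <- recording(matrix(rnorm(2 * 2450), 2), fs_hz = 500)
  expect_equal(dim(segment_epochs(short, 5)$epochs)[1], 0)

  twelve <- recording(matrix(rnorm(2 * 6000), 2), fs_hz = 500)
  ep <- segment_epochs(twelve, 5)
  expect_equal(dim(ep$epochs)[1], 2)
  # epochs are verbatim slices of the input
  expect_identical(ep$epochs[2, , ], unname(twelve$data[, 2501:5000]))
})

test_that("artifact rejection drops exactly the contaminated epochs", {
  set.seed(11)
  rec <- recording(matrix(rnorm(3 * 25000, sd = 10), 3), fs_hz = 500)
  clean <- reject_artifact_epochs(segment_epochs(rec, 5))
  expect_equal(clean$kept_indices, 1:10)

  bad <- inject_transient(rec, at_s = 12.5, amplitude_uv = 500)
  ep <- reject_artifact_epochs(segment_epochs(bad, 5))
  expect_equal(setdiff(1:10, ep$kept_indices), 3)

  ident <- reject_artifact_epochs(segment_epochs(bad, 5),
                                  ptp_threshold_uv = Inf, z_threshold = Inf)
  expect_equal(ident$kept_indices, 1:10)

  flat <- recording(matrix(rnorm(2 * 5000, sd = 1000), 2), 500)
  expect_warning(
    reject_artifact_epochs(segment_epochs(flat, 5), ptp_threshold_uv = 1),
    "all epochs rejected"
  )
})

test_that("the full chain returns artifact-free epochs in order", {
  set.seed(2)
  rec <- recording(matrix(rnorm(4 * 30000, sd = 10), 4), fs_hz = 500)
  ep <- preprocess(rec, epoch_length_s = 5)
  expect_s3_class(ep, "epoch_set")
  expect_equal(dim(ep$epochs)[2:3], c(4, 2500))
  expect_false(is.unsorted(ep$kept_indices, strictly = TRUE))
  # common average reference: spatial mean is ~0 at every sample
  expect_lt(max(abs(colMeans(ep$epochs[1, , ]))), 1e-9)
})

test_that("common average referencing zeroes the spatial mean", {
  t <- seq_len(1000) / 500
  a <- sin(2 * pi * 5 * t)
  rec <- recording(rbind(a, -a), 500)
  expect_equal(rereference_common_average(rec)$data, rec$data,
               tolerance = 1e-12)

  same <- recording(rbind(a, a, a), 500)
  expect_true(all(abs(rereference_common_average(same)$data) < 1e-12))

  set.seed(8)
  rnd <- recording(matrix(rnorm(3 * 100), 3), 500)
  expect_lt(max(abs(colMeans(rereference_common_average(rnd)$data))), 1e-9)
  expect_error(rereference_common_average(recording(matrix(1, 1, 10), 500)),
               "2 channels")
})
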