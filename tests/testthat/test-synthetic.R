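test_that("toy forward models partition ROIs evenly and are deterministic", {
  fm <- make_toy_forward_model(19, 68, 68, seed = 1)
  expect_equal(dim(fm$lead_field), c(19, 68))
  expect_equal(length(unique(fm$roi_labels)), 68)
  expect_true(all(table(fm$roi_labels) == 1))

  fm2 <- make_toy_forward_model(8, 20, 4, seed = 7)
  expect_true(all(table(fm2$roi_labels) == 5))

  expect_identical(make_toy_forward_model(8, 20, 4, seed = 7), fm2)
  expect_error(make_toy_forward_model(8, 3, 4), "n_sources")
})

test_that("cohort generation is deterministic and honours group sizes", {
  fm <- tiny_model()
  sp <- cohort_spec(n_subjects_per_group = c(risk = 18, protective = 35),
                    duration_s = 5)
  coh <- generate_cohort(sp, fm, seed = 3, output = "roi")
  expect_length(coh$recordings, 53)
  expect_equal(sum(coh$metadata$group == "risk"), 18)

  coh2 <- generate_cohort(sp, fm, seed = 3, output = "roi")
  expect_identical(coh$recordings[[10]]$data, coh2$recordings[[10]]$data)
  expect_identical(coh$metadata, coh2$metadata)

  empty <- generate_cohort(
    cohort_spec(n_subjects_per_group = c(risk = 0, protective = 0),
                duration_s = 5), fm, seed = 1)
  expect_length(empty$recordings, 0)

  expect_error(generate_subject(sp, "patient", fm, 1), "unknown group")
})

test_that("band variance fractions match the amplitude ground truth", {
  fm <- tiny_model(6, 6, 6)
  sp <- cohort_spec(n_subjects_per_group = c(risk = 1, protective = 1),
                    duration_s = 20, heterogeneity = 0, subject_sd = 0,
                    noise_amplitude = 0)
  rec <- generate_subject(sp, "protective", fm, 11, output = "roi")
  amps <- sp$band_amplitudes
  want <- amps^2 / sum(amps^2)
  got <- rowMeans(apply(rec$data, 1, oracle_band_fractions, fs = sp$fs_hz))
  expect_equal(unname(got), unname(want), tolerance = 0.05)
  # total variance ~= sum of squared amplitudes
  expect_equal(mean(apply(rec$data, 1, var)), sum(amps^2), tolerance = 0.1)
})

test_that("risk-group effect multiplies band power by its square", {
  fm <- tiny_model(6, 6, 3)
  sp <- cohort_spec(
    n_subjects_per_group = c(risk = 1, protective = 1), duration_s = 10,
    band_amplitudes = c(delta = 0, theta = 0, alpha = 0, beta = 1, gamma = 0),
    effect_multipliers = c(delta = 1, theta = 1, alpha = 1, beta = 0.8,
                           gamma = 1),
    heterogeneity = 0, subject_sd = 0, noise_amplitude = 0
  )
  pow <- function(group, seeds) {
    mean(vapply(seeds, function(s) {
      mean(apply(generate_subject(sp, group, fm, s, output = "roi")$data,
                 1, var))
    }, numeric(1)))
  }
  ratio <- pow("risk", 1:25) / pow("protective", 101:125)
  expect_equal(ratio, 0.64, tolerance = 0.04)
})

test_that("degenerate amplitude settings behave as limits", {
  fm <- tiny_model(6, 6, 3)
  sp0 <- cohort_spec(n_subjects_per_group = c(risk = 1, protective = 1),
                     duration_s = 5, band_amplitudes = c(
                       delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
                     heterogeneity = 0, subject_sd = 0, noise_amplitude = 0)
  rec <- generate_subject(sp0, "risk", fm, 5)
  expect_true(all(rec$data == 0))

  # alpha-only content: alpha dominates every ROI's relative power
  sp_a <- cohort_spec(n_subjects_per_group = c(risk = 1, protective = 1),
                      duration_s = 10, band_amplitudes = c(
                        delta = 0, theta = 0, alpha = 1, beta = 0, gamma = 0),
                      heterogeneity = 0, subject_sd = 0, noise_amplitude = 0)
  rec <- generate_subject(sp_a, "risk", fm, 5, output = "roi")
  res <- rp_per_subject(as_roi_signals(segment_epochs(rec, 5)))
  expect_true(all(res$rp[, "alpha"] > 0.8))
  expect_true(all(res$rp[, "alpha"] > res$rp[, "beta"]))
})

test_that("cohort spec validation rejects inconsistent settings", {
  expect_error(cohort_spec(fs_hz = 100), "fs_hz")
  expect_error(cohort_spec(band_amplitudes = c(delta = -1, theta = 1,
                                               alpha = 1, beta = 1,
                                               gamma = 1)), "nonnegative")
  expect_error(cohort_spec(duration_s = 0), "duration")
})

test_that("cohorts round-trip through CSV files", {
  fm <- tiny_model(4, 4, 2)
  sp <- cohort_spec(n_subjects_per_group = c(risk = 1, protective = 1),
                    duration_s = 2, fs_hz = 200)
  coh <- generate_cohort(sp, fm, seed = 9)
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  back <- read_recording_csv(file.path(dir, "S001.csv"))
  expect_equal(back$fs_hz, 200)
  expect_equal(unname(back$data), unname(coh$recordings[[1]]$data),
               tolerance = 1e-6)
  md <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(md$group, c("risk", "protective"))
  unlink(dir, recursive = TRUE)
})

test_that("injected transients raise the peak amplitude where placed", {
  rec <- recording(matrix(0, 3, 1000), fs_hz = 500)
  out <- inject_transient(rec, at_s = 1, amplitude_uv = 500, channels = 2)
  expect_equal(max(out$data[2, ]), 500, tolerance = 1e-6)
  expect_true(all(out$data[c(1, 3), ] == 0))
})
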