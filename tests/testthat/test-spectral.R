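test_that("the compiled Welch kernel matches a plain R implementation", {
  set.seed(1)
  x <- rnorm(2500)
  got <- compute_psd(x, 500)
  want <- oracle_welch(x, 500)
  expect_equal(got$freq, want$freq)
  expect_equal(got$psd, want$psd, tolerance = 1e-10)
})

test_that("the Hermitian synthesis kernel matches R's inverse FFT", {
  set.seed(2)
  n <- 1000
  kmax <- floor((n - 1) / 2)
  z <- matrix(complex(real = rnorm(kmax * 3), imaginary = rnorm(kmax * 3)),
              kmax, 3)
  full <- matrix(0 + 0i, n, 3)
  full[1 + seq_len(kmax), ] <- z
  full[n + 1 - seq_len(kmax), ] <- Conj(z)
  want <- Re(stats::mvfft(full, inverse = TRUE)) / n
  expect_equal(eegspect:::cpp_hermitian_ifft(z, n), want, tolerance = 1e-10)
})

test_that("a pure tone concentrates its PSD at the tone frequency", {
  x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 500))[-1]
  p <- compute_psd(x, 500)
  expect_equal(p$freq[which.max(p$psd)], 10)
  inb <- p$freq >= 1 & p$freq <= 70
  near <- p$freq >= 9 & p$freq <= 11
  expect_gt(sum(p$psd[near]) / sum(p$psd[inb]), 0.95)

  expect_true(all(compute_psd(numeric(2500), 500)$psd == 0))
  expect_error(compute_psd(rnorm(100), 500), "2 s")
})

test_that("white noise gives a flat spectrum across the analysis range", {
  set.seed(5)
  x <- rnorm(250000)
  p <- compute_psd(x, 500)
  inb <- p$freq >= 1 & p$freq <= 70
  expect_lt(max(abs(p$psd[inb] / mean(p$psd[inb]) - 1)), 0.2)
})

test_that("normalization produces a unit-mass spectrum on 1-70 Hz", {
  set.seed(6)
  p <- compute_psd(abs(rnorm(2500)) + 1, 500)
  n1 <- normalize_psd(p$freq, p$psd)
  expect_equal(sum(n1$psd_n), 1, tolerance = 1e-12)
  expect_true(all(n1$freq >= 1 & n1$freq <= 70))
  # idempotent on an already-normalized spectrum
  n2 <- normalize_psd(n1$freq, n1$psd_n)
  expect_equal(n2$psd_n, n1$psd_n, tolerance = 1e-12)
  # degenerate single-bin mass
  conc <- as.numeric(n1$freq == 10)
  expect_equal(normalize_psd(n1$freq, conc)$psd_n, conc)
  expect_error(normalize_psd(p$freq, rep(0, length(p$freq))), "no mass")
})

test_that("relative power respects the half-open band convention", {
  f <- 1:70
  rp10 <- relative_power(f, as.numeric(f == 10))
  expect_equal(unname(rp10), c(0, 0, 1, 0, 0))
  rp20 <- relative_power(f, as.numeric(f == 20))
  expect_equal(unname(rp20["beta" == names(rp20)]), 1)
  # 13 Hz belongs to beta, not alpha; 70 Hz closes gamma
  rp13 <- relative_power(f, as.numeric(f == 13))
  expect_equal(unname(rp13[c("alpha", "beta")]), c(0, 1))
  rp70 <- relative_power(f, as.numeric(f == 70))
  expect_equal(unname(rp70["gamma"]), 1)
})

test_that("relative power always sums to one and ignores signal scale", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(2500) * runif(1, 0.1, 100)
    p <- compute_psd(x, 500)
    n <- normalize_psd(p$freq, p$psd)
    rp <- relative_power(n$freq, n$psd_n)
    expect_equal(sum(rp), 1, tolerance = 1e-9)
    p2 <- compute_psd(5.5 * x, 500)
    n2 <- normalize_psd(p2$freq, p2$psd)
    expect_equal(relative_power(n2$freq, n2$psd_n), rp, tolerance = 1e-9)
  }
})

test_that("per-subject RP averages epochs and repeats are consistent", {
  set.seed(8)
  one <- matrix(rnorm(6 * 2500), 6)
  arr <- array(0, c(3, 6, 2500))
  for (e in 1:3) arr[e, , ] <- one
  rs <- roi_signals(arr, paste0("r", 1:6), 500)
  res <- rp_per_subject(rs)
  expect_equal(res$rp, res$per_epoch[1, , ], tolerance = 1e-12)
  expect_equal(unname(rowSums(res$rp)), rep(1, 6), tolerance = 1e-9)
  expect_error(rp_per_subject(roi_signals(array(0, c(0, 6, 2500)),
                                          paste0("r", 1:6), 500)),
               "no epochs")
})

test_that("welch and periodogram estimators agree on long stationary tones", {
  x <- sin(2 * pi * 10 * seq_len(5000) / 500)
  pw <- compute_psd(x, 500)
  pp <- compute_psd(x, 500, method = "periodogram")
  expect_equal(pp$freq[which.max(pp$psd)], 10, tolerance = 0.11)
  expect_equal(pw$freq[which.max(pw$psd)], 10)
})
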