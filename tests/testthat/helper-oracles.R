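# Fixtures and independent oracles used across the test files.

tiny_model <- function(n_sensors = 8, n_sources = 12, n_rois = 4, seed = 7) {
  make_toy_forward_model(n_sensors, n_sources, n_rois, seed = seed)
}

quick_spec <- function(...) {
  cohort_spec(n_subjects_per_group = c(risk = 2, protective = 2),
              duration_s = 5, ...)
}

# Brute-force spatial entropy: quartiles by linear interpolation, equal-width
# bins, [lo, hi) with the last bin closed, -sum p log p / log N. Written
# independently of the package's histogram helpers.
oracle_se <- function(x) {
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  h <- 2 * (q[2] - q[1]) * n^(-1 / 3)
  lo <- min(x)
  hi <- max(x)
  if (h <= 0 || lo == hi) return(0)
  nb <- ceiling((hi - lo) / h)
  if (nb < 2) return(0)
  e <- lo + (hi - lo) * (0:nb) / nb
  e[nb + 1] <- hi  # guard the maximum against rounding out of the last bin
  counts <- vapply(seq_len(nb), function(j) {
    if (j < nb) sum(x >= e[j] & x < e[j + 1]) else sum(x >= e[j] & x <= e[j + 1])
  }, numeric(1))
  p <- counts / sum(counts)
  p <- p[p > 0]
  if (length(p) < 2) return(0)
  -sum(p * log(p)) / log(nb)
}

# Exhaustive-permutation two-sided p for the Mann-Whitney test on tie-free
# samples: distribution of U over all assignments of the pooled ranks.
oracle_perm_mw <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(N, n1)
  u_all <- apply(sets, 2, function(idx) sum(seq_len(N)[idx]) - n1 * (n1 + 1) / 2)
  c_mid <- n1 * (N - n1) / 2
  mean(abs(u_all - c_mid) >= abs(u_obs - c_mid))
}

# Direct R Welch implementation (plain fft), oracle for the compiled kernel.
oracle_welch <- function(x, fs, nperseg = fs, overlap = 0.5) {
  step <- round(nperseg * (1 - overlap))
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
  nf <- nperseg %/% 2 + 1
  acc <- rowMeans(vapply(starts, function(s) {
    abs(stats::fft(x[s + 0:(nperseg - 1)] * w))[1:nf]^2
  }, numeric(nf)))
  psd <- acc / (fs * sum(w^2))
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / nperseg, psd = psd * dbl)
}

# Variance fraction of a synthetic signal in each band, measured directly on
# the DFT with R's own fft (the synthesis places band mass exactly in the
# band's bins, so this is exact up to draw randomness).
oracle_band_fractions <- function(x, fs, scheme = band_scheme()) {
  n <- length(x)
  X <- abs(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs  # negative frequencies
  fa <- abs(f)
  tot <- sum(X[-1])
  vapply(seq_len(nrow(scheme)), function(b) {
    lo <- scheme$f_lo[b]
    hi <- scheme$f_hi[b]
    m <- if (b == nrow(scheme)) fa >= lo & fa <= hi else fa >= lo & fa < hi
    sum(X[m]) / tot
  }, numeric(1))
}
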