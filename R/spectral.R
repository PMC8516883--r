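#' Welch power spectral density
#'
#' Welch's averaged modified periodogram with Hamming-windowed segments of
#' `nperseg` samples (default one second, giving a 1 Hz frequency
#' resolution that aligns bins to the integer band edges) and 50% overlap.
#' With `method = "periodogram"` a single full-length periodogram is
#' computed instead.
#'
#' @param x Numeric vector (one epoch of one channel/ROI).
#' @param fs_hz Sampling rate.
#' @param nperseg Segment length in samples (default `fs_hz`, i.e. 1 s).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param method `"welch"` or `"periodogram"`.
#' @return A list with `freq` (Hz, one-sided) and `psd` (density,
#'   \eqn{\mu V^2/Hz}, nonnegative).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 500))
#' p <- compute_psd(x, 500)
#' p$freq[which.max(p$psd)]  # 10
#' @export
compute_psd <- function(x, fs_hz, nperseg = round(fs_hz), overlap = 0.5,
                        method = c("welch", "periodogram")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) < 2 * fs_hz) stopf("signal must be at least 2 s long")
  if (method == "periodogram") {
    nperseg <- length(x)
    overlap <- 0
  }
  p <- welch_matrix(matrix(x, ncol = 1), fs_hz, nperseg, overlap)
  list(freq = p$freq, psd = as.numeric(p$psd))
}

# Welch PSD of every column of X [n_samples x n_series].
# Returns freq plus psd matrix [n_freq x n_series].
welch_matrix <- function(X, fs_hz, nperseg = round(fs_hz), overlap = 0.5) {
  n <- nrow(X)
  nperseg <- min(nperseg, n)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- signal::hamming(nperseg)
  scale <- 1 / (fs_hz * sum(w^2))
  nf <- nperseg %/% 2 + 1L
  psd <- cpp_welch(X, nperseg, step, w) * scale
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  list(freq = (seq_len(nf) - 1) * fs_hz / nperseg, psd = psd)
}

#' Normalize a PSD over the analysis range
#'
#' Restricts the spectrum to the band scheme's normalization range
#' (default 1-70 Hz) and rescales it to sum to one, turning it into a
#' discrete probability distribution over frequency bins.
#'
#' @param freq Frequency vector (Hz).
#' @param psd Nonnegative PSD values, positive total mass in range.
#' @param scheme A [band_scheme()].
#' @return A list with `freq` (restricted) and `psd_n` (sums to 1).
#' @export
normalize_psd <- function(freq, psd, scheme = band_scheme()) {
  if (any(psd < 0)) stopf("psd must be nonnegative")
  rng <- attr(scheme, "range")
  keep <- freq >= rng[1] & freq <= rng[2]
  total <- sum(psd[keep])
  if (total <= 0) stopf("psd has no mass in the normalization range")
  list(freq = freq[keep], psd_n = psd[keep] / total)
}

#' Relative power per frequency band
#'
#' Sums the normalized PSD over the bins of each band:
#' \deqn{RP_{band} = \sum_{f \in band} PSD_n(f).}
#' Bands are half-open \eqn{[lo, hi)}, the last band closed at its upper
#' edge, so the relative powers always sum to one.
#'
#' @param freq Frequencies of the normalized PSD.
#' @param psd_n Normalized PSD (sums to 1).
#' @param scheme A [band_scheme()].
#' @return Named numeric vector of per-band relative power.
#' @examples
#' # all power at 10 Hz -> pure alpha
#' f <- 1:70; p <- as.numeric(f == 10)
#' relative_power(f, p)
#' @export
relative_power <- function(freq, psd_n, scheme = band_scheme()) {
  if (abs(sum(psd_n) - 1) > 1e-6) {
    stopf("psd_n must be normalized (use normalize_psd)")
  }
  rp <- vapply(seq_len(nrow(scheme)), function(i) {
    sum(psd_n[band_mask(freq, scheme, i)])
  }, numeric(1))
  stats::setNames(rp, band_names(scheme))
}

#' Per-subject relative power over ROIs
#'
#' Computes relative power per epoch and ROI, then averages arithmetically
#' across epochs. The per-epoch array is returned as well because the
#' spatial-entropy statistic is computed per epoch before averaging.
#'
#' @param rsig A [roi_signals()] object (>= 1 epoch).
#' @param scheme A [band_scheme()].
#' @param nperseg,overlap Welch parameters, see [compute_psd()].
#' @return A list with `rp` (matrix `[n_rois x n_bands]`, rows of the
#'   epoch-averaged table), `per_epoch` (array
#'   `[n_epochs x n_rois x n_bands]`) and `psd_n` (the subject-mean
#'   normalized PSD over ROIs: list of `freq`, `psd_n`).
#' @export
rp_per_subject <- function(rsig, scheme = band_scheme(),
                           nperseg = round(rsig$fs_hz), overlap = 0.5) {
  stopifnot(inherits(rsig, "roi_signals"))
  d <- dim(rsig$data)
  if (d[1] == 0) stopf("no epochs")
  rng <- attr(scheme, "range")
  nb <- nrow(scheme)
  per_epoch <- array(0, dim = c(d[1], d[2], nb),
                     dimnames = list(NULL, rsig$roi_labels,
                                     band_names(scheme)))
  mean_psd <- 0
  f <- NULL
  for (e in seq_len(d[1])) {
    W <- welch_matrix(t(matrix(rsig$data[e, , ], nrow = d[2])),
                      rsig$fs_hz, nperseg, overlap)
    keep <- W$freq >= rng[1] & W$freq <= rng[2]
    P <- W$psd[keep, , drop = FALSE]
    tot <- colSums(P)
    if (any(tot <= 0)) stopf("epoch %d has an all-zero spectrum", e)
    Pn <- sweep(P, 2, tot, `/`)
    f <- W$freq[keep]
    for (b in seq_len(nb)) {
      per_epoch[e, , b] <- colSums(Pn[band_mask(f, scheme, b), ,
                                      drop = FALSE])
    }
    mean_psd <- mean_psd + rowMeans(Pn) / d[1]
  }
  rp <- apply(per_epoch, c(2, 3), mean)
  list(rp = rp, per_epoch = per_epoch,
       psd_n = list(freq = f, psd_n = mean_psd))
}
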