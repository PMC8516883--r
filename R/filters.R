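# FIR designs and zero-phase application.
#
# Both analysis filters are linear-phase Hamming-window FIRs applied
# forward-backward, so every dB contract in the documentation refers to the
# net zero-phase response |H(f)|^2.

# Odd tap count giving a Hamming transition width of about `transition_hz`.
hamming_taps <- function(fs_hz, transition_hz) {
  n <- ceiling(3.3 * fs_hz / transition_hz)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

fir_bandpass <- function(lo, hi, fs_hz, transition_hz = 1) {
  ntaps <- hamming_taps(fs_hz, transition_hz)
  signal::fir1(ntaps - 1, c(lo, hi) / (fs_hz / 2), type = "pass",
               window = signal::hamming(ntaps))
}

fir_bandstop <- function(lo, hi, fs_hz, transition_hz = 2) {
  ntaps <- hamming_taps(fs_hz, transition_hz)
  signal::fir1(ntaps - 1, c(lo, hi) / (fs_hz / 2), type = "stop",
               window = signal::hamming(ntaps))
}

# Zero-phase FIR filtering of the columns of `x` (samples x series) via FFT
# convolution with the filter's autocorrelation (net response |H|^2, no
# group delay). Edges are padded by odd reflection to suppress transients.
fir_filtfilt <- function(b, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- length(b)
  pad <- min(m, n - 1L)
  xp <- rbind(
    2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) -
      x[pad + 1L - seq_len(pad) + 1L, , drop = FALSE],
    x,
    2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) -
      x[n - seq_len(pad), , drop = FALSE]
  )
  np <- nrow(xp)
  L <- 2^ceiling(log2(np + 2 * m))
  H <- stats::fft(c(b, numeric(L - m)))
  G <- Re(H * Conj(H))  # zero-phase net response
  X <- stats::mvfft(rbind(xp, matrix(0, L - np, ncol(xp))))
  y <- Re(stats::mvfft(X * G, inverse = TRUE)) / L
  # |H|^2 is the transform of the zero-lag-centered autocorrelation of b,
  # so y is already aligned with xp; drop the reflection padding only
  y[pad + seq_len(n), , drop = FALSE]
}

# Apply a zero-phase FIR to an eeg_recording (channels x samples).
apply_fir <- function(rec, b) {
  out <- t(fir_filtfilt(b, t(rec$data)))
  rec$data <- out
  rownames(rec$data) <- rec$channel_labels
  rec
}
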