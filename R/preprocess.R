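#' Preprocessing chain for resting-state EEG
#'
#' The six-step sensor-space chain applied before source localization:
#' (i) per-channel mean removal, (ii) power-line notch filter, (iii)
#' Hamming-window band-pass filter, (iv) an optional artifact-removal hook
#' (identity by default; slot for ICA-style cleaning), (v) segmentation
#' into fixed-length epochs, and (vi) automatic rejection of epochs with
#' excessive amplitude or variance. All filters are linear-phase FIRs
#' applied forward-backward (zero phase).
#'
#' @param rec An [recording()].
#' @param notch_hz Power-line frequency to suppress (default 50 Hz).
#' @param band Band-pass edges in Hz (default 1-70).
#' @param epoch_length_s Epoch duration in seconds (default 5).
#' @param ptp_threshold_uv,z_threshold Rejection thresholds, see
#'   [reject_artifact_epochs()].
#' @param ica_hook A function `recording -> recording` inserted between
#'   filtering and re-referencing; defaults to the identity.
#' @param reref Apply the common average reference (default TRUE).
#' @return An [epoch_set()] of artifact-free epochs.
#' @examples
#' rec <- recording(matrix(rnorm(4 * 5000), 4), fs_hz = 500)
#' ep <- preprocess(rec, epoch_length_s = 2)
#' ep
#' @export
preprocess <- function(rec, notch_hz = 50, band = c(1, 70),
                       epoch_length_s = 5, ptp_threshold_uv = 150,
                       z_threshold = 4, ica_hook = identity, reref = TRUE) {
  rec <- remove_mean(rec)
  rec <- notch_filter(rec, notch_hz)
  rec <- bandpass_filter(rec, band[1], band[2])
  rec <- ica_hook(rec)
  if (reref) rec <- rereference_common_average(rec)
  epochs <- segment_epochs(rec, epoch_length_s)
  reject_artifact_epochs(epochs, ptp_threshold_uv, z_threshold)
}

#' Remove the per-channel mean
#'
#' @param rec An [recording()].
#' @return The recording with every channel's sample mean subtracted.
#' @export
remove_mean <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) == 0) stopf("empty recording")
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Power-line notch filter
#'
#' Zero-phase Hamming-window FIR band-stop around `f0` (stop band
#' `f0 +/- 2` Hz, transition about 2 Hz). The net zero-phase response
#' attenuates a tone at `f0` by far more than 40 dB while tones 5 Hz away
#' pass within 1 dB.
#'
#' @param rec An [recording()].
#' @param f0 Notch frequency in Hz; must be below the Nyquist frequency.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, f0 = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (f0 >= rec$fs_hz / 2) stopf("notch frequency must be below Nyquist")
  b <- fir_bandstop(f0 - 2, f0 + 2, rec$fs_hz)
  apply_fir(rec, b)
}

#' Band-pass filter
#'
#' Zero-phase Hamming-window FIR band-pass (default 1-70 Hz) with a
#' transition width of about 1 Hz, sharp enough to respect the 1 Hz lower
#' edge at a 500 Hz sampling rate (about 1651 taps).
#'
#' @param rec An [recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param transition_hz Transition width of the Hamming design.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 70, transition_hz = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(lo > 0 && lo < hi && hi < rec$fs_hz / 2)) {
    stopf("need 0 < lo < hi < fs/2")
  }
  b <- fir_bandpass(lo, hi, rec$fs_hz, transition_hz)
  apply_fir(rec, b)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the spatial mean is zero at every sample.
#'
#' @param rec An [recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
rereference_common_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stopf("common average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Set of fixed-length epochs
#'
#' @param epochs Numeric array `[n_epochs x n_channels x n_samples_epoch]`.
#' @param fs_hz Sampling rate.
#' @param epoch_length_s Epoch duration in seconds.
#' @param kept_indices Strictly increasing original epoch indices.
#' @param channel_labels Channel (or ROI) labels.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs_hz, epoch_length_s, kept_indices,
                      channel_labels = NULL) {
  stopifnot(length(dim(epochs)) == 3)
  if (dim(epochs)[3] != round(epoch_length_s * fs_hz)) {
    stopf("epoch sample count does not match epoch_length_s * fs_hz")
  }
  if (is.unsorted(kept_indices, strictly = TRUE)) {
    stopf("kept_indices must be strictly increasing")
  }
  structure(
    list(epochs = epochs, fs_hz = fs_hz, epoch_length_s = epoch_length_s,
         kept_indices = as.integer(kept_indices),
         channel_labels = channel_labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
    dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
    x$epoch_length_s, x$fs_hz
  ))
  invisible(x)
}

#' Segment a recording into non-overlapping epochs
#'
#' Consecutive non-overlapping epochs of `epoch_length_s` seconds; a
#' trailing partial epoch is discarded.
#'
#' @param rec An [recording()].
#' @param epoch_length_s Epoch duration in seconds (> 0).
#' @return An [epoch_set()].
#' @examples
#' rec <- recording(matrix(rnorm(3 * 6000), 3), fs_hz = 500)
#' segment_epochs(rec, 5)  # 12 s -> 2 epochs, last 2 s dropped
#' @export
segment_epochs <- function(rec, epoch_length_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch_length_s <= 0) stopf("epoch_length_s must be positive")
  len <- round(epoch_length_s * rec$fs_hz)
  n_epochs <- ncol(rec$data) %/% len
  arr <- aperm(array(rec$data[, seq_len(n_epochs * len), drop = FALSE],
                     dim = c(nrow(rec$data), len, n_epochs)),
               c(3, 1, 2))
  epoch_set(arr, rec$fs_hz, epoch_length_s, seq_len(n_epochs),
            rec$channel_labels)
}

#' Automatic artifact-epoch rejection
#'
#' Deterministic stand-in for visual artifact screening: an epoch is
#' dropped when any channel's peak-to-peak amplitude exceeds
#' `ptp_threshold_uv`, or when any channel's within-epoch standard
#' deviation lies more than `z_threshold` standard deviations above the
#' mean of that channel's across-epoch SD distribution.
#'
#' @param epochs An [epoch_set()].
#' @param ptp_threshold_uv Peak-to-peak threshold in microvolts.
#' @param z_threshold Across-epoch SD z-score threshold.
#' @return An [epoch_set()] containing only the retained epochs, with
#'   `kept_indices` updated. Warns (does not fail) when every epoch is
#'   rejected.
#' @export
reject_artifact_epochs <- function(epochs, ptp_threshold_uv = 150,
                                   z_threshold = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  ne <- dim(epochs$epochs)[1]
  if (ne == 0) stopf("empty epoch set")
  nc <- dim(epochs$epochs)[2]
  st <- cpp_row_ptp_sd(matrix(epochs$epochs, ne * nc,
                              dim(epochs$epochs)[3]))
  ptp <- matrix(st$ptp, ne, nc)
  sds <- matrix(st$sd, ne, nc)
  bad_ptp <- apply(ptp > ptp_threshold_uv, 1, any)
  mu <- colMeans(sds)
  sg <- apply(sds, 2, stats::sd)
  bad_sd <- if (ne > 1 && is.finite(z_threshold)) {
    apply(sweep(sds, 2, mu + z_threshold * sg) > 0, 1, any)
  } else {
    rep(FALSE, ne)
  }
  keep <- which(!(bad_ptp | bad_sd))
  if (length(keep) == 0) {
    warn("all epochs rejected; downstream stages will refuse this subject")
  }
  epoch_set(
    epochs$epochs[keep, , , drop = FALSE], epochs$fs_hz,
    epochs$epoch_length_s, epochs$kept_indices[keep],
    epochs$channel_labels
  )
}
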