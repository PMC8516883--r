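#' Sensor-space EEG recording
#'
#' A lightweight container for a multi-channel EEG recording: a numeric
#' matrix of channels by samples (microvolts), the sampling rate and unique
#' channel labels.
#'
#' @param data Numeric matrix `[n_channels x n_samples]` in microvolts.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to the 19 electrodes of the 10-20 system when
#'   `data` has 19 rows, otherwise `ch01`, `ch02`, ...
#'
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(19 * 500), 19), fs_hz = 500)
#' rec
#' @export
recording <- function(data, fs_hz, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stopf("recording data must be a finite numeric matrix")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stopf("fs_hz must be a positive scalar")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 19) {
      channels_1020()
    } else {
      sprintf("ch%02d", seq_len(nrow(data)))
    }
  }
  if (length(channel_labels) != nrow(data)) {
    stopf("need one channel label per data row")
  }
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs_hz = fs_hz, channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' The 19 electrode labels of the international 10-20 system
#' @return Character vector of length 19.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz
  ))
  cat("channels:", paste(utils::head(x$channel_labels, 8), collapse = " "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Read / write a recording as a plain text matrix
#'
#' Recordings are exchanged as plain ASCII/CSV matrices, one row per channel
#' and one column per sample, with channel labels in the first column. The
#' sampling rate is stored in a `# fs_hz:` header comment.
#'
#' @param path File path.
#' @param rec An [recording()] object.
#' @return `read_recording_csv()` returns an `eeg_recording`;
#'   `write_recording_csv()` returns `path` invisibly.
#' @export
read_recording_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# fs_hz:", header)) {
    stopf("%s: missing '# fs_hz:' header line", path)
  }
  fs <- as.numeric(sub("^# fs_hz:\\s*", "", header))
  tab <- utils::read.csv(path, comment.char = "#", header = FALSE,
                         stringsAsFactors = FALSE)
  labels <- as.character(tab[[1]])
  data <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(data) <- NULL
  recording(data, fs_hz = fs, channel_labels = labels)
}

#' @rdname read_recording_csv
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz: %.10g", rec$fs_hz), con)
  utils::write.table(
    data.frame(rec$channel_labels, rec$data),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
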