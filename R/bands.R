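#' Frequency band scheme
#'
#' Defines an ordered set of contiguous, non-overlapping frequency bands
#' together with the normalization range over which power spectra are
#' normalized before band powers are summed. Bands follow the half-open
#' convention \eqn{[f_{lo}, f_{hi})}; the last band additionally includes its
#' upper edge, so the five conventional bands partition the full range and
#' relative powers always sum to one.
#'
#' @param bands A data frame with columns `band` (character), `f_lo`, `f_hi`
#'   (Hz). Defaults to the five conventional EEG bands: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30 and gamma 30-70 Hz.
#'
#' @return A tibble of class `band_scheme` with columns `band`, `f_lo`,
#'   `f_hi`, carrying the normalization range `c(f_min, f_max)` as attribute
#'   `range`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble(
      band = c("delta", "theta", "alpha", "beta", "gamma"),
      f_lo = c(1, 4, 8, 13, 30),
      f_hi = c(4, 8, 13, 30, 70)
    )
  }
  bands <- as_tibble(bands)
  req <- c("band", "f_lo", "f_hi")
  if (!all(req %in% names(bands))) {
    stopf("`bands` needs columns %s", paste(req, collapse = ", "))
  }
  if (any(bands$f_hi <= bands$f_lo)) stopf("each band needs f_hi > f_lo")
  if (nrow(bands) > 1 &&
      any(abs(bands$f_lo[-1] - bands$f_hi[-nrow(bands)]) > 1e-12)) {
    stopf("bands must be contiguous and ordered")
  }
  structure(
    bands,
    range = c(bands$f_lo[1], bands$f_hi[nrow(bands)]),
    class = c("band_scheme", class(bands))
  )
}

band_names <- function(scheme) scheme$band

# Logical mask of frequencies belonging to band i of the scheme
# (half-open [lo, hi); last band closed at its upper edge).
band_mask <- function(freqs, scheme, i) {
  lo <- scheme$f_lo[i]
  hi <- scheme$f_hi[i]
  if (i == nrow(scheme)) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
}
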