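#' Specification of a synthetic EEG cohort
#'
#' Describes a two-group (risk / protective genotype) resting-state EEG
#' cohort with known spectral ground truth. Each cortical source carries a
#' sum of band-limited Gaussian oscillations (one per frequency band, with
#' per-band root-mean-square amplitude) plus a 1/f "pink" background.
#' Group effects act multiplicatively on the band amplitudes of the risk
#' group only; spatial heterogeneity draws per-ROI log-normal amplitude
#' multipliers; `subject_sd` draws per-subject log-normal band-amplitude
#' multipliers, emulating inter-subject variability of band composition.
#'
#' Default amplitudes approximate an elderly eyes-closed resting spectrum
#' (alpha-dominant, modest beta and low gamma) with source-level signals of
#' roughly unit RMS in microvolts.
#'
#' @param n_subjects_per_group Length-2 counts, `c(risk, protective)`.
#'   Defaults to the 18 / 35 split of the study cohort.
#' @param band_amplitudes Named per-band nonnegative RMS amplitudes
#'   (microvolts at the source).
#' @param effect_multipliers Named per-band multipliers applied to the risk
#'   group's amplitudes only (1 = no effect).
#' @param heterogeneity Per-band (or scalar) log-normal sigma of per-ROI
#'   amplitude multipliers; 0 = spatially homogeneous.
#' @param subject_sd Log-normal sigma of per-subject, per-band amplitude
#'   multipliers (0 = identical subjects).
#' @param noise_amplitude RMS of the 1/f background (power proportional to
#'   1/f between 1 and 70 Hz).
#' @param duration_s Recording duration in seconds.
#' @param fs_hz Sampling rate in Hz; must exceed twice the highest band
#'   edge.
#' @param scheme A [band_scheme()].
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_subjects_per_group = c(risk = 2, protective = 3),
#'             duration_s = 10)
#' @export
cohort_spec <- function(n_subjects_per_group = c(risk = 18, protective = 35),
                        band_amplitudes = c(delta = 0.45, theta = 0.35,
                                            alpha = 0.55, beta = 0.33,
                                            gamma = 0.18),
                        effect_multipliers = NULL,
                        heterogeneity = 0.3,
                        subject_sd = 0.2,
                        noise_amplitude = 0.5,
                        duration_s = 300,
                        fs_hz = 500,
                        scheme = band_scheme()) {
  nb <- band_names(scheme)
  n_subjects_per_group <- unlist(n_subjects_per_group)  # lists from YAML
  if (length(n_subjects_per_group) != 2 ||
      !all(vapply(n_subjects_per_group, is_count, TRUE))) {
    stopf("n_subjects_per_group must be two nonnegative counts")
  }
  if (is.null(names(n_subjects_per_group))) {
    names(n_subjects_per_group) <- c("risk", "protective")
  }
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, length(nb)), nb)
    if (is.null(names(x)) && length(x) == length(nb)) names(x) <- nb
    if (!all(nb %in% names(x))) stopf("%s must name every band", what)
    x[nb]
  }
  band_amplitudes <- expand(band_amplitudes, "band_amplitudes")
  effect_multipliers <- expand(effect_multipliers %||%
                                 stats::setNames(rep(1, length(nb)), nb),
                               "effect_multipliers")
  heterogeneity <- expand(heterogeneity, "heterogeneity")
  if (any(band_amplitudes < 0) || noise_amplitude < 0 ||
      any(effect_multipliers < 0)) {
    stopf("amplitudes and multipliers must be nonnegative")
  }
  if (any(heterogeneity < 0) || subject_sd < 0) {
    stopf("dispersion coefficients must be nonnegative")
  }
  if (fs_hz <= 2 * max(scheme$f_hi)) {
    stopf("fs_hz must exceed twice the highest band edge (%g Hz)",
          max(scheme$f_hi))
  }
  if (duration_s <= 0) stopf("duration_s must be positive")
  structure(
    list(
      n_subjects_per_group = n_subjects_per_group,
      band_amplitudes = band_amplitudes,
      effect_multipliers = effect_multipliers,
      heterogeneity = heterogeneity,
      subject_sd = subject_sd,
      noise_amplitude = noise_amplitude,
      duration_s = duration_s,
      fs_hz = fs_hz,
      scheme = scheme
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d risk + %d protective subjects, %.0f s @ %g Hz\n",
    x$n_subjects_per_group[1], x$n_subjects_per_group[2],
    x$duration_s, x$fs_hz
  ))
  cat("amplitudes:",
      paste(sprintf("%s=%.2f", names(x$band_amplitudes), x$band_amplitudes),
            collapse = " "), "\n")
  invisible(x)
}

# Synthesize band-limited Gaussian series by frequency-domain shaping.
# amp: [n_series x n_bands] RMS amplitude per band; pink_amp: per-series RMS
# of the 1/f background. Returns [n_samples x n_series]. The per-band
# variance of the output equals amp^2 exactly in expectation, because each
# band's spectral mass lives only in its own bins (same half-open band-edge
# convention as the analysis side).
synth_spectrum <- function(n_samples, fs_hz, amp, pink_amp, scheme,
                           bands_keep = NULL) {
  n_series <- nrow(amp)
  kmax <- floor((n_samples - 1) / 2)
  f <- seq_len(kmax) * fs_hz / n_samples
  rng <- attr(scheme, "range")
  nb <- nrow(scheme)
  keep <- bands_keep %||% seq_len(nb)
  # per-bin variance profile [kmax x n_series]
  prof <- matrix(0, kmax, n_series)
  for (b in keep) {
    m <- band_mask(f, scheme, b)
    nbins <- sum(m)
    if (nbins == 0) next
    # E|Z_k|^2 summed over the band's conjugate pairs gives amp^2 * n^2
    prof[m, ] <- prof[m, ] +
      rep(amp[, b]^2 * n_samples^2 / (2 * nbins), each = nbins)
  }
  if (any(pink_amp > 0)) {
    m <- f >= rng[1] & f <= rng[2]
    w <- 1 / f[m]
    w <- w / sum(w)
    prof[m, ] <- prof[m, ] +
      outer(w, pink_amp^2 * n_samples^2 / 2)
  }
  # draw complex Gaussians only for occupied bins; return the
  # positive-frequency half-spectrum (bins 1..kmax; DC and Nyquist zero)
  nz <- which(rowSums(prof) > 0)
  z <- matrix(complex(
    real = stats::rnorm(length(nz) * n_series),
    imaginary = stats::rnorm(length(nz) * n_series)
  ), length(nz), n_series) * sqrt(prof[nz, , drop = FALSE] / 2)
  spec <- matrix(0 + 0i, kmax, n_series)
  spec[nz, ] <- z
  spec
}

synth_series <- function(n_samples, fs_hz, amp, pink_amp, scheme,
                         bands_keep = NULL) {
  spec <- synth_spectrum(n_samples, fs_hz, amp, pink_amp, scheme, bands_keep)
  cpp_hermitian_ifft(spec, n_samples)
}

# Draw one subject's ground-truth amplitudes and complex source spectrum
# under the subject seed (shared by generate_subject and the batched
# cohort paths, so both consume the RNG identically).
draw_subject_spectrum <- function(spec, group_label, model, subject_seed) {
  rois <- unique(model$roi_labels)
  n_samples <- round(spec$duration_s * spec$fs_hz)
  with_seed(subject_seed, {
    gt <- subject_roi_amplitudes(spec, group_label, length(rois))
    roi_idx <- match(model$roi_labels, rois)
    k_roi <- tabulate(roi_idx, length(rois))
    # per-source amplitude so that the ROI-level sum has RMS = ROI amplitude
    src_amp <- gt$roi_amp[roi_idx, , drop = FALSE] / sqrt(k_roi[roi_idx])
    pink_src <- spec$noise_amplitude / sqrt(k_roi[roi_idx])
    S <- synth_spectrum(n_samples, spec$fs_hz, src_amp, pink_src,
                        spec$scheme)
    list(spectrum = S, roi_idx = roi_idx, rois = rois, band_amp = gt$band_amp)
  })
}

# Effective per-ROI band amplitudes for one subject (ground truth).
subject_roi_amplitudes <- function(spec, group_label, n_rois) {
  nb <- length(spec$band_amplitudes)
  subj_mult <- exp(stats::rnorm(nb, 0, spec$subject_sd))
  amp_b <- spec$band_amplitudes * subj_mult
  if (group_label == "risk") amp_b <- amp_b * spec$effect_multipliers
  het <- matrix(stats::rnorm(n_rois * nb), n_rois, nb)
  het <- exp(sweep(het, 2, spec$heterogeneity, `*`))
  roi_amp <- sweep(het, 2, amp_b, `*`)
  colnames(roi_amp) <- names(spec$band_amplitudes)
  list(roi_amp = roi_amp, band_amp = amp_b)
}

#' Generate one synthetic subject
#'
#' Draws a single subject's recording from a [cohort_spec()]: per-source
#' band-limited oscillations at the subject's per-ROI amplitudes plus a 1/f
#' background, mixed to the sensors through the forward model's lead field.
#'
#' @param spec A [cohort_spec()].
#' @param group_label `"risk"` or `"protective"`; the spec's effect
#'   multipliers act on the risk group only.
#' @param model A [forward_model()].
#' @param subject_seed Integer seed; output is deterministic given the
#'   seed.
#' @param output `"sensor"` (lead-field-mixed channels), `"roi"`
#'   (member-source signals summed per ROI, bypassing the inverse stage) or
#'   `"source"` (raw source time series).
#'
#' @return An [recording()]; for `"roi"` / `"source"` output the channel
#'   labels are ROI / source names. Ground-truth per-band amplitudes are
#'   attached as attribute `band_amp`.
#' @export
generate_subject <- function(spec, group_label, model, subject_seed,
                             output = c("sensor", "roi", "source")) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "forward_model"))
  output <- match.arg(output)
  if (!group_label %in% c("risk", "protective")) {
    stopf("unknown group label '%s'", group_label)
  }
  n_sources <- ncol(model$lead_field)
  n_samples <- round(spec$duration_s * spec$fs_hz)
  dr <- draw_subject_spectrum(spec, group_label, model, subject_seed)
  x <- cpp_hermitian_ifft(dr$spectrum, n_samples)
  data <- switch(output,
    sensor = model$lead_field %*% t(x),
    roi = rowsum(t(x), group = dr$roi_idx),
    source = t(x)
  )
  labels <- switch(output,
    sensor = if (nrow(model$lead_field) == 19) channels_1020() else NULL,
    roi = dr$rois,
    source = sprintf("src%04d", seq_len(n_sources))
  )
  rec <- recording(data, spec$fs_hz, labels)
  attr(rec, "band_amp") <- dr$band_amp
  attr(rec, "level") <- output
  rec
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects_per_group` recordings per genotype group, with
#' per-subject seeds derived reproducibly from the master seed, and a
#' metadata table carrying each subject's ground-truth band amplitudes.
#'
#' @inheritParams generate_subject
#' @param seed Master integer seed.
#' @return A list with elements `recordings` (list of [recording()]s) and
#'   `metadata` (tibble: subject_id, group, seed, one `amp_<band>` column
#'   per band).
#' @examples
#' fm <- make_toy_forward_model(8, 12, 4, seed = 1)
#' sp <- cohort_spec(n_subjects_per_group = c(risk = 1, protective = 2),
#'                   duration_s = 5)
#' coh <- generate_cohort(sp, fm, seed = 42)
#' coh$metadata
#' @export
generate_cohort <- function(spec, model, seed,
                            output = c("sensor", "roi", "source")) {
  stopifnot(inherits(spec, "cohort_spec"))
  output <- match.arg(output)
  n <- spec$n_subjects_per_group
  groups <- rep(c("risk", "protective"), times = n)
  total <- sum(n)
  seeds <- derive_seeds(seed, total)
  recs <- vector("list", total)
  meta <- vector("list", total)
  for (i in seq_len(total)) {
    recs[[i]] <- generate_subject(spec, groups[i], model, seeds[i],
                                  output = output)
    amps <- attr(recs[[i]], "band_amp")
    meta[[i]] <- tibble(
      subject_id = sprintf("S%03d", i),
      group = groups[i],
      seed = seeds[i],
      !!!stats::setNames(as.list(amps), paste0("amp_", names(amps)))
    )
  }
  list(recordings = recs, metadata = bind_rows(meta))
}

#' Inject an artifact-like transient into a recording
#'
#' Adds a Gaussian-windowed pulse to selected channels, for exercising the
#' automatic epoch-rejection stage.
#'
#' @param rec An [recording()].
#' @param at_s Center time of the transient in seconds.
#' @param amplitude_uv Peak amplitude in microvolts.
#' @param width_s Gaussian full width (seconds).
#' @param channels Channel indices to contaminate.
#' @return The modified recording.
#' @export
inject_transient <- function(rec, at_s, amplitude_uv = 500, width_s = 0.1,
                             channels = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  t <- seq_len(ncol(rec$data)) / rec$fs_hz
  pulse <- amplitude_uv * exp(-0.5 * ((t - at_s) / (width_s / 2))^2)
  rec$data[channels, ] <- sweep(
    rec$data[channels, , drop = FALSE], 2, pulse, `+`
  )
  rec
}

#' Write a cohort to disk
#'
#' One plain CSV per subject (see [write_recording_csv()]) plus a
#' `metadata.csv`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$recordings)) {
    write_recording_csv(
      cohort$recordings[[i]],
      file.path(dir, paste0(cohort$metadata$subject_id[i], ".csv"))
    )
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
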