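#' Monte-Carlo calibration / power study of the global band tests
#'
#' Repeatedly draws independent synthetic cohorts from a [cohort_spec()],
#' runs the spectral chain (Welch relative power per epoch and ROI,
#' epoch-averaged, ROI-averaged) on the ROI-level signals, and applies the
#' global per-band Mann-Whitney U test between the two genotype groups of
#' every cohort. With all effect multipliers at 1 this measures the
#' empirical type-I error of the test chain; with an effect it measures
#' power.
#'
#' The computation is identical to running [generate_cohort()] (ROI
#' output), [segment_epochs()], [analyze_subjects()] and
#' [compare_groups()] cohort by cohort — the unit tests assert the
#' equality — but the FFT work of all subjects is batched, which is what
#' makes studies with hundreds of cohorts practical. No artifact rejection
#' is applied: the generator injects no artifacts, and on clean data the
#' rejection stage is a no-op by construction.
#'
#' @param spec A [cohort_spec()] (its `effect_multipliers` decide null vs
#'   power study).
#' @param model A [make_toy_forward_model()]; its ROI labelling defines
#'   the spatial granularity.
#' @param n_cohorts Number of independent cohorts to simulate.
#' @param seed Master seed; cohort seeds (and through them subject seeds)
#'   are derived reproducibly.
#' @param epoch_length_s Epoch duration used for the spectral stage.
#' @param roi_tests Also run the per-ROI families with BH correction and
#'   return their rejection counts per band.
#' @return A tibble with one row per cohort and band: `cohort`, `band`,
#'   `p_value` (global test), `significant` (at 0.05), and when
#'   `roi_tests` is set, `n_roi_significant` (FDR-corrected per-ROI
#'   rejections).
#' @examples
#' fm <- make_toy_forward_model(19, 12, 12, seed = 1)
#' sp <- cohort_spec(n_subjects_per_group = c(risk = 5, protective = 5),
#'                   duration_s = 5)
#' power_study(sp, fm, n_cohorts = 2, seed = 1)
#' @export
power_study <- function(spec, model, n_cohorts, seed, epoch_length_s = 5,
                        roi_tests = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "forward_model"))
  scheme <- spec$scheme
  nb <- nrow(scheme)
  rng <- attr(scheme, "range")
  n <- spec$n_subjects_per_group
  total <- sum(n)
  if (total < 4) stopf("need at least 2 subjects per group")
  groups <- rep(c("risk", "protective"), times = n)
  g1 <- groups == "risk"
  rois <- unique(model$roi_labels)
  R <- length(rois)
  n_samples <- round(spec$duration_s * spec$fs_hz)
  len <- round(epoch_length_s * spec$fs_hz)
  n_ep <- n_samples %/% len
  if (n_ep < 1) stopf("duration_s shorter than one epoch")
  cohort_seeds <- derive_seeds(seed, n_cohorts)
  # loop-invariant Welch geometry: 1 s segments at 1 Hz resolution
  nperseg <- round(spec$fs_hz)
  freq <- (seq_len(nperseg %/% 2 + 1) - 1) * spec$fs_hz / nperseg
  keep <- freq >= rng[1] & freq <= rng[2]
  f <- freq[keep]
  B <- vapply(seq_len(nb), function(b) as.numeric(band_mask(f, scheme, b)),
              numeric(length(f)))
  out <- vector("list", n_cohorts)
  for (ci in seq_len(n_cohorts)) {
    seeds <- derive_seeds(cohort_seeds[ci], total)
    X <- matrix(0, n_samples, R * total)
    for (s in seq_len(total)) {
      dr <- draw_subject_spectrum(spec, groups[s], model, seeds[s])
      S <- dr$spectrum
      if (ncol(S) > R) {
        # sum member-source spectra per ROI (linear, same as summing series)
        S <- t(rowsum(t(Re(S)), dr$roi_idx)) +
          1i * t(rowsum(t(Im(S)), dr$roi_idx))
      }
      X[, (s - 1) * R + seq_len(R)] <- cpp_hermitian_ifft(S, n_samples)
    }
    # split every column into consecutive epochs (epoch index fastest)
    Xe <- matrix(X[seq_len(n_ep * len), , drop = FALSE], nrow = len)
    W <- welch_matrix(Xe, spec$fs_hz, nperseg)
    P <- W$psd[keep, , drop = FALSE]
    Pn <- sweep(P, 2, colSums(P), `/`)
    band_p <- t(B) %*% Pn                     # [band x (epoch,roi,subject)]
    rp <- if (n_ep == 1) {
      array(band_p, c(nb, R, total))          # [band x roi x subject]
    } else {
      cube <- array(band_p, c(nb, n_ep, R, total))
      apply(cube, c(1, 3, 4), mean)
    }
    M <- matrix(rp, nb * R, total)
    glob <- vapply(seq_len(nb), function(b) {
      colMeans(M[b + nb * (seq_len(R) - 1), , drop = FALSE])
    }, numeric(total))                        # [subject x band]
    t_glob <- mw_many(glob[g1, , drop = FALSE], glob[!g1, , drop = FALSE])
    row <- tibble(
      cohort = ci, band = band_names(scheme),
      p_value = t_glob$p_value, significant = t_glob$p_value <= 0.05
    )
    if (roi_tests) {
      nsig <- vapply(seq_len(nb), function(b) {
        M <- t(rp[b, , ])                     # [subject x roi]
        t_roi <- mw_many(M[g1, , drop = FALSE], M[!g1, , drop = FALSE])
        sum(benjamini_hochberg(t_roi$p_value, 0.05)$flags)
      }, numeric(1))
      row$n_roi_significant <- nsig
    }
    out[[ci]] <- row
  }
  bind_rows(out)
}
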