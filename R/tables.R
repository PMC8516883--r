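#' Relative power and spatial entropy tables for a set of subjects
#'
#' Runs [rp_per_subject()] and [se_per_subject()] over a list of
#' [roi_signals()] and assembles tidy tables: one RP row per (subject,
#' ROI, band), one SE row per (subject, band), and one subject-mean
#' normalized PSD row per (subject, frequency bin).
#'
#' @param rsig_list List of [roi_signals()], one per subject.
#' @param subject_ids Character vector, one id per element of
#'   `rsig_list`.
#' @param scheme A [band_scheme()].
#' @return A list with tibbles `rp` (class `rp_table`: subject_id, roi,
#'   band, rp), `se` (class `se_table`: subject_id, band, se) and `psd`
#'   (subject_id, freq, psd_n).
#' @examples
#' fm <- make_toy_forward_model(8, 8, 4, seed = 2)
#' sp <- cohort_spec(n_subjects_per_group = c(risk = 1, protective = 1),
#'                   duration_s = 10)
#' coh <- generate_cohort(sp, fm, seed = 5, output = "roi")
#' eps <- lapply(coh$recordings, function(r)
#'   as_roi_signals(segment_epochs(r, 5)))
#' tabs <- analyze_subjects(eps, coh$metadata$subject_id)
#' head(tabs$rp)
#' @export
analyze_subjects <- function(rsig_list, subject_ids,
                             scheme = band_scheme()) {
  stopifnot(length(rsig_list) == length(subject_ids))
  rp_rows <- list()
  se_rows <- list()
  psd_rows <- list()
  nb <- band_names(scheme)
  for (i in seq_along(rsig_list)) {
    res <- rp_per_subject(rsig_list[[i]], scheme)
    rp_rows[[i]] <- tibble(
      subject_id = subject_ids[i],
      roi = rep(rownames(res$rp), times = length(nb)),
      band = rep(nb, each = nrow(res$rp)),
      rp = as.vector(res$rp)
    )
    se_rows[[i]] <- tibble(
      subject_id = subject_ids[i],
      band = nb,
      se = vapply(seq_along(nb), function(b) {
        se_per_subject(matrix(res$per_epoch[, , b],
                              nrow = dim(res$per_epoch)[1]))
      }, numeric(1))
    )
    psd_rows[[i]] <- tibble(
      subject_id = subject_ids[i],
      freq = res$psd_n$freq,
      psd_n = res$psd_n$psd_n
    )
  }
  list(
    rp = structure(bind_rows(rp_rows), class = c("rp_table", class(tibble()))),
    se = structure(bind_rows(se_rows), class = c("se_table", class(tibble()))),
    psd = bind_rows(psd_rows)
  )
}

#' Epochs of a ROI-level recording as ROI signals
#'
#' The synthetic generator can emit ROI-level recordings directly
#' (bypassing the inverse stage); this converts their [epoch_set()] into
#' the [roi_signals()] container the spectral stage consumes.
#'
#' @param epochs An [epoch_set()] whose "channels" are atlas ROIs.
#' @return A [roi_signals()].
#' @export
as_roi_signals <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  roi_signals(epochs$epochs, epochs$channel_labels, epochs$fs_hz)
}

#' Serialize RP / SE tables
#'
#' Long-format CSVs (`subject_id, roi, band, rp` / `subject_id, band,
#' se`); `write_rp_wide()` writes the RP table in wide format with one
#' `roi_band` column per combination.
#'
#' @param tab A table from [analyze_subjects()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
write_rp_wide <- function(tab, path) {
  wide <- pivot_wider(as_tibble(tab),
                      names_from = c("roi", "band"),
                      values_from = "rp")
  utils::write.csv(as.data.frame(wide), path, row.names = FALSE)
  invisible(path)
}
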