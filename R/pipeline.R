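#' Pipeline configuration
#'
#' Assembles and validates the full set of run parameters: input mode,
#' preprocessing, inverse stage, band scheme, statistics options, output
#' directory and master seed. Defaults mirror the study's printed
#' parameters: 500 Hz sampling, 1-70 Hz band-pass, 50 Hz notch, 5 s
#' epochs, 68 ROIs, alpha = q = 0.05.
#'
#' @param input_mode `"synthetic"` (generate a cohort) or `"ascii"` (read
#'   per-subject CSV matrices plus `metadata.csv` from `input_dir`).
#' @param input_dir Directory of recordings for `"ascii"` mode.
#' @param cohort List of arguments for [cohort_spec()] (synthetic mode).
#' @param forward List of arguments for [make_toy_forward_model()], or
#'   `list(path = <stem>)` to read a model with [read_forward_model()].
#' @param preprocessing List: `notch_hz`, `band`, `epoch_length_s`,
#'   `ptp_threshold_uv`, `z_threshold`.
#' @param inverse List: `alpha` (NULL = automatic), `bypass` (TRUE =
#'   generate/consume ROI-level signals and skip the inverse stage),
#'   `aggregate` (`"mean"` or `"power"`).
#' @param stats List: `q`, `alpha`, `u_convention`.
#' @param output_dir Where run artifacts are written.
#' @param seed Master seed controlling every random draw.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "ascii"),
                            input_dir = NULL,
                            cohort = list(),
                            forward = list(n_sensors = 19, n_sources = 68,
                                           n_rois = 68),
                            preprocessing = list(),
                            inverse = list(),
                            stats = list(),
                            output_dir = tempfile("eegspect_run_"),
                            seed = 1) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "ascii" && (is.null(input_dir) || !dir.exists(input_dir))) {
    stopf("ascii mode needs an existing input_dir")
  }
  pp <- utils::modifyList(
    list(notch_hz = 50, band = c(1, 70), epoch_length_s = 5,
         ptp_threshold_uv = 150, z_threshold = 4),
    preprocessing
  )
  inv <- utils::modifyList(
    list(alpha = NULL, bypass = FALSE, aggregate = "mean"), inverse
  )
  st <- utils::modifyList(
    list(q = 0.05, alpha = 0.05, u_convention = "first"), stats
  )
  if (st$q <= 0 || st$q > 1 || st$alpha <= 0 || st$alpha > 1) {
    stopf("q and alpha must lie in (0, 1]")
  }
  structure(
    list(input_mode = input_mode, input_dir = input_dir, cohort = cohort,
         forward = forward, preprocessing = pp, inverse = inv, stats = st,
         output_dir = output_dir, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation (or loading), preprocessing, source
#' localization (or the ROI-level bypass), relative power and spatial
#' entropy computation, nonparametric group statistics and grand-average
#' summaries. Everything is written into `config$output_dir`: `rp.csv`,
#' `se.csv`, `stats.csv`, `qc.csv` (epochs kept per subject), the grand
#' averaged normalized spectra (`psd_grand_average.csv`), the serialized
#' configuration and a JSON run manifest. Subjects whose epochs are all
#' rejected are excluded with a logged warning, never silently.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `rp`, `se`, `psd`, `stats`, `qc`,
#'   `metadata` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- band_scheme()
  pp <- config$preprocessing

  model <- if (!is.null(config$forward$path)) {
    read_forward_model(config$forward$path)
  } else {
    do.call(make_toy_forward_model,
            c(config$forward, list(seed = config$seed)))
  }

  if (config$input_mode == "synthetic") {
    spec <- do.call(cohort_spec, config$cohort)
    cohort <- generate_cohort(
      spec, model, seed = config$seed,
      output = if (config$inverse$bypass) "roi" else "sensor"
    )
    recordings <- cohort$recordings
    metadata <- cohort$metadata
  } else {
    metadata <- as_tibble(utils::read.csv(
      file.path(config$input_dir, "metadata.csv"), stringsAsFactors = FALSE
    ))
    recordings <- lapply(metadata$subject_id, function(id) {
      path <- file.path(config$input_dir, paste0(id, ".csv"))
      if (!file.exists(path)) stopf("missing recording %s", path)
      read_recording_csv(path)
    })
  }

  op <- if (!config$inverse$bypass) {
    build_inverse(model, alpha = config$inverse$alpha)
  }

  rsig <- vector("list", length(recordings))
  qc <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (config$inverse$bypass) {
      # ROI-level signals: no sensor-space filtering chain
      ep <- reject_artifact_epochs(
        segment_epochs(remove_mean(rec), pp$epoch_length_s),
        pp$ptp_threshold_uv, pp$z_threshold
      )
      kept <- dim(ep$epochs)[1]
      if (kept > 0) rsig[[i]] <- as_roi_signals(ep)
    } else {
      ep <- preprocess(rec, notch_hz = pp$notch_hz, band = pp$band,
                       epoch_length_s = pp$epoch_length_s,
                       ptp_threshold_uv = pp$ptp_threshold_uv,
                       z_threshold = pp$z_threshold)
      kept <- dim(ep$epochs)[1]
      if (kept > 0) {
        rsig[[i]] <- extract_roi_signals(op, ep, model,
                                         aggregate = config$inverse$aggregate)
      }
    }
    qc[[i]] <- tibble(subject_id = metadata$subject_id[i],
                      epochs_kept = kept)
  }
  qc <- bind_rows(qc)
  empty <- qc$subject_id[qc$epochs_kept == 0]
  if (length(empty) > 0) {
    warn(sprintf("excluding %d subject(s) with no surviving epochs: %s",
                 length(empty), paste(empty, collapse = ", ")))
  }
  keep <- qc$epochs_kept > 0
  tabs <- analyze_subjects(rsig[keep], metadata$subject_id[keep], scheme)

  stats_tab <- NULL
  md_keep <- metadata[keep, ]
  if ("group" %in% names(md_keep) &&
      length(unique(md_keep$group)) == 2 &&
      all(table(md_keep$group) >= 2)) {
    stats_tab <- compare_groups(
      tabs$rp, tabs$se, md_keep, q = config$stats$q,
      alpha = config$stats$alpha, convention = config$stats$u_convention
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegspect")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    n_subjects = nrow(metadata),
    n_excluded = length(empty)
  )

  write_table_csv(tabs$rp, file.path(config$output_dir, "rp.csv"))
  write_table_csv(tabs$se, file.path(config$output_dir, "se.csv"))
  write_table_csv(qc, file.path(config$output_dir, "qc.csv"))
  grand <- tabs$psd |>
    group_by(.data$freq) |>
    summarise(psd_n = mean(.data$psd_n), .groups = "drop")
  write_table_csv(grand,
                  file.path(config$output_dir, "psd_grand_average.csv"))
  if (all(c("group", "severity") %in% names(md_keep))) {
    sg <- summarize_psd_by_group(tabs$psd, tabs$rp, md_keep)
    write_table_csv(sg$psd,
                    file.path(config$output_dir, "psd_by_group_severity.csv"))
    write_table_csv(sg$spider,
                    file.path(config$output_dir, "rp_spider.csv"))
  }
  if (!is.null(stats_tab)) {
    write_table_csv(tidy(stats_tab), file.path(config$output_dir, "stats.csv"))
  }
  yaml::write_yaml(manifest$config, file.path(config$output_dir, "config.yaml"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(rp = tabs$rp, se = tabs$se, psd = tabs$psd,
                 stats = stats_tab, qc = qc, metadata = metadata,
                 manifest = manifest))
}

#' Grand-average spectra and band profile by group and severity
#'
#' Grand-averaged normalized PSD and mean per-band relative power ("spider
#' plot" table) for each combination of genotype group and disease
#' severity, the summary used to inspect EEG slowing along the disease
#' continuum.
#'
#' @param psd Tibble `subject_id, freq, psd_n` from [analyze_subjects()].
#' @param rp An `rp_table`.
#' @param metadata Data frame with `subject_id`, `group` and a severity
#'   column with labels among `MIL`, `MOD`, `SEV`, `control`.
#' @param severity_col Name of the severity column.
#' @return A list with tibbles `psd` (group, severity, freq, psd_n) and
#'   `spider` (group, severity, band, rp).
#' @export
summarize_psd_by_group <- function(psd, rp, metadata,
                                   severity_col = "severity") {
  md <- as_tibble(metadata)
  if (!severity_col %in% names(md)) {
    stopf("metadata lacks a '%s' column", severity_col)
  }
  sev <- md[[severity_col]]
  bad <- setdiff(unique(sev), c("MIL", "MOD", "SEV", "control"))
  if (length(bad) > 0) {
    stopf("unknown severity label(s): %s", paste(bad, collapse = ", "))
  }
  md <- md |>
    mutate(severity = sev) |>
    select(all_of(c("subject_id", "group", "severity")))
  psd_avg <- psd |>
    left_join(md, by = "subject_id") |>
    group_by(.data$group, .data$severity, .data$freq) |>
    summarise(psd_n = mean(.data$psd_n), .groups = "drop")
  spider <- as_tibble(rp) |>
    group_by(.data$subject_id, .data$band) |>
    summarise(rp = mean(.data$rp), .groups = "drop") |>
    left_join(md, by = "subject_id") |>
    group_by(.data$group, .data$severity, .data$band) |>
    summarise(rp = mean(.data$rp), .groups = "drop")
  list(psd = psd_avg, spider = spider)
}
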