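#' Desikan-Killiany atlas region labels
#'
#' The 68 cortical region labels of the Desikan-Killiany gyrus-based atlas
#' (34 regions per hemisphere, prefixed `lh_` / `rh_`).
#'
#' @return Character vector of length 68.
#' @export
dk_atlas_labels <- function() {
  regions <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
  c(paste0("lh_", regions), paste0("rh_", regions))
}

#' Forward model (lead field + source space)
#'
#' Couples a lead-field gain matrix mapping cortical source currents to
#' sensor potentials with source positions and an atlas labelling of the
#' sources.
#'
#' @param lead_field Numeric matrix `[n_sensors x n_sources]` of unitless
#'   gains; must have full row rank.
#' @param source_positions Numeric matrix `[n_sources x 3]` (arbitrary
#'   units).
#' @param roi_labels Character vector of length `n_sources`; every distinct
#'   label must index at least one source.
#'
#' @return An object of class `forward_model`.
#' @seealso [make_toy_forward_model()]
#' @export
forward_model <- function(lead_field, source_positions, roi_labels) {
  lead_field <- as.matrix(lead_field)
  if (nrow(lead_field) < 3) stopf("need at least 3 sensors")
  if (!all(is.finite(lead_field))) stopf("lead field must be finite")
  if (length(roi_labels) != ncol(lead_field)) {
    stopf("need one ROI label per source")
  }
  if (any(colSums(abs(lead_field)) == 0)) {
    stopf("lead field has an all-zero column")
  }
  if (qr(lead_field)$rank < nrow(lead_field)) {
    stopf("lead field must have full row rank")
  }
  source_positions <- as.matrix(source_positions)
  if (nrow(source_positions) != ncol(lead_field) ||
      ncol(source_positions) != 3) {
    stopf("source_positions must be [n_sources x 3]")
  }
  structure(
    list(
      lead_field = lead_field,
      source_positions = source_positions,
      roi_labels = as.character(roi_labels)
    ),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "<forward_model> %d sensors, %d sources, %d ROIs\n",
    nrow(x$lead_field), ncol(x$lead_field), length(unique(x$roi_labels))
  ))
  invisible(x)
}

#' Build a toy forward model
#'
#' A configurable stand-in for a realistic head model: sources are placed
#' uniformly on a unit sphere, sensors on a concentric sphere of radius 1.1,
#' and gains fall off with the inverse square of the sensor-source distance.
#' ROI labels partition the sources as evenly as possible, in order. With
#' `n_rois = 68` the labels are the Desikan-Killiany region names.
#'
#' @param n_sensors Number of sensors (>= 3).
#' @param n_sources Number of scalar (fixed-orientation) sources
#'   (>= `n_rois`).
#' @param n_rois Number of atlas regions (default 68).
#' @param seed Integer seed; the model is deterministic given the seed.
#'
#' @return A [forward_model()].
#' @examples
#' fm <- make_toy_forward_model(19, 68, 68, seed = 1)
#' dim(fm$lead_field)
#' @export
make_toy_forward_model <- function(n_sensors, n_sources, n_rois = 68,
                                   seed = 1) {
  if (!is_count(n_sensors) || n_sensors < 3) stopf("n_sensors must be >= 3")
  if (!is_count(n_rois) || n_rois < 1) stopf("n_rois must be >= 1")
  if (!is_count(n_sources) || n_sources < n_rois) {
    stopf("need n_sources >= n_rois")
  }
  with_seed(seed, {
    unit_sphere <- function(n, radius) {
      p <- matrix(stats::rnorm(n * 3), n, 3)
      radius * p / sqrt(rowSums(p^2))
    }
    src <- unit_sphere(n_sources, 1)
    sens <- unit_sphere(n_sensors, 1.1)
    # inverse-square gain with random source orientation sign
    d2 <- outer(seq_len(n_sensors), seq_len(n_sources), function(i, j) {
      rowSums((sens[i, , drop = FALSE] - src[j, , drop = FALSE])^2)
    })
    gain <- 1 / (d2 + 0.1)
    gain <- gain * matrix(stats::rnorm(n_sensors * n_sources, sd = 0.05),
                          n_sensors, n_sources) + gain
    labels <- if (n_rois == 68) dk_atlas_labels() else sprintf("roi%03d", seq_len(n_rois))
    # even partition: first (n_sources mod n_rois) ROIs get one extra source
    sizes <- rep(n_sources %/% n_rois, n_rois)
    extra <- n_sources %% n_rois
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    forward_model(gain, src, rep(labels, times = sizes))
  })
}

#' Read / write a forward model as a pair of CSV files
#'
#' The gain matrix goes to `<stem>_gain.csv` (plain numeric matrix, sensors
#' by sources); the source table (x, y, z, roi) to `<stem>_sources.csv`.
#'
#' @param model A [forward_model()].
#' @param stem Path stem for the two files.
#' @return `read_forward_model()` returns a `forward_model`;
#'   `write_forward_model()` returns `stem` invisibly.
#' @export
write_forward_model <- function(model, stem) {
  stopifnot(inherits(model, "forward_model"))
  utils::write.table(model$lead_field, paste0(stem, "_gain.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(
    data.frame(model$source_positions, roi = model$roi_labels),
    paste0(stem, "_sources.csv"), row.names = FALSE
  )
  invisible(stem)
}

#' @rdname write_forward_model
#' @export
read_forward_model <- function(stem) {
  gain <- as.matrix(utils::read.csv(paste0(stem, "_gain.csv"), header = FALSE))
  dimnames(gain) <- NULL
  src <- utils::read.csv(paste0(stem, "_sources.csv"),
                         stringsAsFactors = FALSE)
  forward_model(gain, as.matrix(src[, 1:3]), src$roi)
}
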