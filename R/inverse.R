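#' Standardized minimum-norm inverse operator
#'
#' Builds an sLORETA-style inverse operator for a forward model, assuming
#' an identity noise covariance and average-referenced sensor data. With
#' `K` the lead field and `H` the average-reference centering operator, the
#' minimum-norm kernel is
#' \deqn{W = K^T H (H K K^T H + \alpha H)^+ H,}
#' (pseudoinverse on the centered sensor space), and source estimates are
#' standardized by the diagonal of the model resolution matrix `W K`. This
#' standardization is what gives zero localization error for noiseless
#' point sources.
#'
#' @param model A [forward_model()].
#' @param alpha Regularization scalar (>= 0). Defaults to
#'   `1e-8 * trace(H K K^T H) / n_sensors`, appropriate for noiseless
#'   data; increase for noisy recordings.
#' @return An object of class `inverse_operator` with fields `kernel`
#'   (`[n_sources x n_sensors]`), `resolution_diag` (positive) and
#'   `alpha`.
#' @examples
#' fm <- make_toy_forward_model(8, 20, 4, seed = 7)
#' inv <- build_inverse(fm)
#' @export
build_inverse <- function(model, alpha = NULL) {
  stopifnot(inherits(model, "forward_model"))
  K <- model$lead_field
  m <- nrow(K)
  H <- centering_operator(m)
  G <- H %*% K %*% t(K) %*% H
  if (is.null(alpha)) alpha <- 1e-8 * sum(diag(G)) / m
  if (alpha < 0) stopf("alpha must be nonnegative")
  if (alpha == 0) {
    # the centered Gram matrix is rank m-1 by construction; anything less
    # means the centered lead field itself is rank deficient
    if (qr(G, tol = 1e-10)$rank < m - 1) {
      stopf("centered Gram matrix is rank deficient; use alpha > 0")
    }
  }
  A <- G + alpha * H
  kernel <- t(K) %*% H %*% pinv(A) %*% H
  rd <- diag(kernel %*% K)
  rd <- pmax(rd, 1e-12 * max(rd, 1e-300))
  structure(
    list(kernel = kernel, resolution_diag = rd, alpha = alpha,
         roi_labels = model$roi_labels),
    class = "inverse_operator"
  )
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d sources x %d sensors, alpha = %.3g\n",
              nrow(x$kernel), ncol(x$kernel), x$alpha))
  invisible(x)
}

#' Standardized source power for one sensor frame
#'
#' Applies the inverse kernel to a single sensor vector (the kernel centers
#' it to the average reference internally) and standardizes the squared
#' source estimates by the resolution diagonal. For noiseless data
#' generated by a single source, the standardized power peaks exactly at
#' that source.
#'
#' @param op An [build_inverse()] operator.
#' @param sensor_frame Numeric vector of length `n_sensors`.
#' @return Numeric vector of standardized source power.
#' @export
localize <- function(op, sensor_frame) {
  stopifnot(inherits(op, "inverse_operator"))
  if (length(sensor_frame) != ncol(op$kernel)) {
    stopf("frame length %d does not match %d sensors",
          length(sensor_frame), ncol(op$kernel))
  }
  j <- drop(op$kernel %*% sensor_frame)
  j^2 / op$resolution_diag
}

#' ROI-level time series
#'
#' @param data Array `[n_epochs x n_rois x n_samples]`.
#' @param roi_labels Atlas names, one per ROI.
#' @param fs_hz Sampling rate.
#' @return An object of class `roi_signals`.
#' @export
roi_signals <- function(data, roi_labels, fs_hz) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(roi_labels)) {
    stopf("need one label per ROI")
  }
  if (!all(is.finite(data))) stopf("ROI signals must be finite")
  structure(list(data = data, roi_labels = roi_labels, fs_hz = fs_hz),
            class = "roi_signals")
}

#' @export
print.roi_signals <- function(x, ...) {
  cat(sprintf("<roi_signals> %d epochs x %d ROIs x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs_hz))
  invisible(x)
}

#' Source-localize epochs and aggregate to ROI time series
#'
#' Applies the inverse kernel sample-by-sample to every epoch and collapses
#' the member sources of each atlas region. Aggregation is either the
#' arithmetic mean of the member-source time series (default; no
#' sign-flipping) or, with `aggregate = "power"`, the mean of the per-source
#' standardized power (in which case the "time series" are nonnegative
#' power traces).
#'
#' @param op An [build_inverse()] operator.
#' @param epochs An [epoch_set()] whose channel count matches the lead
#'   field rows.
#' @param model The [forward_model()] the operator was built from.
#' @param aggregate `"mean"` or `"power"`.
#' @return A [roi_signals()] array `[n_epochs x n_rois x n_samples]`.
#' @export
extract_roi_signals <- function(op, epochs, model,
                                aggregate = c("mean", "power")) {
  stopifnot(inherits(op, "inverse_operator"), inherits(epochs, "epoch_set"))
  aggregate <- match.arg(aggregate)
  ne <- dim(epochs$epochs)[1]
  if (ne == 0) stopf("empty epoch set")
  if (dim(epochs$epochs)[2] != ncol(op$kernel)) {
    stopf("channel count does not match the lead field")
  }
  rois <- unique(model$roi_labels)
  roi_idx <- match(model$roi_labels, rois)
  ns <- dim(epochs$epochs)[3]
  out <- array(0, dim = c(ne, length(rois), ns))
  for (e in seq_len(ne)) {
    src <- op$kernel %*% epochs$epochs[e, , ]
    agg <- if (aggregate == "mean") {
      rowsum(src, roi_idx) / as.vector(table(roi_idx))
    } else {
      rowsum(src^2 / op$resolution_diag, roi_idx) /
        as.vector(table(roi_idx))
    }
    out[e, , ] <- agg
  }
  roi_signals(out, rois, epochs$fs_hz)
}
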