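#' Freedman-Diaconis histogram edges
#'
#' Equal-width bin edges spanning `[min(x), max(x)]` with bin width
#' \eqn{h = 2\,IQR\,n^{-1/3}} (quartiles by linear interpolation of order
#' statistics, i.e. R's default type-7 quantiles) and
#' `n_bins = ceiling((max - min)/h)`. Degenerate inputs (zero IQR or all
#' values equal) yield a single bin.
#'
#' @param values At least two finite numeric values.
#' @return Ascending numeric vector of bin edges (length `n_bins + 1`).
#' @examples
#' freedman_diaconis_edges(1:8)  # width 3.5 -> edges 1, 4.5, 8
#' @export
freedman_diaconis_edges <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values))) {
    stopf("need at least 2 finite values")
  }
  rng <- range(values)
  iqr <- stats::IQR(values, type = 7)
  h <- 2 * iqr * length(values)^(-1 / 3)
  if (iqr == 0 || rng[1] == rng[2] || h <= 0) {
    return(rng + c(0, if (rng[1] == rng[2]) 1e-12 else 0))
  }
  n_bins <- ceiling((rng[2] - rng[1]) / h)
  seq(rng[1], rng[2], length.out = n_bins + 1)
}

# Histogram counts on equal-width edges; bins are [lo, hi), the last bin
# right-closed.
hist_counts <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(edges) - 1)
}

#' Spatial entropy of a set of regional values
#'
#' Normalized Shannon entropy of the Freedman-Diaconis histogram of the
#' values (natural logarithm; the normalization by `log N` makes the result
#' base-invariant):
#' \deqn{SE = -\frac{1}{\log N} \sum_{n=1}^{N} p_n \log p_n,}
#' with \eqn{0 \log 0 := 0}. SE lies in \eqn{[0, 1]}: 0 for a spatially
#' homogeneous distribution (a single occupied bin, including the
#' degenerate one-bin histogram), 1 when all \eqn{N \ge 2} bins are equally
#' occupied.
#'
#' @param values At least two finite numeric values (e.g. the relative
#'   power of one band over the 68 atlas ROIs in one epoch).
#' @return SE scalar in `[0, 1]`.
#' @examples
#' spatial_entropy(1:8)        # two bins of four values -> 1
#' spatial_entropy(rep(2, 10)) # constant -> 0
#' @export
spatial_entropy <- function(values) {
  edges <- freedman_diaconis_edges(values)
  n_bins <- length(edges) - 1
  if (n_bins < 2) return(0)
  p <- hist_counts(values, edges)
  p <- p / sum(p)
  p <- p[p > 0]
  if (length(p) < 2) return(0)
  -sum(p * log(p)) / log(n_bins)
}

#' Epoch-averaged spatial entropy for one subject and band
#'
#' Computes the spatial entropy of each epoch's regional relative-power
#' values and averages arithmetically across epochs.
#'
#' @param per_epoch_rp Matrix `[n_epochs x n_rois]` of one band's RP
#'   values (>= 1 epoch, >= 2 ROIs).
#' @return SE scalar in `[0, 1]`.
#' @export
se_per_subject <- function(per_epoch_rp) {
  per_epoch_rp <- as.matrix(per_epoch_rp)
  if (nrow(per_epoch_rp) < 1 || ncol(per_epoch_rp) < 2) {
    stopf("need >= 1 epoch and >= 2 ROIs")
  }
  mean(apply(per_epoch_rp, 1, spatial_entropy))
}
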