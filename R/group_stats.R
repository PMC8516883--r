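#' Mann-Whitney U test
#'
#' Two-sample rank-sum test. The exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The reported statistic is the U of the first sample by default
#' (`convention = "second"` reports \eqn{n_1 n_2 - U}).
#'
#' @param x,y Nonempty numeric samples (risk and protective group, say).
#' @param alternative Passed to [stats::wilcox.test()].
#' @param convention Which sample's U to report.
#' @return A one-row tibble: `statistic` (U), `p_value`, `n1`, `n2`,
#'   `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided",
                           convention = c("first", "second")) {
  convention <- match.arg(convention)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stopf("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  u <- unname(wt$statistic)
  if (convention == "second") u <- length(x) * length(y) - u
  tibble(
    statistic = u,
    p_value = wt$p.value,
    n1 = length(x),
    n2 = length(y),
    method = if (exact) "mann-whitney exact" else "mann-whitney normal-approx"
  )
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Classic step-up procedure: with the p-values sorted ascending, all
#' hypotheses up to the largest `i` with \eqn{p_{(i)} \le i q / m} are
#' rejected. Adjusted p-values are the usual cumulative-minimum
#' backtransform, clipped at 1 (identical to
#' `p.adjust(method = "BH")`).
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return A list with `adjusted` (same order as input) and `flags`
#'   (logical rejections).
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)$flags
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p)
  adjusted <- stats::p.adjust(p, method = "BH")
  ord <- order(p)
  thresh <- seq_len(m) * q / m
  below <- p[ord] <= thresh
  flags <- rep(FALSE, m)
  if (any(below)) {
    k <- max(which(below))
    flags[ord[seq_len(k)]] <- TRUE
  }
  list(adjusted = adjusted, flags = flags)
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic \eqn{\sum (O - E)^2 / E} without continuity
#' correction, with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table 2-D nonnegative integer matrix with positive row and
#'   column margins.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`, `method`.
#' @examples
#' pearson_chi2(matrix(c(8, 5, 4, 7), 2))  # 1.51, p = 0.219
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stopf("table must contain nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n = sum(table),
    method = "pearson chi-square"
  )
}

#' Exploratory distribution checks
#'
#' Advisory normality and homoscedasticity screening before the
#' nonparametric comparison: a one-sample Kolmogorov-Smirnov test of each
#' group against a normal with the group's fitted mean and SD, and a
#' Levene test (Brown-Forsythe median centering) of variance homogeneity
#' across groups. The pipeline always proceeds nonparametrically
#' regardless of the outcome.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric values and
#'   group labels; every group needs at least 3 values.
#' @return A tibble with one `ks` row per group and one `levene` row.
#' @export
distribution_checks <- function(data, value, group) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (any(table(g) < 3)) stopf("every group needs at least 3 values")
  ks <- lapply(levels(g), function(lev) {
    x <- v[g == lev]
    p <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
    )
    tibble(test = "ks_normality", group = lev, p_value = p)
  })
  lev_p <- if (nlevels(g) >= 2) {
    car::leveneTest(v ~ g, center = stats::median)[1, "Pr(>F)"]
  } else {
    NA_real_
  }
  bind_rows(c(ks, list(tibble(test = "levene", group = NA_character_,
                              p_value = lev_p))))
}

# Mann-Whitney U for every column of X (group 1) vs Y (group 2), under the
# same contract as mann_whitney_u(): exact when n1 + n2 <= 20 and the
# column is tie-free, otherwise normal approximation with tie and
# continuity correction. Returns list(statistic, p_value).
mw_many <- function(X, Y, convention = "first") {
  n1 <- nrow(X)
  n2 <- nrow(Y)
  m <- ncol(X)
  u <- numeric(m)
  p <- numeric(m)
  small <- (n1 + n2) <= 20
  for (j in seq_len(m)) {
    v <- c(X[, j], Y[, j])
    r <- rank(v)
    u[j] <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- anyDuplicated(v) > 0
    if (small && !ties) {
      p[j] <- stats::wilcox.test(X[, j], Y[, j], exact = TRUE)$p.value
    } else {
      nt <- table(v)
      z <- u[j] - n1 * n2 / 2
      sigma <- sqrt((n1 * n2 / 12) *
                      ((n1 + n2 + 1) -
                         sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))))
      z <- (z - sign(z) * 0.5) / sigma
      p[j] <- min(1, 2 * min(stats::pnorm(z),
                             stats::pnorm(z, lower.tail = FALSE)))
    }
  }
  if (convention == "second") u <- n1 * n2 - u
  list(statistic = u, p_value = p)
}

#' Group comparison of RP and SE tables
#'
#' The statistical layer of the pipeline: for each frequency band,
#' (a) a global Mann-Whitney U test on the subject-level ROI-averaged
#' relative power, (b) one U test per ROI with Benjamini-Hochberg FDR
#' correction across the ROIs of that band (one family per band), and
#' (c) a U test on the subjects' spatial entropy. Significance of the
#' global and SE tests is assessed at level `alpha` on the raw p-value,
#' of the per-ROI tests on the FDR-adjusted p-value at level `q`.
#'
#' @param rp An `rp_table` from [analyze_subjects()].
#' @param se An `se_table` (optional: `NULL` skips SE tests).
#' @param metadata Data frame with `subject_id` and `group` columns;
#'   `group` must take exactly two values with >= 2 subjects each. The
#'   first of `group_levels` is treated as the "risk" group whose U is
#'   reported.
#' @param q FDR level for the per-ROI families.
#' @param alpha Significance level for the global and SE tests.
#' @param group_levels Length-2 character vector fixing group order;
#'   defaults to `c("risk", "protective")` when present.
#' @param convention U-statistic reporting convention, see
#'   [mann_whitney_u()].
#' @param roi_tests Compute the per-ROI families (set `FALSE` to run only
#'   the global and SE tests, e.g. in large calibration studies).
#' @return A tibble of class `eeg_group_comparison`: columns `scope`
#'   (`"rp_global"`, `"rp_roi"`, `"se"`), `band`, `roi` (NA outside
#'   per-ROI rows), `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_groups <- function(rp, se = NULL, metadata, q = 0.05, alpha = 0.05,
                           group_levels = NULL,
                           convention = c("first", "second"),
                           roi_tests = TRUE) {
  convention <- match.arg(convention)
  md <- as_tibble(metadata)
  if (!all(c("subject_id", "group") %in% names(md))) {
    stopf("metadata needs subject_id and group columns")
  }
  lv <- group_levels %||%
    (if (all(c("risk", "protective") %in% md$group)) {
       c("risk", "protective")
     } else {
       sort(unique(md$group))
     })
  if (length(lv) != 2 || !all(md$group %in% lv)) {
    stopf("group must take exactly two values")
  }
  if (any(table(factor(md$group, lv)) < 2)) {
    stopf("need at least 2 subjects per group")
  }
  ids <- md$subject_id
  g1 <- md$group == lv[1]
  bands <- unique(rp$band)
  rois <- unique(rp$roi)
  # subjects x rois x bands cube
  cube <- array(NA_real_, dim = c(length(ids), length(rois), length(bands)))
  cube[cbind(match(rp$subject_id, ids), match(rp$roi, rois),
             match(rp$band, bands))] <- rp$rp
  if (anyNA(cube)) stopf("rp table is not complete over subjects x rois x bands")
  rows <- list()
  # (a) global per band on ROI-averaged RP
  glob <- apply(cube, c(1, 3), mean)
  t <- mw_many(glob[g1, , drop = FALSE], glob[!g1, , drop = FALSE],
               convention)
  rows[[1]] <- tibble(
    scope = "rp_global", band = bands, roi = NA_character_,
    statistic = t$statistic, p_value = t$p_value,
    p_adjusted = NA_real_, significant = t$p_value <= alpha
  )
  # (b) per-ROI per band, BH correction within each band's family
  if (roi_tests) {
    for (b in seq_along(bands)) {
      M <- cube[, , b]
      t <- mw_many(M[g1, , drop = FALSE], M[!g1, , drop = FALSE],
                   convention)
      bh <- benjamini_hochberg(t$p_value, q)
      rows[[length(rows) + 1]] <- tibble(
        scope = "rp_roi", band = bands[b], roi = rois,
        statistic = t$statistic, p_value = t$p_value,
        p_adjusted = bh$adjusted, significant = bh$flags
      )
    }
  }
  # (c) SE per band
  if (!is.null(se)) {
    se_bands <- unique(se$band)
    S <- matrix(NA_real_, length(ids), length(se_bands))
    S[cbind(match(se$subject_id, ids), match(se$band, se_bands))] <- se$se
    t <- mw_many(S[g1, , drop = FALSE], S[!g1, , drop = FALSE], convention)
    rows[[length(rows) + 1]] <- tibble(
      scope = "se", band = se_bands, roi = NA_character_,
      statistic = t$statistic, p_value = t$p_value,
      p_adjusted = NA_real_, significant = t$p_value <= alpha
    )
  }
  out <- bind_rows(rows)
  structure(out, class = c("eeg_group_comparison", class(out)),
            groups = lv, q = q, alpha = alpha)
}
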