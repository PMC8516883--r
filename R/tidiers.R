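#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_point geom_line
#'   geom_col facet_wrap labs theme_minimal scale_y_log10 geom_hline
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a group comparison
#'
#' The comparison object already is a tidy tibble; `tidy()` strips the
#' class, `glance()` summarises it to one row per scope and band.
#'
#' @param x An `eeg_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eeg_group_comparison <- function(x, ...) {
  as_tibble(unclass(x)[c("scope", "band", "roi", "statistic",
                         "p_value", "p_adjusted", "significant")])
}

#' @rdname tidy.eeg_group_comparison
#' @export
glance.eeg_group_comparison <- function(x, ...) {
  tidy(x) |>
    group_by(.data$scope, .data$band) |>
    summarise(
      n_tests = n(),
      n_significant = sum(.data$significant),
      min_p = min(.data$p_value),
      .groups = "drop"
    )
}

#' Plot a group comparison
#'
#' Per-ROI significance profile: -log10 adjusted p-values per band, with
#' the FDR level marked; global and SE tests drawn as points.
#'
#' @param object An `eeg_group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_group_comparison <- function(object, ...) {
  d <- tidy(object)
  roi <- d[d$scope == "rp_roi", ]
  q <- attr(object, "q")
  ggplot(roi, aes(x = .data$roi, y = -log10(.data$p_adjusted),
                  colour = .data$significant)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = -log10(q), linetype = 2) +
    facet_wrap(~band, ncol = 1) +
    labs(x = NULL, y = expression(-log[10] ~ "adjusted p"),
         colour = "significant") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a relative power table
#'
#' Boxplots of subject-level ROI-averaged relative power per band,
#' coloured by group when a metadata table is supplied.
#'
#' @param object An `rp_table` from [analyze_subjects()].
#' @param metadata Optional data frame with `subject_id`, `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rp_table <- function(object, metadata = NULL, ...) {
  d <- as_tibble(object) |>
    group_by(.data$subject_id, .data$band) |>
    summarise(rp = mean(.data$rp), .groups = "drop")
  if (!is.null(metadata)) {
    d <- left_join(d, as_tibble(metadata)[, c("subject_id", "group")],
                   by = "subject_id")
    p <- ggplot(d, aes(x = .data$band, y = .data$rp, fill = .data$group))
  } else {
    p <- ggplot(d, aes(x = .data$band, y = .data$rp))
  }
  p + geom_boxplot() +
    labs(x = NULL, y = "relative power") +
    theme_minimal()
}

#' Plot a spatial entropy table
#'
#' @param object An `se_table` from [analyze_subjects()].
#' @inheritParams autoplot.rp_table
#' @return A ggplot object.
#' @export
autoplot.se_table <- function(object, metadata = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(metadata)) {
    d <- left_join(d, as_tibble(metadata)[, c("subject_id", "group")],
                   by = "subject_id")
    p <- ggplot(d, aes(x = .data$band, y = .data$se, fill = .data$group))
  } else {
    p <- ggplot(d, aes(x = .data$band, y = .data$se))
  }
  p + geom_boxplot() +
    labs(x = NULL, y = "spatial entropy") +
    theme_minimal()
}
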