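#' Daily time-use distributions
#'
#' Box plots of mean daily minutes per activity, optionally split by a
#' grouping column joined from a clinical table.
#'
#' @param summaries Activity summaries from [summarize_cohort()].
#' @param clinical Optional scored clinical tibble with `participant_id` and
#'   the grouping column.
#' @param group Name of the grouping column in `clinical` (default
#'   `"severity"`).
#' @return A ggplot object.
#' @export
plot_time_use <- function(summaries, clinical = NULL, group = "severity") {
  long <- summaries |>
    dplyr::select("participant_id", dplyr::all_of(paste0("minutes_", analysis_labels()))) |>
    tidyr::pivot_longer(-"participant_id", names_to = "activity",
                        names_prefix = "minutes_", values_to = "minutes") |>
    dplyr::mutate(activity = factor(.data$activity, levels = analysis_labels()))
  if (!is.null(clinical)) {
    long <- dplyr::left_join(long,
                             dplyr::select(clinical, "participant_id", dplyr::all_of(group)),
                             by = "participant_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$activity, y = .data$minutes,
                                            fill = .data[[group]]))
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$activity, y = .data$minutes))
  }
  p + ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "mean daily minutes") +
    ggplot2::theme_minimal()
}

#' Cohort-mean bout histograms
#'
#' Bar chart of mean daily bout counts per duration bin, one panel per
#' activity (narrow bins for walking/standing, broad for sitting/lying).
#'
#' @param summaries Activity summaries from [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_bout_histogram <- function(summaries) {
  long <- summaries |>
    dplyr::select("participant_id", dplyr::starts_with("bouts_")) |>
    tidyr::pivot_longer(-"participant_id", names_to = "key", values_to = "count") |>
    tidyr::separate_wider_regex("key",
      c("bouts_", activity = "[a-z]+", "_", bin = ".*")) |>
    dplyr::group_by(.data$activity, .data$bin) |>
    dplyr::summarise(mean_daily_count = mean(.data$count), .groups = "drop") |>
    dplyr::mutate(activity = factor(.data$activity, levels = analysis_labels()))
  long$bin <- factor(long$bin, levels = c("1_2", "2_3", "1_5", "3_10", "5_10",
                                          "10_30", "gt30", "30_60", "gt60"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$mean_daily_count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~activity, scales = "free_x") +
    ggplot2::labs(x = "bout duration bin (min)", y = "mean daily bout count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of the association suite
#'
#' Wald estimates and 95% CIs (log scale) for the six clinical predictors in
#' each of the five activity-outcome gamma models.
#'
#' @param object An `"assoc_suite"` from [run_association_suite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_suite
#' @export
autoplot.assoc_suite <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                             size = 0.3) +
    ggplot2::facet_wrap(~outcome, nrow = 1) +
    ggplot2::labs(x = "coefficient (log link) with 95% CI", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Kruskal-Wallis result
#'
#' @param x A `"kw_test"` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `n`, `k`.
#' @method tidy kw_test
#' @export
tidy.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n = x$n, k = x$k)
}

#' @method glance kw_test
#' @export
glance.kw_test <- tidy.kw_test

#' Tidy a Dunn post-hoc table
#'
#' @param x A `"dunn_test"` tibble.
#' @param ... Unused.
#' @return The underlying tibble with the adjustment method as a column.
#' @method tidy dunn_test
#' @export
tidy.dunn_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$adjust <- attr(x, "adjust")
  out
}
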