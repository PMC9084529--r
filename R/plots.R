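#' Plot per-criterion registration-quality trends over time
#'
#' Mean score fraction per start year, one panel per rubric criterion, one
#' line per registry group — the visual companion of
#' [criterion_time_trend()].
#'
#' @param scores Long tibble with `group`, `criterion`, `start_year`,
#'   `fraction`.
#' @return A ggplot object.
#' @export
plot_quality_trend <- function(scores) {
  assert_columns(scores, c("group", "criterion", "start_year", "fraction"),
                 "scores")
  yearly <- scores |>
    dplyr::filter(!is.na(.data$start_year), !is.na(.data$fraction)) |>
    dplyr::group_by(.data$group, .data$criterion, .data$start_year) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction), .groups = "drop")
  ggplot2::ggplot(yearly,
                  ggplot2::aes(x = .data$start_year,
                               y = .data$mean_fraction,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::labs(x = "Trial start year",
                  y = "Mean score fraction (attained / attainable)",
                  colour = "Registry") +
    ggplot2::theme_minimal()
}

#' Plot yearly pre-registration rates
#'
#' @param trials Flagged trial tibble with `preregistered` and a year column.
#' @param year Column name to plot over (default `"registration_year"`).
#' @return A ggplot object.
#' @export
plot_prereg_rates <- function(trials, year = "registration_year") {
  assert_columns(trials, c("preregistered", year), "trials")
  df <- trials |>
    dplyr::filter(.data$preregistered %in% c("pre", "retro")) |>
    dplyr::group_by(year = .data[[year]]) |>
    dplyr::summarise(rate = mean(.data$preregistered == "pre"),
                     n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = "Year", y = "Pre-registered trials") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted trial model
#'
#' Forest-style display of estimates with their 95% confidence intervals;
#' odds ratios on a log scale for logistic fits.
#'
#' @param object A `ctrq_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctrq_fit
#' @export
autoplot.ctrq_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  null_line <- if (object$spec$family == "logistic") 1 else 0
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                        y = .data$term)) +
    ggplot2::geom_vline(xintercept = null_line, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = if (object$spec$family == "logistic") "Odds ratio (95% CI)"
          else "Coefficient (95% CI)",
      y = NULL) +
    ggplot2::theme_minimal()
  if (object$spec$family == "logistic") p <- p + ggplot2::scale_x_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
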