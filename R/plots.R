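#' Plot hatch-date distributions for one or more scenarios
#'
#' @param pdfs A hatch-date tibble or a named list of them.
#' @return A ggplot: daily hatch probability over the spawning year.
#' @export
plot_hatch_pdf <- function(pdfs) {
  if (inherits(pdfs, "data.frame")) pdfs <- list(scenario = pdfs)
  df <- purrr::imap_dfr(pdfs, ~ dplyr::mutate(.x, scenario = .y))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$date, y = .data$prob,
    colour = .data$scenario
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = NULL, y = "hatch probability / day",
      colour = NULL, title = "Temperature-driven hatch-date distribution"
    ) +
    ggplot2::theme_minimal()
}

#' Violin plot of scenario length distributions
#'
#' Mirrors the usual presentation of scenario experiments: per-fish percent
#' deviation of furcal length from the baseline scenario's mean length, as
#' violins with interquartile boxes.
#'
#' @param object A `scenario_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_experiment <- function(object, ...) {
  base_mean <- object$summary$mean_cm[object$summary$scenario == object$baseline]
  df <- dplyr::mutate(
    object$lengths,
    pct = 100 * (.data$fl_cm - base_mean) / base_mean
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$scenario, y = .data$pct,
    fill = .data$scenario
  )) +
    ggplot2::geom_violin(trim = TRUE, alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA, fill = "white") +
    ggplot2::labs(
      x = NULL,
      y = "length deviation from baseline mean (%)",
      title = "Length at catch under thermal scenarios"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Posterior interval plot for population-level parameters
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot of posterior means with 95% credible intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  df <- tidy.growth_fit(object, pars = "population")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::labs(
      x = "posterior mean (95% credible interval)", y = NULL,
      title = "Population-level growth parameters"
    ) +
    ggplot2::theme_minimal()
}

#' Observed versus predicted lengths for a validation report
#'
#' @param object A `validation_report`.
#' @param by `"scatter"`, `"region"` or `"birth_month"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, by = c("scatter", "region", "birth_month"), ...) {
  by <- match.arg(by)
  pf <- object$per_fish
  if (by == "scatter") {
    return(
      ggplot2::ggplot(pf, ggplot2::aes(x = .data$observed_cm, y = .data$predicted_cm)) +
        ggplot2::geom_point(alpha = 0.4) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::labs(
          x = "observed FL (cm)", y = "predicted FL (cm)",
          title = sprintf("Validation: RMSD %.2f cm", object$rmsd_cm)
        ) +
        ggplot2::theme_minimal()
    )
  }
  grp <- if (by == "region") "region" else "birth_month"
  ggplot2::ggplot(pf, ggplot2::aes(
    x = factor(.data[[grp]]),
    y = .data$resid_cm
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = grp, y = "residual (cm)") +
    ggplot2::theme_minimal()
}
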