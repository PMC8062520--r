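#' Persist fit artifacts as plain-text files
#'
#' Writes the posterior draws as CSV (one column per parameter, with chain
#' and iteration indices) and a fit report as JSON: split R-hat per
#' parameter, the DIC decomposition, and an echo of the MCMC configuration.
#'
#' @param fit A `growth_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "growth_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$draws, file.path(dir, "posterior_draws.csv"),
    progress = FALSE
  )
  report <- list(
    config = unclass(fit$config),
    environmental = fit$environmental,
    dic = list(
      dic = as.numeric(fit$dic), dbar = attr(fit$dic, "dbar"),
      dhat = attr(fit$dic, "dhat"), p_d = attr(fit$dic, "p_d")
    ),
    rhat = stats::setNames(as.list(fit$summary$rhat), fit$summary$param),
    posterior_mean = stats::setNames(
      as.list(fit$summary$mean),
      fit$summary$param
    )
  )
  jsonlite::write_json(report, file.path(dir, "fit_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Persist a validation report as plain-text files
#'
#' Writes the headline accuracy/precision numbers and grouped residual
#' summaries as JSON, and the per-fish observed/predicted/interval table as
#' CSV.
#'
#' @param report A `validation_report` from [validate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$per_fish, file.path(dir, "validation_per_fish.csv"),
    progress = FALSE
  )
  jsonlite::write_json(
    list(
      rmsd_cm = report$rmsd_cm, mean_iqr_cm = report$mean_iqr_cm,
      by_region = report$by_region, by_birth_month = report$by_birth_month,
      bin_coverage = report$bin_coverage
    ),
    file.path(dir, "validation_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
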