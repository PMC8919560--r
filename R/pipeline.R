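#' Run the full resilience-indicator pipeline
#'
#' Convenience wrapper chaining the stages on a raw (typically simulated)
#' dataset: record editing, herd-month + pregnancy correction, indicator
#' derivation and outlier screening. Genetic analyses are run separately on
#' the returned indicator table with [fit_univariate_repeatability()] /
#' [fit_bivariate_repeatability()].
#'
#' @param dataset list of raw tables, as from [simulate_herd()] or
#'   [read_step_dataset()].
#' @param ... editing parameters passed to [edit_records()].
#' @param outlier_sd outlier threshold in SDs (default 4).
#' @return list with `edited` (full editing output), `fit` (correction
#'   model), `corrected` (records with corrected steps), `indicators`
#'   (screened indicator table), `outlier_log`.
#' @export
run_resilience_pipeline <- function(dataset, ..., outlier_sd = 4) {
  ed <- edit_records(dataset, ...)
  fit <- fit_correction_model(ed$records)
  cor <- corrected_steps(ed$records, fit)
  ind <- derive_indicators(cor, lactations = ed$lactations)
  scr <- remove_indicator_outliers(ind, k = outlier_sd)
  ind <- scr$indicators
  # covariates for the downstream repeatability model
  ind$animal <- ind$cow_id
  list(edited = ed, fit = fit, corrected = cor,
       indicators = ind, outlier_log = scr$log)
}
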