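#' Analysis run configuration
#'
#' Collects every tunable constant of the pipeline in one validated object.
#' Defaults are the study constants: 365-day new-user lookback, 180-day
#' minimum follow-up, 1825-day (5-year) administrative cap, Delta-AIC
#' retention cut of 4, age stratification at 65.
#'
#' @param outcomes outcomes to analyse (subset of `ACS_STROKE`,
#'   `ALL_CAUSE_DEATH`, `CV_DEATH`).
#' @param grid_mode candidate-grid mode, `"resolution"` (multiples of
#'   `grid_resolution`) or `"observed"` (distinct PDC values).
#' @param grid_resolution spacing of the fixed-resolution grid (default 0.01,
#'   two-decimal thresholds).
#' @param trim_fraction minimum fraction of subjects required on each side of
#'   an admissible candidate threshold, in `[0, 0.5)`.
#' @param pdc_mode `"union"` (a day is covered if any fill's supply spans it)
#'   or `"carryover"` (overlapping supply is stockpiled forward).
#' @param max_followup_days administrative censoring horizon (days).
#' @param min_followup_days exclusion cut: patients observed for strictly
#'   fewer days than this after the index date are excluded.
#' @param lookback_days clean-period length required before the index
#'   dispensation.
#' @param delta_aic_cut strict Delta-AIC cut used to retain thresholds.
#' @param age_split age (years) separating the two sensitivity strata.
#' @param stratify logical; run the age-stratified blocks?
#' @param include_hospitalization logical; include the any-hospitalization-
#'   during-follow-up covariate in the ACS/stroke model (it is never used for
#'   the mortality outcomes).
#' @param alternate_offsets offsets used to bracket each method threshold
#'   when building the comparison-table threshold set.
#' @param extra_thresholds always-included comparison thresholds (default the
#'   conventional 0.80).
#' @param ties_method tie handling for the Cox fits, `"efron"` or
#'   `"breslow"`.
#' @param seed integer RNG seed recorded in report provenance.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(outcomes = c("ACS_STROKE", "ALL_CAUSE_DEATH", "CV_DEATH"),
                       grid_mode = c("resolution", "observed"),
                       grid_resolution = 0.01,
                       trim_fraction = 0.05,
                       pdc_mode = c("union", "carryover"),
                       max_followup_days = 1825L,
                       min_followup_days = 180L,
                       lookback_days = 365L,
                       delta_aic_cut = 4,
                       age_split = 65,
                       stratify = TRUE,
                       include_hospitalization = TRUE,
                       alternate_offsets = c(0.01, 0.05, 0.10),
                       extra_thresholds = 0.80,
                       ties_method = c("efron", "breslow"),
                       seed = 1L) {
  cfg <- list(
    outcomes = match.arg(outcomes, several.ok = TRUE),
    grid_mode = match.arg(grid_mode),
    grid_resolution = grid_resolution,
    trim_fraction = trim_fraction,
    pdc_mode = match.arg(pdc_mode),
    max_followup_days = as.integer(max_followup_days),
    min_followup_days = as.integer(min_followup_days),
    lookback_days = as.integer(lookback_days),
    delta_aic_cut = delta_aic_cut,
    age_split = age_split,
    stratify = isTRUE(stratify),
    include_hospitalization = isTRUE(include_hospitalization),
    alternate_offsets = alternate_offsets,
    extra_thresholds = extra_thresholds,
    ties_method = match.arg(ties_method),
    seed = as.integer(seed)
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  day_pars <- c("max_followup_days", "min_followup_days", "lookback_days")
  for (p in day_pars) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 1 || cfg[[p]] != round(cfg[[p]]))
      stop("config error: ", p, " must be a positive integer")
  }
  if (!is.finite(cfg$trim_fraction) || cfg$trim_fraction < 0 || cfg$trim_fraction >= 0.5)
    stop("config error: trim_fraction must lie in [0, 0.5)")
  if (!is.finite(cfg$grid_resolution) || cfg$grid_resolution <= 0 || cfg$grid_resolution >= 1)
    stop("config error: grid_resolution must lie in (0, 1)")
  if (!is.finite(cfg$delta_aic_cut) || cfg$delta_aic_cut <= 0)
    stop("config error: delta_aic_cut must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Covariate set for one outcome
#'
#' The adjusted models use age, sex and the seven comorbidity flags for every
#' outcome; the ACS/stroke model additionally adjusts for any hospitalization
#' during follow-up (the mortality models do not).
#'
#' @param outcome_kind one of `ACS_STROKE`, `ALL_CAUSE_DEATH`, `CV_DEATH`.
#' @param config a [run_config()].
#' @return character vector of covariate column names in the analysis table.
#' @export
default_covariates <- function(outcome_kind, config = run_config()) {
  base <- c("age_years", "sex", comorbidity_cols)
  if (outcome_kind == "ACS_STROKE" && isTRUE(config$include_hospitalization))
    base <- c(base, "hospitalized_during_followup")
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return `read_run_config` returns a validated [run_config()];
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass(run_config())
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("config error: unknown keys ", paste(unknown, collapse = ", "))
  base[names(raw)] <- raw
  base$max_followup_days <- as.integer(base$max_followup_days)
  base$min_followup_days <- as.integer(base$min_followup_days)
  base$lookback_days <- as.integer(base$lookback_days)
  validate_run_config(base)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
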