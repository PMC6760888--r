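#' @name pipeline
#' @title End-to-end threshold-discovery runs
#'
#' @description Orchestrates cohort construction, PDC computation, cutpoint
#' estimation and AIC-based threshold adjudication per outcome, overall and
#' within age strata, producing a reproducible structured report.
NULL

.comparison_thresholds <- function(method_thresholds, config, rows) {
  offs <- c(0, config$alternate_offsets, -config$alternate_offsets)
  cand <- sort(unique(round(c(outer(method_thresholds, offs, `+`),
                              config$extra_thresholds), 6)))
  cand <- cand[cand > 0 & cand < 1]
  # a dichotomized Cox fit needs events and subjects on both sides
  keep <- vapply(cand, function(c) {
    low <- rows$pdc < c
    any(low) && !all(low) &&
      sum(rows$event & low) >= 2 && sum(rows$event & !low) >= 2
  }, TRUE)
  cand[keep]
}

.analysis_block <- function(rows, outcome_kind, config) {
  if (sum(rows$event) < 2 || length(unique(rows$pdc)) < 2)
    return(list(status = "insufficient_events", n = nrow(rows),
                n_events = sum(rows$event)))
  grid <- tryCatch(
    make_candidate_grid(rows$pdc, config$grid_mode, config$grid_resolution,
                        config$trim_fraction),
    error = function(e) NULL)
  if (is.null(grid))
    return(list(status = "insufficient_events", n = nrow(rows),
                n_events = sum(rows$event)))
  cp <- tryCatch(estimate_cutpoints(rows, grid),
                 error = function(e) NULL)
  if (is.null(cp))
    return(list(status = "insufficient_events", n = nrow(rows),
                n_events = sum(rows$event)))
  covs <- default_covariates(outcome_kind, config)
  covs <- covs[vapply(covs, function(v) length(unique(rows[[v]])) > 1, TRUE)]
  ths <- .comparison_thresholds(cp$results$threshold, config, rows)
  if (length(ths) < 2)
    return(list(status = "insufficient_events", n = nrow(rows),
                n_events = sum(rows$event)))
  comparison <- tryCatch(
    compare_thresholds(rows, ths, covs, config$ties_method,
                       on_error = "skip"),
    error = function(e) NULL)
  if (is.null(comparison))
    return(list(status = "insufficient_events", n = nrow(rows),
                n_events = sum(rows$event)))
  retained <- retain_threshold_range(comparison, config$delta_aic_cut)
  class(comparison) <- "data.frame"
  list(status = "ok",
       n = nrow(rows), n_events = sum(rows$event),
       median_pdc = stats::median(rows$pdc),
       cutpoints = cp$results,
       contal_p_value = cp$contal$p_value,
       comparison = as.data.frame(comparison),
       retained = retained$retained,
       range = retained$range)
}

#' Run the full analysis chain for one outcome
#'
#' Builds the cohort, assembles the analysis table for the outcome, estimates
#' the three cutpoints, fits the adjusted Cox comparison over the union of
#' method thresholds and configured alternates, and (when
#' `config$stratify`) repeats the whole chain within each age stratum
#' (cutpoints re-estimated per stratum). A stratum with too few events
#' yields a structured `insufficient_events` marker instead of aborting the
#' run.
#'
#' @param tables validated study tables.
#' @param outcome_kind `"ACS_STROKE"`, `"ALL_CAUSE_DEATH"` or `"CV_DEATH"`.
#' @param config a [run_config()].
#' @param cohort optional pre-built cohort (rebuilt from `tables` if NULL).
#' @return named list: `outcome`, `overall` block, and per-stratum blocks
#'   `age_lt` / `age_ge` when stratified. Each block carries cutpoint
#'   results, the threshold-comparison table, the retained range and row
#'   counts.
#' @export
run_outcome_analysis <- function(tables, outcome_kind, config = run_config(),
                                 cohort = NULL) {
  if (is.null(cohort)) cohort <- build_cohort(tables, config)
  rows <- build_analysis_table(cohort, tables, outcome_kind, config)
  out <- list(outcome = outcome_kind,
              overall = .analysis_block(rows, outcome_kind, config))
  if (config$stratify) {
    young <- rows[rows$age_years < config$age_split, , drop = FALSE]
    old <- rows[rows$age_years >= config$age_split, , drop = FALSE]
    out[[paste0("age_lt_", config$age_split)]] <-
      .analysis_block(young, outcome_kind, config)
    out[[paste0("age_ge_", config$age_split)]] <-
      .analysis_block(old, outcome_kind, config)
  }
  out
}

#' Run the full study across all configured outcomes
#'
#' @inheritParams run_outcome_analysis
#' @return object of class `analysis_report`: list with one section per
#'   outcome plus `provenance` (seed, config, cohort funnel, row counts).
#'   The report is a pure function of (tables, config).
#' @export
run_full_study <- function(tables, config = run_config()) {
  for (kind in names(claims_schemas)) {
    if (is.null(tables[[kind]]))
      stop("schema error: missing input table '", kind, "'")
  }
  cohort <- build_cohort(tables, config)
  sections <- lapply(config$outcomes, function(ok)
    run_outcome_analysis(tables, ok, config, cohort = cohort))
  names(sections) <- config$outcomes
  report <- list(sections = sections,
                 provenance = list(
                   seed = config$seed,
                   config = unclass(config),
                   funnel = as.list(cohort_summary(cohort)),
                   n_dispensations = nrow(tables$dispensations),
                   n_patients = nrow(tables$patients)))
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Adherence-threshold analysis report\n")
  f <- x$provenance$funnel
  cat(sprintf("  cohort: %d candidates, %d included\n", f$total, f$included))
  for (nm in names(x$sections)) {
    blk <- x$sections[[nm]]$overall
    if (identical(blk$status, "ok")) {
      cp <- blk$cutpoints
      cat(sprintf("  %s: n=%d, events=%d; thresholds C-O'Q %.2f, Youden %.2f, min-dist %.2f; retained range [%.2f, %.2f]\n",
                  nm, blk$n, blk$n_events,
                  cp$threshold[cp$method == "CONTAL_OQUIGLEY"],
                  cp$threshold[cp$method == "YOUDEN"],
                  cp$threshold[cp$method == "MIN_DISTANCE"],
                  blk$range[1], blk$range[2]))
    } else {
      cat(sprintf("  %s: insufficient events (n=%d, events=%d)\n",
                  nm, blk$n, blk$n_events))
    }
  }
  invisible(x)
}

.canonical_report <- function(x) {
  # round-trippable representation: plain lists/vectors/data.frames
  rapply(unclass(x), function(v) v, how = "replace")
}

#' Write / read an analysis report
#'
#' Writes `report.json` (the full machine-readable report) plus one CSV per
#' threshold-comparison table and cutpoint table (columns `threshold`, `hr`,
#' `ci_low`, `ci_high`, `aic`, `delta_aic`, `support`), mirroring the shapes
#' of the published comparison tables. `read_report(write_report(x))`
#' reproduces the report.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `write_report` returns `dir` invisibly; `read_report` returns the
#'   report.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "analysis_report")) stop("not an analysis_report")
  if (!length(report$sections)) stop("empty report: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.canonical_report(report),
                       file.path(dir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  for (nm in names(report$sections)) {
    sec <- report$sections[[nm]]
    for (blk_name in setdiff(names(sec), "outcome")) {
      blk <- sec[[blk_name]]
      if (!identical(blk$status, "ok")) next
      tag <- paste0(tolower(nm), "_", blk_name)
      utils::write.csv(blk$comparison,
                       file.path(dir, paste0("comparison_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(blk$cutpoints,
                       file.path(dir, paste0("cutpoints_", tag, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) stop("no report.json under ", dir)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  for (nm in names(raw$sections)) {
    for (blk_name in setdiff(names(raw$sections[[nm]]), "outcome")) {
      blk <- raw$sections[[nm]][[blk_name]]
      if (identical(blk$status, "ok")) {
        blk$comparison <- as.data.frame(blk$comparison)
        blk$cutpoints <- as.data.frame(blk$cutpoints)
        raw$sections[[nm]][[blk_name]] <- blk
      }
    }
  }
  class(raw) <- "analysis_report"
  raw
}
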