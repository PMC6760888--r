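#' @name pdc
#' @title Proportion of days covered
#'
#' @description PDC is the fraction of observation days on which at least one
#' dispensed supply of the drug class covers the day. Fills are pooled across
#' drug classes (switches allowed). Days spent in hospital are removed from
#' both the numerator and the denominator: in-hospital drug use is not
#' observable in claims, and crediting unobservable covered days could push
#' PDC above 1.
NULL

# total length of the union of half-open intervals [start, end), already
# finite; returns 0 for empty input
.union_length <- function(start, end) {
  keep <- end > start
  if (!any(keep)) return(0L)
  s <- start[keep]; e <- end[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  run <- cummax(e)
  prev <- c(-Inf, run[-length(run)])
  sum(pmax(0, e - pmax(s, prev)))
}

# coverage intervals implied by one patient's fills under a mode; carryover
# shifts overlapping supply forward: each fill starts at
# max(dispense_day, previous coverage end)
.coverage_intervals <- function(dispense_day, days_supply,
                                mode = c("union", "carryover")) {
  mode <- match.arg(mode)
  if (!length(dispense_day)) return(list(start = integer(), end = integer()))
  o <- order(dispense_day)
  s <- dispense_day[o]
  L <- days_supply[o]
  if (mode == "union") return(list(start = s, end = s + L))
  C <- cumsum(L)
  e <- C + cummax(s - c(0L, C[-length(C)]))
  list(start = e - L, end = e)
}

.clip <- function(iv, w0, w1) {
  list(start = pmax(iv$start, w0), end = pmin(iv$end, w1))
}

#' Days covered within an observation window
#'
#' Counts the days of `[window_start, window_end)` covered by a patient's
#' fills. In `union` mode a day is covered if any fill's supply interval
#' `[dispense_day, dispense_day + days_supply)` spans it; in `carryover`
#' mode overlapping supply is stockpiled (shifted forward) before clipping,
#' so early refills extend coverage. A fill dispensed before the window
#' contributes its in-window remainder (carry-in).
#'
#' @param dispensations one patient's dispensation records (data.frame with
#'   `dispense_day`, `days_supply`).
#' @param window_start,window_end half-open observation window, integer days.
#' @param mode `"union"` or `"carryover"`.
#' @return integer number of covered days, at most the window length.
#' @export
coverage_days <- function(dispensations, window_start, window_end,
                          mode = c("union", "carryover")) {
  stopifnot(window_end > window_start)
  iv <- .coverage_intervals(dispensations$dispense_day,
                            dispensations$days_supply, mode)
  iv <- .clip(iv, window_start, window_end)
  as.integer(.union_length(iv$start, iv$end))
}

#' PDC with hospital-day adjustment
#'
#' `pdc = (covered days outside hospital) / (window days - in-window hospital
#' days)`, where in-window hospital days are the union of stay intervals
#' clipped to the window. A patient hospitalized for the entire window has no
#' observable days; the result is `NA` with a `reason` attribute and such
#' rows are dropped (with a logged reason) by [build_analysis_table()].
#'
#' @inheritParams coverage_days
#' @param hospital_stays one patient's stays (data.frame with `admit_day`,
#'   `discharge_day`), possibly empty.
#' @return PDC in `[0, 1]`, or `NA` when the denominator is `<= 0`.
#' @export
compute_pdc <- function(dispensations, window_start, window_end,
                        hospital_stays = NULL,
                        mode = c("union", "carryover")) {
  stopifnot(window_end > window_start)
  mode <- match.arg(mode)
  win_len <- window_end - window_start
  cov <- .clip(.coverage_intervals(dispensations$dispense_day,
                                   dispensations$days_supply, mode),
               window_start, window_end)
  if (is.null(hospital_stays) || !nrow(hospital_stays)) {
    hs <- list(start = integer(), end = integer())
  } else {
    hs <- .clip(list(start = hospital_stays$admit_day,
                     end = hospital_stays$discharge_day),
                window_start, window_end)
  }
  hosp <- .union_length(hs$start, hs$end)
  denom <- win_len - hosp
  if (denom <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "entire window hospitalized"
    return(out)
  }
  either <- .union_length(c(cov$start, hs$start), c(cov$end, hs$end))
  numer <- either - hosp  # covered days outside hospital
  numer / denom
}

#' Assemble the per-patient analysis table for one outcome
#'
#' One row per included cohort patient: PDC over the outcome-specific window,
#' follow-up time, event indicator and the adjustment covariates. The PDC
#' window and the survival time share the anchor:
#' \itemize{
#'   \item patients with the outcome: window ends at the event day
#'     (event-anchored);
#'   \item patients lost or with under-5-year observation: window ends at the
#'     patient-specific end (censor-anchored);
#'   \item completers: fixed 1825-day window.
#' }
#' For `ACS_STROKE` the event is the first post-index ACS/stroke
#' hospitalization (death censors); for `ALL_CAUSE_DEATH` any death; for
#' `CV_DEATH` a cardiovascular death, with non-CV death censoring at the
#' death day.
#'
#' @param cohort output of [build_cohort()]; only included rows are used.
#' @param tables named list of validated tables (`dispensations`,
#'   `hospital_stays`, `outcomes`, `patients`).
#' @param outcome_kind `"ACS_STROKE"`, `"ALL_CAUSE_DEATH"` or `"CV_DEATH"`.
#' @param config a [run_config()] (PDC mode, follow-up cap).
#' @return data.frame with columns `patient_id`, `pdc`, `time_days`, `event`,
#'   `age_years`, `sex`, the seven comorbidity flags and
#'   `hospitalized_during_followup`; attribute `"dropped"` records patients
#'   excluded for a non-positive PDC denominator.
#' @export
build_analysis_table <- function(cohort, tables,
                                 outcome_kind = c("ACS_STROKE",
                                                  "ALL_CAUSE_DEATH",
                                                  "CV_DEATH"),
                                 config = run_config()) {
  outcome_kind <- match.arg(outcome_kind)
  inc <- cohort[cohort$included, , drop = FALSE]
  pat <- tables$patients
  pat_idx <- match(inc$patient_id, pat$patient_id)

  disp <- split(tables$dispensations[, c("dispense_day", "days_supply")],
                factor(tables$dispensations$patient_id, levels = inc$patient_id))
  stays <- split(tables$hospital_stays[, c("admit_day", "discharge_day")],
                 factor(tables$hospital_stays$patient_id, levels = inc$patient_id))
  oc <- split(tables$outcomes,
              factor(tables$outcomes$patient_id, levels = inc$patient_id))

  n <- nrow(inc)
  pdc <- time_days <- rep(NA_real_, n)
  event <- hosp_flag <- rep(FALSE, n)
  drop_reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    idx <- inc$index_day[i]
    cap_end <- idx + config$max_followup_days
    enrol_end <- pat$enrol_end_day[pat_idx[i]]
    obs_end <- min(enrol_end, cap_end)
    ev <- oc[[i]]

    death_day <- cv <- NULL
    if (!is.null(ev) && nrow(ev)) {
      if (any(ev$event_day > enrol_end))
        stop("consistency error: outcome after enrolment end for patient ",
             inc$patient_id[i])
      d <- ev[ev$event_type == "DEATH", , drop = FALSE]
      if (nrow(d)) {
        if (d$event_day[1] <= idx)
          stop("consistency error: death on or before index for patient ",
               inc$patient_id[i])
        death_day <- d$event_day[1]
        cv <- isTRUE(d$cv_cause[1])
      }
    }

    if (outcome_kind == "ACS_STROKE") {
      acs <- if (is.null(ev)) integer() else
        ev$event_day[ev$event_type == "ACS_STROKE" & ev$event_day > idx &
                       ev$event_day <= obs_end]
      ends <- c(if (length(acs)) min(acs) else Inf,
                if (!is.null(death_day) && death_day <= obs_end) death_day else Inf,
                obs_end)
      w_end <- min(ends)
      is_event <- length(acs) && min(acs) == w_end
    } else {
      died <- !is.null(death_day) && death_day <= obs_end
      w_end <- if (died) death_day else obs_end
      is_event <- died && (outcome_kind == "ALL_CAUSE_DEATH" || isTRUE(cv))
    }

    p <- compute_pdc(disp[[i]], idx, w_end, stays[[i]], config$pdc_mode)
    if (is.na(p)) {
      drop_reason[i] <- attr(p, "reason")
      next
    }
    pdc[i] <- p
    time_days[i] <- w_end - idx
    event[i] <- is_event
    st <- stays[[i]]
    hosp_flag[i] <- !is.null(st) && nrow(st) > 0 &&
      any(pmin(st$discharge_day, w_end) > pmax(st$admit_day, idx))
  }

  keep <- is.na(drop_reason)
  out <- data.frame(patient_id = inc$patient_id,
                    pdc = pdc, time_days = time_days, event = event,
                    age_years = pat$age_years[pat_idx],
                    sex = pat$sex[pat_idx],
                    pat[pat_idx, comorbidity_cols, drop = FALSE],
                    hospitalized_during_followup = hosp_flag,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- data.frame(patient_id = inc$patient_id[!keep],
                        reason = drop_reason[!keep], stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(nrow(dropped), " patient(s) dropped: ",
            paste(unique(dropped$reason), collapse = "; "))
  attr(out, "dropped") <- dropped
  out
}
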