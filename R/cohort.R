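#' @name cohort
#' @title New-user cohort construction
#'
#' @description Applies the new-user design to the raw tables: the index date
#' is a patient's earliest dispensation preceded by at least `lookback_days`
#' of observable enrolment containing no lipid-lowering dispensation; patients
#' with a pre-index ACS/stroke hospitalization or with under
#' `min_followup_days` of post-index observation are excluded. Follow-up is
#' capped at `max_followup_days` (administrative censoring).
NULL

exclusion_precedence <- c("INSUFFICIENT_HISTORY", "NOT_NEW_USER",
                          "PRIOR_EVENT", "SHORT_FOLLOWUP")
end_reason_precedence <- c("EVENT", "DEATH", "ADMIN_1825", "LOST")

#' Identify new users and their index dates
#'
#' A dispensation qualifies as an index if (a) the patient has at least
#' `lookback_days` of enrolment before it (otherwise the clean period is
#' unobservable) and (b) no dispensation of the drug class falls in
#' `[index - lookback_days, index)`. The earliest qualifying dispensation is
#' the index; patients with none are flagged `INSUFFICIENT_HISTORY` when
#' their first fill lacks observable history, else `NOT_NEW_USER`.
#'
#' @param dispensations validated dispensations table.
#' @param patients validated patients (baseline) table.
#' @param lookback_days clean-period length, >= 1.
#' @return data.frame with columns `patient_id`, `index_day` (NA when no
#'   qualifying index) and `flag` (`""`, `INSUFFICIENT_HISTORY` or
#'   `NOT_NEW_USER`), one row per patient with any dispensation, ordered by
#'   patient id.
#' @export
identify_new_users <- function(dispensations, patients, lookback_days = 365L) {
  stopifnot(lookback_days >= 1)
  orphan <- setdiff(unique(dispensations$patient_id), patients$patient_id)
  if (length(orphan))
    stop("referential error: dispensations for patients missing a baseline row: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  dt <- data.table::as.data.table(dispensations)[, c("patient_id", "dispense_day")]
  data.table::setorder(dt, patient_id, dispense_day)
  enrol <- stats::setNames(patients$enrol_start_day, patients$patient_id)
  res <- dt[, {
    d <- dispense_day
    hist_ok <- (d - enrol[[patient_id[1]]]) >= lookback_days
    prev <- c(-Inf, d[-length(d)])
    clean_ok <- (d - prev) >= lookback_days  # no fill in [d - lookback, d)
    ok <- hist_ok & clean_ok
    if (any(ok)) {
      list(index_day = d[which(ok)[1]], flag = "")
    } else {
      list(index_day = NA_integer_,
           flag = if (!hist_ok[1]) "INSUFFICIENT_HISTORY" else "NOT_NEW_USER")
    }
  }, by = patient_id]
  data.table::setorder(res, patient_id)
  as.data.frame(res)
}

#' Apply exclusion rules and assign follow-up windows
#'
#' Builds one cohort entry per candidate: `PRIOR_EVENT` when any ACS/stroke
#' event precedes the index (strictly); `SHORT_FOLLOWUP` when the observation
#' end (earliest of first post-index ACS/stroke, death, enrolment end,
#' index + `max_followup_days`) falls strictly fewer than
#' `min_followup_days` after the index. Exactly `min_followup_days` of
#' follow-up is included. Ties for the observation end resolve
#' EVENT > DEATH > ADMIN_1825 > LOST, so an event on the censoring day counts
#' as an event.
#'
#' @param candidates output of [identify_new_users()].
#' @param patients validated patients table.
#' @param outcomes validated outcomes table.
#' @param min_followup_days,max_followup_days day constants (defaults 180 and
#'   1825).
#' @return data.frame of cohort entries: `patient_id`, `index_day`,
#'   `followup_end_day`, `end_reason`, `flags` (`;`-joined, `""` when
#'   included), `first_flag` (precedence flag used for funnel counting),
#'   `included` (logical).
#' @export
apply_exclusions <- function(candidates, patients, outcomes,
                             min_followup_days = 180L,
                             max_followup_days = 1825L) {
  pat <- patients[match(candidates$patient_id, patients$patient_id), ]
  if (nrow(outcomes)) {
    bad <- merge(outcomes, patients[, c("patient_id", "enrol_start_day")],
                 by = "patient_id")
    bad <- bad[bad$event_day < bad$enrol_start_day, , drop = FALSE]
    if (nrow(bad))
      stop("data-consistency error: outcome event before enrolment start for ",
           paste(utils::head(unique(bad$patient_id), 5), collapse = ", "))
  }

  n <- nrow(candidates)
  flags <- vector("list", n)
  for (i in seq_len(n)) flags[[i]] <- character()
  idx <- candidates$index_day
  for (i in which(candidates$flag != "")) flags[[i]] <- candidates$flag[i]

  oc <- split(outcomes, outcomes$patient_id)
  end_day <- rep(NA_integer_, n)
  end_reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (is.na(idx[i])) next
    ev <- oc[[candidates$patient_id[i]]]
    acs_pre <- !is.null(ev) && any(ev$event_type == "ACS_STROKE" & ev$event_day < idx[i])
    if (acs_pre) flags[[i]] <- c(flags[[i]], "PRIOR_EVENT")

    acs_post <- if (is.null(ev)) integer() else
      ev$event_day[ev$event_type == "ACS_STROKE" & ev$event_day >= idx[i]]
    death <- if (is.null(ev)) integer() else
      ev$event_day[ev$event_type == "DEATH"]
    cand_end <- c(EVENT = if (length(acs_post)) min(acs_post) else NA,
                  DEATH = if (length(death)) min(death) else NA,
                  ADMIN_1825 = idx[i] + max_followup_days,
                  LOST = pat$enrol_end_day[i])
    cand_end <- cand_end[!is.na(cand_end)]
    # earliest end wins; on ties the precedence order (EVENT > DEATH >
    # ADMIN_1825 > LOST) decides, and the vector is already in that order
    best <- which(cand_end == min(cand_end))[1]
    end_day[i] <- min(cand_end)
    end_reason[i] <- names(cand_end)[best]
    if ((end_day[i] - idx[i]) < min_followup_days)
      flags[[i]] <- c(flags[[i]], "SHORT_FOLLOWUP")
  }

  flag_str <- vapply(flags, function(f) paste(f, collapse = ";"), "")
  first_flag <- vapply(flags, function(f) {
    if (!length(f)) "" else exclusion_precedence[min(match(f, exclusion_precedence))]
  }, "")
  out <- data.frame(patient_id = candidates$patient_id,
                    index_day = idx,
                    followup_end_day = end_day,
                    end_reason = end_reason,
                    flags = flag_str,
                    first_flag = first_flag,
                    included = flag_str == "",
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the cohort from raw tables
#'
#' Convenience chain of [identify_new_users()] and [apply_exclusions()].
#'
#' @param tables named list with `dispensations`, `outcomes`, `patients` (as
#'   from [read_study_tables()] or [generate_study()]).
#' @param config a [run_config()].
#' @return cohort entries, see [apply_exclusions()].
#' @export
build_cohort <- function(tables, config = run_config()) {
  cand <- identify_new_users(tables$dispensations, tables$patients,
                             config$lookback_days)
  apply_exclusions(cand, tables$patients, tables$outcomes,
                   config$min_followup_days, config$max_followup_days)
}

#' Cohort selection funnel
#'
#' Counts candidates by inclusion and, for excluded patients, by the first
#' applicable exclusion flag in the fixed precedence
#' INSUFFICIENT_HISTORY > NOT_NEW_USER > PRIOR_EVENT > SHORT_FOLLOWUP, so the
#' counts partition the input.
#'
#' @param entries output of [apply_exclusions()] / [build_cohort()].
#' @return named integer vector: `total`, `included`, one count per
#'   exclusion flag.
#' @export
cohort_summary <- function(entries) {
  counts <- vapply(exclusion_precedence,
                   function(f) sum(entries$first_flag == f), 0L)
  c(total = nrow(entries), included = sum(entries$included), counts)
}
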