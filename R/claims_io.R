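#' Claims-table schemas
#'
#' Column names and types for the four flat input tables. All day fields are
#' integer offsets from a per-dataset epoch; intervals are half-open
#' `[start, end)`.
#'
#' @format A named list, one entry per table kind:
#' \describe{
#'   \item{dispensations}{patient_id, dispense_day, days_supply, drug_class}
#'   \item{hospital_stays}{patient_id, admit_day, discharge_day}
#'   \item{outcomes}{patient_id, event_type (`ACS_STROKE`/`DEATH`), event_day,
#'     cv_cause (logical, meaningful for deaths only), icd_code (annotation)}
#'   \item{patients}{patient_id, age_years, sex (`F`/`M`), seven comorbidity
#'     flags, enrol_start_day, enrol_end_day}
#' }
#' @export
claims_schemas <- list(
  dispensations = c("patient_id", "dispense_day", "days_supply", "drug_class"),
  hospital_stays = c("patient_id", "admit_day", "discharge_day"),
  outcomes = c("patient_id", "event_type", "event_day", "cv_cause", "icd_code"),
  patients = c("patient_id", "age_years", "sex", "diabetes", "copd", "asthma",
               "heart_failure", "ihd_history", "mental_health", "ckd",
               "enrol_start_day", "enrol_end_day")
)

comorbidity_cols <- c("diabetes", "copd", "asthma", "heart_failure",
                      "ihd_history", "mental_health", "ckd")

.parse_int <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.finite(v) | v != round(v)] <- NA_real_
  as.integer(v)
}

.parse_flag <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO", "")] <- FALSE
  out
}

#' Read and validate a claims table
#'
#' Reads one of the four CSV input tables (comma-separated, header required,
#' UTF-8), validates each row against the schema's type and range
#' constraints, and returns the accepted rows. Rejected rows are reported,
#' never silently dropped: `nrow(accepted) + nrow(rejected)` always equals
#' the number of data rows in the file.
#'
#' @param path path to a CSV file.
#' @param kind one of `names(claims_schemas)`.
#' @return A `data.frame` of validated, typed records with an attribute
#'   `"rejected"` (a `data.frame` with columns `row` and `reason`, 1-based
#'   data-row indices). Retrieve it with [rejected_rows()].
#' @details Structural problems (missing file, missing or extra required
#'   columns) stop with an error; per-row problems (unparseable numbers,
#'   `days_supply < 1`, `discharge_day < admit_day`, unknown enums,
#'   `cv_cause` on a non-death, a second death for the same patient,
#'   `enrol_end_day <= enrol_start_day`) reject that row only.
#' @export
read_claims_table <- function(path, kind) {
  kind <- match.arg(kind, names(claims_schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  validate_claims_table(raw, kind)
}

#' Validate an in-memory claims table
#'
#' Same validation as [read_claims_table()] applied to a data frame already
#' in memory (e.g. freshly simulated).
#'
#' @param raw data.frame with the schema's columns.
#' @inheritParams read_claims_table
#' @return As [read_claims_table()].
#' @export
validate_claims_table <- function(raw, kind) {
  kind <- match.arg(kind, names(claims_schemas))
  want <- claims_schemas[[kind]]
  missing_cols <- setdiff(want, names(raw))
  extra_cols <- setdiff(names(raw), want)
  if (length(missing_cols) || length(extra_cols)) {
    stop("schema error for '", kind, "': ",
         if (length(missing_cols)) paste0("missing columns [", paste(missing_cols, collapse = ", "), "] "),
         if (length(extra_cols)) paste0("unexpected columns [", paste(extra_cols, collapse = ", "), "]"))
  }
  raw <- raw[, want, drop = FALSE]
  n <- nrow(raw)
  bad <- character(n)  # "" = ok

  note <- function(idx, msg) {
    idx <- which(idx)
    idx <- idx[bad[idx] == ""]
    bad[idx] <<- msg
    invisible(NULL)
  }

  out <- data.frame(patient_id = trimws(raw$patient_id),
                    stringsAsFactors = FALSE)
  note(out$patient_id == "" | is.na(out$patient_id), "empty patient_id")

  if (kind == "dispensations") {
    out$dispense_day <- .parse_int(raw$dispense_day)
    out$days_supply <- .parse_int(raw$days_supply)
    out$drug_class <- trimws(raw$drug_class)
    note(is.na(out$dispense_day), "unparseable dispense_day")
    note(is.na(out$days_supply), "unparseable days_supply")
    note(!is.na(out$days_supply) & out$days_supply < 1, "days_supply must be >= 1")
  } else if (kind == "hospital_stays") {
    out$admit_day <- .parse_int(raw$admit_day)
    out$discharge_day <- .parse_int(raw$discharge_day)
    note(is.na(out$admit_day), "unparseable admit_day")
    note(is.na(out$discharge_day), "unparseable discharge_day")
    note(!is.na(out$admit_day) & !is.na(out$discharge_day) &
           out$discharge_day < out$admit_day,
         "discharge_day must be >= admit_day")
  } else if (kind == "outcomes") {
    out$event_type <- toupper(trimws(raw$event_type))
    out$event_day <- .parse_int(raw$event_day)
    out$cv_cause <- .parse_flag(raw$cv_cause)
    out$icd_code <- trimws(raw$icd_code)
    note(!out$event_type %in% c("ACS_STROKE", "DEATH"), "unknown event_type")
    note(is.na(out$event_day), "unparseable event_day")
    note(is.na(out$cv_cause), "unparseable cv_cause")
    note(!is.na(out$cv_cause) & out$cv_cause & out$event_type != "DEATH",
         "cv_cause only meaningful for DEATH")
    is_death <- out$event_type == "DEATH" & bad == ""
    dup <- is_death & duplicated(ifelse(is_death, out$patient_id, NA_character_)) &
      !is.na(out$patient_id)
    note(dup, "patient has more than one DEATH")
  } else { # patients
    out$age_years <- suppressWarnings(as.numeric(raw$age_years))
    out$sex <- toupper(trimws(raw$sex))
    for (cc in comorbidity_cols) out[[cc]] <- .parse_flag(raw[[cc]])
    out$enrol_start_day <- .parse_int(raw$enrol_start_day)
    out$enrol_end_day <- .parse_int(raw$enrol_end_day)
    note(!is.finite(out$age_years), "unparseable age_years")
    note(!out$sex %in% c("F", "M"), "sex must be F or M")
    for (cc in comorbidity_cols) note(is.na(out[[cc]]), paste0("unparseable ", cc))
    note(is.na(out$enrol_start_day), "unparseable enrol_start_day")
    note(is.na(out$enrol_end_day), "unparseable enrol_end_day")
    note(!is.na(out$enrol_start_day) & !is.na(out$enrol_end_day) &
           out$enrol_end_day <= out$enrol_start_day,
         "enrol_end_day must be > enrol_start_day")
    note(duplicated(out$patient_id), "duplicate patient_id")
  }

  keep <- bad == ""
  rejected <- data.frame(row = which(!keep), reason = bad[!keep],
                         stringsAsFactors = FALSE)
  accepted <- out[keep, , drop = FALSE]
  rownames(accepted) <- NULL
  attr(accepted, "rejected") <- rejected
  attr(accepted, "kind") <- kind
  accepted
}

#' Rejected rows of a validated claims table
#'
#' @param x result of [read_claims_table()] / [validate_claims_table()].
#' @return data.frame with columns `row` (1-based data-row index in the
#'   source) and `reason`.
#' @export
rejected_rows <- function(x) {
  r <- attr(x, "rejected")
  if (is.null(r)) data.frame(row = integer(), reason = character()) else r
}

#' Write a claims table to CSV
#'
#' Inverse of [read_claims_table()]: `read_claims_table(write_claims_table(x))`
#' round-trips every record.
#'
#' @param x data.frame with the schema's columns.
#' @inheritParams read_claims_table
#' @export
write_claims_table <- function(x, path, kind) {
  kind <- match.arg(kind, names(claims_schemas))
  want <- claims_schemas[[kind]]
  if (!all(want %in% names(x)))
    stop("cannot write '", kind, "': missing columns ",
         paste(setdiff(want, names(x)), collapse = ", "))
  utils::write.csv(x[, want, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the four study tables at once
#'
#' @param dispensations,hospital_stays,outcomes,patients paths to the four
#'   CSV files.
#' @return named list of validated tables (see [read_claims_table()]).
#' @export
read_study_tables <- function(dispensations, hospital_stays, outcomes, patients) {
  list(dispensations = read_claims_table(dispensations, "dispensations"),
       hospital_stays = read_claims_table(hospital_stays, "hospital_stays"),
       outcomes = read_claims_table(outcomes, "outcomes"),
       patients = read_claims_table(patients, "patients"))
}
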