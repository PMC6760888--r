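#' Synthetic-study configuration
#'
#' Parameters of the claims generator. The defaults emulate a new-user
#' lipid-lowering-drug cohort: a right-skewed adherence-propensity
#' distribution (median ~0.79, IQR ~0.44-0.94, matching the skew reported
#' for such cohorts), 30-day fills, 5-year administrative censoring, event
#' rates giving roughly 4% ACS/stroke and 3.4% death over 5 years, a ~38%
#' ever-hospitalized fraction with median stay ~8 days, and a known true
#' adherence threshold `tau_star` below which the event hazards jump by
#' `hr_star`.
#'
#' The hazard depends on the latent propensity `p_i`, not the realized PDC:
#' realized PDC then behaves as a noisy proxy of the quantity that carries
#' the risk, which is exactly the measurement structure the threshold
#' methods face, and keeps the ground truth well-defined (realized PDC
#' depends on the event time).
#'
#' @param n_patients cohort size before eligibility filtering.
#' @param seed integer seed; all randomness flows from it.
#' @param mixture_weight weight of the high-adherence Beta component.
#' @param mixture_shape1,mixture_shape2 shape pairs `c(a, b)` of the
#'   high-adherence and heterogeneous (U-shaped: early discontinuers and
#'   sporadic users) components.
#' @param days_supply days of supply per fill.
#' @param gap_shape Gamma shape of inter-fill gaps (mean is set to
#'   `days_supply * (1 - p) / p` so expected coverage equals `p`).
#' @param discontinuation_hazard per-fill probability of permanent
#'   discontinuation (0 = adherence heterogeneity carried entirely by the
#'   propensity).
#' @param tau_star true adherence threshold in (0, 1).
#' @param hr_star true hazard ratio for `1(p < tau_star)`.
#' @param acs_rate,death_rate baseline (good-adherer) event rates per 1000
#'   person-years.
#' @param cv_death_fraction fraction of deaths with cardiovascular cause.
#' @param hospitalization_rate hospital admissions per person-year
#'   (independent of adherence).
#' @param stay_meanlog,stay_sdlog log-normal stay-length parameters (days).
#' @param ltfu_rate loss-to-follow-up (emigration) rate per person-year.
#' @param max_followup_days administrative horizon.
#' @param frac_prior_event,frac_short_followup,frac_non_new_user fractions of
#'   deliberately ineligible patients injected to exercise the cohort
#'   filters (pre-index ACS; enrolment ending within 180 days of index;
#'   prevalent users whose fills start too soon after enrolment start).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000L,
                       seed = 1L,
                       mixture_weight = 0.40,
                       mixture_shape1 = c(6.0, 1.5),
                       mixture_shape2 = c(0.30, 0.23),
                       days_supply = 30L,
                       gap_shape = 2,
                       discontinuation_hazard = 0,
                       tau_star = 0.5,
                       hr_star = 2.0,
                       acs_rate = 8.0,
                       death_rate = 7.0,
                       cv_death_fraction = 0.37,
                       hospitalization_rate = 0.10,
                       stay_meanlog = log(8),
                       stay_sdlog = 1.3,
                       ltfu_rate = 0.03,
                       max_followup_days = 1825L,
                       frac_prior_event = 0.02,
                       frac_short_followup = 0.02,
                       frac_non_new_user = 0.02) {
  cfg <- as.list(environment())
  if (!(tau_star > 0 && tau_star < 1))
    stop("config error: tau_star must lie in (0, 1)")
  if (hr_star <= 0) stop("config error: hr_star must be positive")
  rates <- c(acs_rate, death_rate, cv_death_fraction, hospitalization_rate,
             ltfu_rate, discontinuation_hazard,
             frac_prior_event, frac_short_followup, frac_non_new_user)
  if (any(rates < 0)) stop("config error: rates must be >= 0")
  if (mixture_weight < 0 || mixture_weight > 1)
    stop("config error: mixture_weight must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Sample adherence propensities
#'
#' Draws each patient's long-run adherence propensity `p_i` from the
#' two-component Beta mixture, clamped to `[1e-3, 1 - 1e-6]` so refill-gap
#' means stay finite.
#'
#' @param config a [sim_config()].
#' @param n number of draws (default `config$n_patients`).
#' @return numeric vector in (0, 1).
#' @export
sample_propensities <- function(config, n = config$n_patients) {
  comp <- runif(n) < config$mixture_weight
  p <- ifelse(comp,
              rbeta(n, config$mixture_shape1[1], config$mixture_shape1[2]),
              rbeta(n, config$mixture_shape2[1], config$mixture_shape2[2]))
  pmin(pmax(p, 1e-3), 1 - 1e-6)
}

# fills for all patients at once; start_day/horizon_day are per-patient
# vectors. Returns data.table(patient_id, dispense_day, days_supply).
# Gap after each fill's supply ~ Gamma(gap_shape, mean supply*(1-p)/p), so
# expected long-run coverage equals p; gaps of 0 give back-to-back fills.
.generate_fills <- function(patient_id, p, start_day, horizon_day, config) {
  L <- config$days_supply
  n <- length(p)
  max_fills <- ceiling(max(horizon_day - start_day) / L) + 1L
  mean_gap <- L * (1 - p) / p
  active <- rep(TRUE, n)
  cur <- as.numeric(start_day)
  out_pid <- vector("list", max_fills)
  out_day <- vector("list", max_fills)
  for (k in seq_len(max_fills)) {
    fill_now <- active & cur < horizon_day
    if (!any(fill_now)) break
    out_pid[[k]] <- patient_id[fill_now]
    out_day[[k]] <- as.integer(floor(cur[fill_now]))
    gap <- numeric(n)
    pos <- fill_now & mean_gap > 0
    gap[pos] <- rgamma(sum(pos), shape = config$gap_shape,
                       scale = mean_gap[pos] / config$gap_shape)
    cur[fill_now] <- cur[fill_now] + L + gap[fill_now]
    if (config$discontinuation_hazard > 0) {
      quit <- fill_now & runif(n) < config$discontinuation_hazard
      active[quit] <- FALSE
    }
  }
  data.table::data.table(patient_id = unlist(out_pid),
                         dispense_day = unlist(out_day),
                         days_supply = L,
                         drug_class = "statin")
}

#' Generate dispensation records for given propensities
#'
#' First fill at each patient's index day; subsequent inter-fill gaps are
#' Gamma-distributed with mean `days_supply * (1 - p) / p`, so the expected
#' coverage fraction equals `p`.
#'
#' @param p propensities in (0, 1).
#' @param index_day per-patient first-fill day (recycled).
#' @param config a [sim_config()].
#' @param patient_id optional ids (default `P000001`, ...).
#' @return data.frame of dispensation records.
#' @export
generate_dispensations <- function(p, index_day, config,
                                   patient_id = sprintf("P%06d", seq_along(p))) {
  index_day <- rep_len(index_day, length(p))
  horizon <- index_day + config$max_followup_days
  as.data.frame(.generate_fills(patient_id, p, index_day, horizon, config))
}

#' Generate outcome events and enrolment ends
#'
#' Event times are exponential, independently per outcome, with rate
#' `lambda_0 * hr_star^(p < tau_star)`; deaths receive a cardiovascular
#' cause with probability `cv_death_fraction`; loss to follow-up is
#' exponential; the administrative end is `max_followup_days` after index.
#' Only events observable before the patient's end of enrolment (and before
#' death, for ACS) are emitted.
#'
#' @param p propensities.
#' @param index_day per-patient index day.
#' @param config a [sim_config()].
#' @param patient_id patient ids.
#' @return list with `outcomes` (data.frame of events), `enrol_end_day`
#'   (integer vector), and `truth` components `acs_day`, `death_day`
#'   (latent, possibly beyond the horizon).
#' @export
generate_events <- function(p, index_day, config,
                            patient_id = sprintf("P%06d", seq_along(p))) {
  n <- length(p)
  poor <- p < config$tau_star
  mult <- ifelse(poor, config$hr_star, 1)
  per_day <- 1 / (1000 * 365.25)
  acs_t <- rexp(n, rate = pmax(config$acs_rate * mult * per_day, 1e-12))
  death_t <- rexp(n, rate = pmax(config$death_rate * mult * per_day, 1e-12))
  ltfu_t <- if (config$ltfu_rate > 0)
    rexp(n, rate = config$ltfu_rate / 365.25) else rep(Inf, n)
  cv <- runif(n) < config$cv_death_fraction

  # enrolment runs from day 0 to at least the administrative horizon unless
  # the patient emigrates first; a slack beyond the horizon distinguishes
  # completers from losses
  admin_end <- index_day + config$max_followup_days
  enrol_end <- pmin(index_day + ceiling(ltfu_t), admin_end + 365L)

  acs_day <- index_day + ceiling(acs_t)
  death_day <- index_day + ceiling(death_t)

  rows <- list()
  obs_acs <- acs_day <= pmin(enrol_end, death_day)
  if (any(obs_acs))
    rows$acs <- data.frame(patient_id = patient_id[obs_acs],
                           event_type = "ACS_STROKE",
                           event_day = acs_day[obs_acs],
                           cv_cause = FALSE, icd_code = "I21",
                           stringsAsFactors = FALSE)
  obs_death <- death_day <= enrol_end
  if (any(obs_death))
    rows$death <- data.frame(patient_id = patient_id[obs_death],
                             event_type = "DEATH",
                             event_day = death_day[obs_death],
                             cv_cause = cv[obs_death],
                             icd_code = ifelse(cv[obs_death], "I25", "C80"),
                             stringsAsFactors = FALSE)
  outcomes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), event_type = character(),
               event_day = integer(), cv_cause = logical(),
               icd_code = character(), stringsAsFactors = FALSE)
  outcomes <- outcomes[order(outcomes$patient_id, outcomes$event_day), , drop = FALSE]
  rownames(outcomes) <- NULL
  list(outcomes = outcomes,
       enrol_end_day = as.integer(enrol_end),
       truth = list(acs_day = acs_day, death_day = death_day, cv = cv))
}

#' Generate a complete synthetic study
#'
#' Produces the four claims tables plus a ground-truth table. Deterministic
#' for a given `config$seed`. A configured fraction of patients is made
#' deliberately ineligible (pre-index ACS hospitalization; enrolment ending
#' within the minimum follow-up; prevalent users whose first fill sits too
#' close to enrolment start), so the cohort filters are exercised.
#'
#' The truth table is bookkeeping only: it is never consumed by the analysis
#' pipeline.
#'
#' @param config a [sim_config()].
#' @return named list of data.frames: `dispensations`, `hospital_stays`,
#'   `outcomes`, `patients`, `truth` (patient_id, propensity, poor_adherer,
#'   ineligible_as) plus attributes `tau_star`, `hr_star` on `truth`.
#' @export
generate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%06d", seq_len(n))

  p <- sample_propensities(config, n)

  # eligibility injections (disjoint groups at the head of the id space
  # would correlate with nothing, but assign randomly anyway)
  u <- runif(n)
  inel <- rep("", n)
  inel[u < config$frac_prior_event] <- "prior_event"
  inel[u >= config$frac_prior_event &
         u < config$frac_prior_event + config$frac_short_followup] <- "short_followup"
  inel[u >= config$frac_prior_event + config$frac_short_followup &
         u < config$frac_prior_event + config$frac_short_followup +
             config$frac_non_new_user] <- "non_new_user"

  # index dates: enough enrolment history for eligible patients; prevalent
  # users start filling shortly after enrolment start instead
  index_day <- 365L + as.integer(floor(runif(n, 0, 366)))
  index_day[inel == "non_new_user"] <- as.integer(floor(runif(sum(inel == "non_new_user"), 30, 200)))

  ev <- generate_events(p, index_day, config, pid)
  enrol_end <- ev$enrol_end_day
  short <- inel == "short_followup"
  enrol_end[short] <- index_day[short] +
    as.integer(floor(runif(sum(short), 10, 170)))
  enrol_end <- pmax(enrol_end, index_day + 1L)
  outcomes <- ev$outcomes[ev$outcomes$event_day <=
                            enrol_end[match(ev$outcomes$patient_id, pid)], , drop = FALSE]

  prior <- inel == "prior_event"
  if (any(prior)) {
    pe <- data.frame(patient_id = pid[prior],
                     event_type = "ACS_STROKE",
                     event_day = index_day[prior] -
                       as.integer(floor(runif(sum(prior), 30, 300))),
                     cv_cause = FALSE, icd_code = "I63",
                     stringsAsFactors = FALSE)
    pe$event_day <- pmax(pe$event_day, 1L)
    outcomes <- rbind(outcomes, pe)
  }
  outcomes <- outcomes[order(outcomes$patient_id, outcomes$event_day), , drop = FALSE]
  rownames(outcomes) <- NULL

  fills <- .generate_fills(pid, p, index_day, pmin(enrol_end, index_day + config$max_followup_days),
                           config)
  data.table::setorder(fills, patient_id, dispense_day)

  # hospitalizations: Poisson admissions over follow-up, log-normal stays,
  # independent of adherence
  fu_years <- pmin(enrol_end - index_day, config$max_followup_days) / 365.25
  n_adm <- rpois(n, config$hospitalization_rate * fu_years)
  stays <- NULL
  if (sum(n_adm) > 0) {
    who <- rep(seq_len(n), n_adm)
    adm <- index_day[who] +
      as.integer(floor(runif(sum(n_adm)) * pmin(enrol_end - index_day,
                                                config$max_followup_days)[who]))
    len <- pmax(1L, as.integer(round(rlnorm(sum(n_adm), config$stay_meanlog,
                                            config$stay_sdlog))))
    stays <- data.frame(patient_id = pid[who], admit_day = adm,
                        discharge_day = adm + len, stringsAsFactors = FALSE)
    stays <- stays[order(stays$patient_id, stays$admit_day), , drop = FALSE]
    rownames(stays) <- NULL
  } else {
    stays <- data.frame(patient_id = character(), admit_day = integer(),
                        discharge_day = integer(), stringsAsFactors = FALSE)
  }

  age <- pmin(pmax(rnorm(n, 61, 12.5), 30), 95)
  patients <- data.frame(
    patient_id = pid,
    age_years = round(age, 1),
    sex = ifelse(runif(n) < 0.459, "F", "M"),
    diabetes = runif(n) < 0.425,
    copd = runif(n) < 0.093,
    asthma = runif(n) < 0.128,
    heart_failure = runif(n) < 0.073,
    ihd_history = runif(n) < 0.229,
    mental_health = runif(n) < 0.498,
    ckd = runif(n) < 0.036,
    enrol_start_day = 0L,
    enrol_end_day = enrol_end,
    stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = pid, propensity = p,
                      poor_adherer = p < config$tau_star,
                      index_day = index_day,
                      ineligible_as = inel,
                      stringsAsFactors = FALSE)
  attr(truth, "tau_star") <- config$tau_star
  attr(truth, "hr_star") <- config$hr_star

  list(dispensations = as.data.frame(fills),
       hospital_stays = stays,
       outcomes = outcomes,
       patients = patients,
       truth = truth)
}

#' Write a synthetic study to disk
#'
#' Writes the four claims CSVs plus `truth.csv` (never read by analysis
#' commands) into a directory.
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in names(claims_schemas))
    write_claims_table(study[[kind]], file.path(dir, paste0(kind, ".csv")), kind)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
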