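# Independent oracles used throughout the suite. They deliberately take the
# dumbest correct route (one boolean per day, naive counting, survdiff,
# hand-written partial likelihood) so they share no code path with the
# implementation they check.

# day-by-day boolean coverage over [w0, w1). carryover uses supply-bank
# semantics: each fill deposits its supply; one unit is consumed per covered
# day while the bank is positive.
oracle_covered_days <- function(disp, w0, w1, mode) {
  days <- seq.int(w0, w1 - 1L)
  if (!nrow(disp)) return(rep(FALSE, length(days)))
  if (mode == "union") {
    cov <- vapply(days, function(d)
      any(disp$dispense_day <= d & d < disp$dispense_day + disp$days_supply),
      TRUE)
    return(cov)
  }
  # simulate from the first fill so carry-in reaches the window
  o <- order(disp$dispense_day)
  fills <- disp[o, ]
  start <- min(fills$dispense_day, w0)
  all_days <- seq.int(start, w1 - 1L)
  bank <- 0
  cov_all <- logical(length(all_days))
  for (i in seq_along(all_days)) {
    d <- all_days[i]
    bank <- bank + sum(fills$days_supply[fills$dispense_day == d])
    if (bank > 0) {
      cov_all[i] <- TRUE
      bank <- bank - 1
    }
  }
  cov_all[all_days >= w0]
}

oracle_pdc <- function(disp, w0, w1, stays, mode) {
  cov <- oracle_covered_days(disp, w0, w1, mode)
  days <- seq.int(w0, w1 - 1L)
  hosp <- if (is.null(stays) || !nrow(stays)) rep(FALSE, length(days)) else
    vapply(days, function(d)
      any(stays$admit_day <= d & d < stays$discharge_day), TRUE)
  denom <- sum(!hosp)
  if (denom <= 0) return(NA_real_)
  sum(cov & !hosp) / denom
}

# log-rank numerator for the low-adherence group via survdiff (obs - exp)
oracle_logrank_U <- function(rows, threshold) {
  grp <- factor(rows$pdc < threshold, levels = c(FALSE, TRUE))
  if (length(unique(grp[!is.na(grp)])) < 2 || min(table(grp)) == 0) return(NA_real_)
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ grp,
                           data = rows)
  unname(sd$obs[2] - sd$exp[2])
}

oracle_sens_spec <- function(rows, threshold) {
  ev <- rows[rows$event, "pdc"]
  nev <- rows[!rows$event, "pdc"]
  c(sn = sum(ev < threshold) / length(ev),
    sp = sum(nev >= threshold) / length(nev))
}

# Efron log partial likelihood for a single covariate
oracle_efron_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  r <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status]))) {
    Dset <- which(status & time == t)
    Rset <- which(time >= t)
    d <- length(Dset)
    sum_r <- sum(r[Rset])
    sum_rd <- sum(r[Dset])
    ll <- ll + sum(eta[Dset])
    for (l in seq_len(d) - 1L)
      ll <- ll - log(sum_r - (l / d) * sum_rd)
  }
  ll
}

# grid search over beta in [-5, 5]; the partial likelihood is concave in a
# single coefficient, so a coarse pass plus a fine pass around the coarse
# maximizer reaches 5e-4 resolution
oracle_grid_beta <- function(time, status, x) {
  coarse <- seq(-5, 5, by = 0.01)
  ll <- vapply(coarse, oracle_efron_loglik, 0, time = time, status = status, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 5e-4)
  llf <- vapply(fine, oracle_efron_loglik, 0, time = time, status = status, x = x)
  fine[which.max(llf)]
}

# random survival dataset for the cutpoint/Cox oracle checks
random_rows <- function(n, event_frac = 0.4) {
  data.frame(pdc = round(runif(n), 3),
             time_days = ceiling(rexp(n, 1 / 500)),
             event = runif(n) < event_frac)
}

# random claims tables for round-trip checks
random_claims <- function(kind, n = 20) {
  pid <- sprintf("P%03d", sample.int(500, n, replace = TRUE))
  switch(kind,
    dispensations = data.frame(
      patient_id = pid,
      dispense_day = sample.int(2000, n, replace = TRUE),
      days_supply = sample.int(90, n, replace = TRUE),
      drug_class = sample(c("statin", "fibrate", "ezetimibe"), n, TRUE),
      stringsAsFactors = FALSE),
    hospital_stays = {
      a <- sample.int(2000, n, replace = TRUE)
      data.frame(patient_id = pid, admit_day = a,
                 discharge_day = a + sample.int(40, n, TRUE) - 1L,
                 stringsAsFactors = FALSE)
    },
    outcomes = data.frame(
      patient_id = sprintf("P%03d", sample.int(500, n)),  # unique: one death rule
      event_type = sample(c("ACS_STROKE", "DEATH"), n, TRUE),
      event_day = sample.int(2000, n, replace = TRUE),
      cv_cause = FALSE, icd_code = "I21",
      stringsAsFactors = FALSE),
    patients = data.frame(
      patient_id = sprintf("P%03d", sample.int(500, n)),
      age_years = round(runif(n, 30, 90), 1),
      sex = sample(c("F", "M"), n, TRUE),
      diabetes = runif(n) < 0.4, copd = runif(n) < 0.1,
      asthma = runif(n) < 0.1, heart_failure = runif(n) < 0.1,
      ihd_history = runif(n) < 0.2, mental_health = runif(n) < 0.5,
      ckd = runif(n) < 0.05,
      enrol_start_day = 0L,
      enrol_end_day = sample.int(3000, n, replace = TRUE) + 400L,
      stringsAsFactors = FALSE))
}

# minimal hand-built study tables (helpers for cohort/pdc unit tests)
make_patients <- function(ids, enrol_start = 0L, enrol_end = 4000L,
                          age = 60, sex = "M") {
  n <- length(ids)
  data.frame(patient_id = ids, age_years = rep_len(age, n),
             sex = rep_len(sex, n),
             diabetes = FALSE, copd = FALSE, asthma = FALSE,
             heart_failure = FALSE, ihd_history = FALSE,
             mental_health = FALSE, ckd = FALSE,
             enrol_start_day = rep_len(as.integer(enrol_start), n),
             enrol_end_day = rep_len(as.integer(enrol_end), n),
             stringsAsFactors = FALSE)
}

make_disp <- function(ids, days, supply = 30L) {
  data.frame(patient_id = rep(ids, lengths(days))[seq_along(unlist(days))],
             dispense_day = as.integer(unlist(days)),
             days_supply = as.integer(supply),
             drug_class = "statin", stringsAsFactors = FALSE)
}

empty_outcomes <- function() {
  data.frame(patient_id = character(), event_type = character(),
             event_day = integer(), cv_cause = logical(),
             icd_code = character(), stringsAsFactors = FALSE)
}

empty_stays <- function() {
  data.frame(patient_id = character(), admit_day = integer(),
             discharge_day = integer(), stringsAsFactors = FALSE)
}

one_outcome <- function(id, type, day, cv = FALSE) {
  data.frame(patient_id = id, event_type = type, event_day = as.integer(day),
             cv_cause = cv, icd_code = "", stringsAsFactors = FALSE)
}
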