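disp1 <- function(days, supply = 30L)
  data.frame(dispense_day = as.integer(days),
             days_supply = as.integer(rep_len(supply, length(days))))

test_that("coverage counting matches the worked examples in both modes", {
  expect_equal(coverage_days(disp1(0), 0, 100, "union"), 30L)
  # overlapping fills: union merges, carryover stockpiles
  d <- disp1(c(0, 20))
  expect_equal(coverage_days(d, 0, 100, "union"), 50L)
  expect_equal(coverage_days(d, 0, 100, "carryover"), 60L)
  # back-to-back fills saturate a 60-day window either way
  d2 <- disp1(c(0, 30))
  expect_equal(coverage_days(d2, 0, 60, "union"), 60L)
  expect_equal(coverage_days(d2, 0, 60, "carryover"), 60L)
  # carry-in: a pre-window fill contributes its in-window remainder
  expect_equal(coverage_days(disp1(-10), 0, 100, "union"), 20L)
  # stockpiled pre-window fills: [-40,-10) then [-10,20) -> 20 in-window days
  expect_equal(coverage_days(disp1(c(-40, -10)), 0, 100, "carryover"), 20L)
})

test_that("hospital days leave both numerator and denominator", {
  d <- disp1(0, 60)
  st <- data.frame(admit_day = 40L, discharge_day = 50L)
  expect_equal(compute_pdc(d, 0, 100, st, "union"), 50 / 90)
  expect_equal(compute_pdc(disp1(integer(0)), 0, 100, NULL, "union"), 0)
  expect_equal(compute_pdc(disp1(0, 100), 0, 100, NULL, "union"), 1)
  # fully hospitalized window has no observable days
  full <- data.frame(admit_day = 0L, discharge_day = 100L)
  expect_true(is.na(compute_pdc(d, 0, 100, full, "union")))
})

test_that("pdc engine matches the day-by-day boolean oracle", {
  set.seed(101)
  for (i in 1:50) {
    nf <- sample(0:8, 1)
    d <- disp1(sort(sample(-30:400, nf)), sample(7:90, max(nf, 1), TRUE)[seq_len(nf)])
    ns <- sample(0:3, 1)
    a <- sort(sample(0:380, ns))
    st <- data.frame(admit_day = a, discharge_day = a + sample(1:30, ns, TRUE))
    w0 <- sample(0:50, 1); w1 <- w0 + sample(50:350, 1)
    for (mode in c("union", "carryover")) {
      expect_equal(coverage_days(d, w0, w1, mode),
                   sum(oracle_covered_days(d, w0, w1, mode)),
                   info = sprintf("i=%d mode=%s", i, mode))
      expect_equal(compute_pdc(d, w0, w1, st, mode),
                   oracle_pdc(d, w0, w1, st, mode),
                   info = sprintf("i=%d mode=%s", i, mode))
    }
  }
})

test_that("coverage and PDC invariants hold on random inputs", {
  set.seed(202)
  for (i in 1:40) {
    nf <- sample(1:8, 1)
    d <- disp1(sort(sample(0:400, nf)), sample(7:90, nf, TRUE))
    w0 <- 0; w1 <- sample(100:500, 1)
    # union coverage never exceeds carryover coverage
    expect_lte(coverage_days(d, w0, w1, "union"),
               coverage_days(d, w0, w1, "carryover"))
    # shifting all dates leaves PDC unchanged
    k <- sample(-50:50, 1)
    dd <- d; dd$dispense_day <- dd$dispense_day + k
    a <- sort(sample(0:400, 2))
    st <- data.frame(admit_day = a, discharge_day = a + c(10L, 25L))
    sts <- st; sts$admit_day <- st$admit_day + k; sts$discharge_day <- st$discharge_day + k
    expect_equal(compute_pdc(d, w0, w1, st, "union"),
                 compute_pdc(dd, w0 + k, w1 + k, sts, "union"))
    # adding a hospital stay never increases numerator or denominator
    p0 <- compute_pdc(d, w0, w1, NULL, "union")
    num0 <- p0 * (w1 - w0)
    hosp <- sum(pmin(st$discharge_day, w1) - pmax(st$admit_day, w0))
    p1 <- compute_pdc(d, w0, w1, st, "union")
    if (!is.na(p1)) {
      den1 <- (w1 - w0) -
        sum(oracle_covered_days(disp1(st$admit_day, st$discharge_day - st$admit_day),
                                w0, w1, "union"))
      expect_lte(p1 * den1, num0 + 1e-9)
      expect_lte(den1, w1 - w0)
    }
  }
})

test_that("analysis windows are outcome-anchored as published", {
  cfg <- run_config()
  pats <- make_patients(c("A", "B", "C"), enrol_end = 4000L)
  cohort <- data.frame(patient_id = c("A", "B", "C"),
                       index_day = 400L,
                       followup_end_day = c(800L, 2225L, 1300L),
                       end_reason = c("EVENT", "ADMIN_1825", "DEATH"),
                       flags = "", first_flag = "", included = TRUE,
                       stringsAsFactors = FALSE)
  # A: ACS at index + 400 with exactly half the days covered
  disp <- make_disp(c("A", "B", "C"), list(400, 400, 400), supply = 200L)
  oc <- rbind(one_outcome("A", "ACS_STROKE", 800),
              one_outcome("C", "DEATH", 1300, cv = FALSE))
  tables <- list(dispensations = disp, hospital_stays = empty_stays(),
                 outcomes = oc, patients = pats)
  rows <- build_analysis_table(cohort, tables, "ACS_STROKE", cfg)
  a <- rows[rows$patient_id == "A", ]
  expect_equal(a$pdc, 0.5)
  expect_equal(a$time_days, 400)
  expect_true(a$event)
  # B: completer gets the fixed 1825-day window
  b <- rows[rows$patient_id == "B", ]
  expect_equal(b$time_days, 1825)
  expect_false(b$event)
  expect_equal(b$pdc, 200 / 1825)
  # C: death censors the ACS analysis at the death day
  cc <- rows[rows$patient_id == "C", ]
  expect_equal(cc$time_days, 900)
  expect_false(cc$event)

  # all-cause mortality: C's death is the event
  rows2 <- build_analysis_table(cohort, tables, "ALL_CAUSE_DEATH", cfg)
  expect_true(rows2$event[rows2$patient_id == "C"])
  expect_equal(rows2$time_days[rows2$patient_id == "C"], 900)
  # A's ACS does not end mortality follow-up
  expect_equal(rows2$time_days[rows2$patient_id == "A"], 1825)

  # CV mortality: a non-CV death is censoring at the death day
  rows3 <- build_analysis_table(cohort, tables, "CV_DEATH", cfg)
  expect_false(rows3$event[rows3$patient_id == "C"])
  expect_equal(rows3$time_days[rows3$patient_id == "C"], 900)
})

test_that("cv deaths count as events only in the CV analysis", {
  cfg <- run_config()
  pats <- make_patients("D", enrol_end = 4000L)
  cohort <- data.frame(patient_id = "D", index_day = 400L,
                       followup_end_day = 1300L, end_reason = "DEATH",
                       flags = "", first_flag = "", included = TRUE,
                       stringsAsFactors = FALSE)
  tables <- list(dispensations = make_disp("D", list(400)),
                 hospital_stays = empty_stays(),
                 outcomes = one_outcome("D", "DEATH", 1300, cv = TRUE),
                 patients = pats)
  expect_true(build_analysis_table(cohort, tables, "CV_DEATH", cfg)$event)
  expect_true(build_analysis_table(cohort, tables, "ALL_CAUSE_DEATH", cfg)$event)
  expect_false(build_analysis_table(cohort, tables, "ACS_STROKE", cfg)$event)
})
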