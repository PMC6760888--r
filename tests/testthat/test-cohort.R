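test_that("new-user identification finds the earliest qualifying index", {
  pats <- make_patients(c("A", "B", "C"))
  # A: fills at 400, 430 with enrolment from 0 -> index 400
  # B: first fill at day 100, only 100 days of observable history
  # C: fills at 300 and 500; 500 has a fill 200 days before, 300 lacks history
  disp <- make_disp(c("A", "B", "C"),
                    list(c(400, 430), 100, c(300, 500)))
  res <- identify_new_users(disp, pats, 365L)
  expect_equal(res$index_day[res$patient_id == "A"], 400L)
  expect_equal(res$flag[res$patient_id == "A"], "")
  expect_equal(res$flag[res$patient_id == "B"], "INSUFFICIENT_HISTORY")
  expect_true(is.na(res$index_day[res$patient_id == "B"]))
  expect_equal(res$flag[res$patient_id == "C"], "INSUFFICIENT_HISTORY")
  expect_true(is.na(res$index_day[res$patient_id == "C"]))
})

test_that("dispensations without a baseline row raise a referential error", {
  expect_error(
    identify_new_users(make_disp("Z", list(400)), make_patients("A"), 365L),
    "referential")
})

test_that("minimum follow-up is strict at 180 days", {
  pats <- make_patients(c("A", "B"))
  cand <- data.frame(patient_id = c("A", "B"), index_day = c(400L, 400L),
                     flag = "", stringsAsFactors = FALSE)
  oc <- rbind(one_outcome("A", "DEATH", 550),   # index + 150
              one_outcome("B", "DEATH", 580))   # index + 180
  entries <- apply_exclusions(cand, pats, oc)
  expect_equal(entries$flags[entries$patient_id == "A"], "SHORT_FOLLOWUP")
  expect_false(entries$included[entries$patient_id == "A"])
  expect_true(entries$included[entries$patient_id == "B"])
  expect_equal(entries$end_reason[entries$patient_id == "B"], "DEATH")
  expect_equal(entries$followup_end_day[entries$patient_id == "B"], 580L)
})

test_that("pre-index ACS/stroke excludes the patient", {
  pats <- make_patients("A")
  cand <- data.frame(patient_id = "A", index_day = 400L, flag = "",
                     stringsAsFactors = FALSE)
  entries <- apply_exclusions(cand, pats, one_outcome("A", "ACS_STROKE", 350))
  expect_equal(entries$flags, "PRIOR_EVENT")
  expect_false(entries$included)
})

test_that("follow-up end takes the earliest competing end, ties to EVENT", {
  pats <- make_patients("A", enrol_end = 4000L)
  cand <- data.frame(patient_id = "A", index_day = 400L, flag = "",
                     stringsAsFactors = FALSE)
  # event exactly on the administrative censoring day counts as an event
  oc <- one_outcome("A", "ACS_STROKE", 400 + 1825)
  entries <- apply_exclusions(cand, pats, oc)
  expect_equal(entries$followup_end_day, 400L + 1825L)
  expect_equal(entries$end_reason, "EVENT")
  # no events: administrative cap before enrolment end
  entries2 <- apply_exclusions(cand, pats, empty_outcomes())
  expect_equal(entries2$followup_end_day, 400L + 1825L)
  expect_equal(entries2$end_reason, "ADMIN_1825")
  # enrolment ends first -> LOST
  entries3 <- apply_exclusions(cand, make_patients("A", enrol_end = 1000L),
                               empty_outcomes())
  expect_equal(entries3$end_reason, "LOST")
  expect_equal(entries3$followup_end_day, 1000L)
})

test_that("outcome events before enrolment start raise a consistency error", {
  cand <- data.frame(patient_id = "A", index_day = 400L, flag = "",
                     stringsAsFactors = FALSE)
  expect_error(
    apply_exclusions(cand, make_patients("A", enrol_start = 100L),
                     one_outcome("A", "ACS_STROKE", 50)),
    "consistency")
})

test_that("funnel counts partition candidates; multi-flag patients count once", {
  pats <- make_patients(c("A", "B", "C"), enrol_end = 4000L)
  cand <- data.frame(patient_id = c("A", "B", "C"),
                     index_day = c(400L, 400L, 400L), flag = "",
                     stringsAsFactors = FALSE)
  # B has both PRIOR_EVENT and SHORT_FOLLOWUP; counted under PRIOR_EVENT
  oc <- rbind(one_outcome("B", "ACS_STROKE", 300),
              one_outcome("B", "DEATH", 450))
  entries <- apply_exclusions(cand, pats, oc)
  s <- cohort_summary(entries)
  expect_equal(unname(s["total"]), 3L)
  expect_equal(unname(s["included"]), 2L)
  expect_equal(unname(s["PRIOR_EVENT"]), 1L)
  expect_equal(unname(s["SHORT_FOLLOWUP"]), 0L)
  prec <- c("INSUFFICIENT_HISTORY", "NOT_NEW_USER", "PRIOR_EVENT",
            "SHORT_FOLLOWUP")
  expect_equal(unname(s["included"] + sum(s[prec])), unname(s["total"]))
  # empty input
  empty <- apply_exclusions(cand[0, ], pats, empty_outcomes())
  expect_true(all(cohort_summary(empty) == 0))
})

test_that("cohort construction is deterministic under input row order", {
  study <- generate_study(sim_config(n_patients = 300, seed = 11))
  cfg <- run_config()
  c1 <- build_cohort(study, cfg)
  shuffled <- study
  set.seed(99)
  shuffled$dispensations <- shuffled$dispensations[sample(nrow(shuffled$dispensations)), ]
  shuffled$outcomes <- shuffled$outcomes[sample(nrow(shuffled$outcomes)), ]
  shuffled$patients <- shuffled$patients[sample(nrow(shuffled$patients)), ]
  c2 <- build_cohort(shuffled, cfg)
  rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("included patients satisfy the cohort invariants", {
  study <- generate_study(sim_config(n_patients = 500, seed = 12))
  cfg <- run_config()
  cohort <- build_cohort(study, cfg)
  inc <- cohort[cohort$included, ]
  expect_true(all(inc$followup_end_day - inc$index_day >= 180))
  expect_true(all(inc$followup_end_day - inc$index_day <= 1825))
  acs <- study$outcomes[study$outcomes$event_type == "ACS_STROKE", ]
  pre <- merge(acs, inc[, c("patient_id", "index_day")], by = "patient_id")
  expect_true(all(pre$event_day >= pre$index_day))
})
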