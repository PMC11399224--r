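# Surveillance loop: raising, deduplication, automatic termination, triage
# lifecycle, determinism, and triage accounting.

kb <- default_kb()
thr <- risk_thresholds()
always <- triage_policy(mode = "always_intervene")

test_that("an alert resolves automatically when its trigger stops", {
  rx <- data.frame(drug_id = c("M01AE01", "B01AC04"),
                   end = c(ts_day(10), ts_day(3)))   # clopidogrel stops day 3
  ds <- mini_cohort(rx = rx)
  log <- run_surveillance(ds, kb, thr, always)
  expect_equal(nrow(log[log$alert_no == 1, ]), 1)
  a <- log[log$alert_no == 1, ]
  expect_identical(a$status, "RESOLVED")
  expect_equal(a$raised_at, ts_day(1))
  expect_equal(a$status_changed_at, ts_day(3))  # first tick at which rx inactive
})

test_that("a persisting trigger raises exactly one alert, not one per tick", {
  ds <- mini_cohort(rx = data.frame(drug_id = c("M01AE01", "B01AC04")),
                    discharge = ts_day(6))
  log <- run_surveillance(ds, kb, thr, always)
  expect_equal(sum(log$alert_no == 1), 1)
  expect_true(all(log$status == "RESOLVED"))   # terminated at discharge
})

test_that("an empty cohort yields an empty log", {
  ds <- cohort_dataset(
    data.frame(patient_id = character(), birth_date = character(),
               sex = character(), consent = logical()),
    data.frame(case_id = character(), patient_id = character(),
               admission = character(), discharge = character(),
               period_label = character()))
  log <- run_surveillance(ds, kb, thr, always,
                          t0 = ts_day(1), t1 = ts_day(2))
  expect_equal(nrow(log), 0)
})

test_that("identical inputs and seeds give identical logs", {
  gen <- generate_cohort(small_synth_config(n = 80, seed = 5))
  pol <- triage_policy(seed = 123)
  l1 <- run_surveillance(gen$dataset, kb, thr, pol)
  l2 <- run_surveillance(gen$dataset, kb, thr, pol)
  expect_identical(l1, l2)
  # and the JSON-Lines round trip preserves the log
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_alert_log(l1, path)
  l3 <- read_alert_log(path)
  expect_equal(as.data.frame(l3), as.data.frame(l1)[names(l3)],
               ignore_attr = TRUE)
})

test_that("prescribing a once-daily PPI resolves missing-PPI alerts without raising alert 12", {
  rx <- data.frame(drug_id = c("B01AC06", "B01AC04", "A02BC02"),
                   daily_dose = c(100, 75, 40),
                   start = c(ts_day(1), ts_day(1), ts_day(4)))
  ds <- mini_cohort(rx = rx)
  log <- run_surveillance(ds, kb, thr, always)
  a9 <- log[log$alert_no == 9, ]
  expect_equal(nrow(a9), 1)
  expect_identical(a9$status, "RESOLVED")
  expect_equal(a9$status_changed_at, ts_day(4))
  expect_false(12 %in% log$alert_no)   # antiplatelet factors indicate the PPI
})

test_that("no alert of a discharged case stays open; excluded cases are not monitored", {
  gen <- generate_cohort(small_synth_config(n = 120, seed = 8))
  log <- run_surveillance(gen$dataset, kb, thr, triage_policy(seed = 2))
  expect_true(all(log$status %in%
                    c("RESOLVED", "NOT_RELEVANT", "INTERVENTION", "PENDING")))
  expect_false(any(log$status %in% c("PENDING", "INTERVENTION")))
  excluded <- gen$dataset$cases$case_id[gen$dataset$cases$excluded]
  expect_length(intersect(log$case_id, excluded), 0)
  # at most one open missing-PPI alert per case at any time: raise times of
  # successive missing alerts for a case never precede the previous
  # alert's termination
  for (cid in unique(log$case_id)) {
    m <- log[log$case_id == cid & log$alert_no <= 11, ]
    m <- m[order(m$raised_at), ]
    if (nrow(m) > 1)
      expect_true(all(diff(order(m$raised_at)) > 0) &&
                    all(m$raised_at[-1] >= m$status_changed_at[-nrow(m)]))
  }
})

test_that("triage accounting reproduces hand-tallied rates", {
  mk_alert <- function(no, status, sent, outcome) {
    data.frame(alert_id = "x", case_id = "c", alert_no = no,
               category = ifelse(no <= 11, "MISSING_PPI", "INAPPROPRIATE_PPI"),
               raised_at = ts_day(1), status = status,
               status_changed_at = ts_day(2), intervention_sent = sent,
               intervention_at = ts_day(2), intervention_outcome = outcome,
               snap_ppi_status = "NONE", snap_factor_count = 1L)
  }
  log <- rbind(
    do.call(rbind, replicate(5, mk_alert(9, "RESOLVED", TRUE, "ACCEPTED"), FALSE)),
    do.call(rbind, replicate(4, mk_alert(9, "RESOLVED", TRUE, "NOT_ACCEPTED"), FALSE)),
    mk_alert(9, "INTERVENTION", TRUE, "UNKNOWN"),
    do.call(rbind, replicate(3, mk_alert(12, "NOT_RELEVANT", FALSE, "n/a"), FALSE)),
    do.call(rbind, replicate(2, mk_alert(12, "RESOLVED", FALSE, "n/a"), FALSE)))
  s <- triage_summary(log)
  expect_equal(s$overall$interventions, 10)
  expect_equal(s$overall$acceptance_rate, 0.5)
  expect_equal(s$overall$unknown_rate, 0.1)
  missing <- s$by_category[s$by_category$category == "MISSING_PPI", ]
  expect_equal(missing$interventions, 10)
  inapp <- s$by_category[s$by_category$category == "INAPPROPRIATE_PPI", ]
  expect_equal(inapp$interventions, 0)
  expect_true(is.na(inapp$acceptance_rate))   # division guard
  expect_equal(inapp$not_relevant, 3)
  expect_equal(inapp$resolved_without_intervention, 2)
})

test_that("an acceptance tally of 59 of 81 interventions rounds to 73%", {
  mk <- function(outcome) data.frame(
    alert_id = "x", case_id = "c", alert_no = 9L, category = "MISSING_PPI",
    raised_at = ts_day(1), status = "RESOLVED", status_changed_at = ts_day(2),
    intervention_sent = TRUE, intervention_at = ts_day(2),
    intervention_outcome = outcome, snap_ppi_status = "NONE",
    snap_factor_count = 1L)
  log <- rbind(do.call(rbind, replicate(59, mk("ACCEPTED"), FALSE)),
               do.call(rbind, replicate(22, mk("NOT_ACCEPTED"), FALSE)))
  s <- triage_summary(log)
  expect_equal(s$overall$interventions, 81)
  expect_equal(round(100 * s$overall$acceptance_rate), 73)
})
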