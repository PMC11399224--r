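# Discharge screening, diagnostic performance, incidence comparison.

kb <- default_kb()
thr <- risk_thresholds()

test_that("discharge screening classifies the canonical cases", {
  # discharged on DAPT without a PPI
  ds <- mini_cohort(rx = data.frame(drug_id = c("B01AC06", "B01AC04"),
                                    daily_dose = c(100, 75)))
  s <- discharge_screen(ds, kb, thr, "C1")
  expect_identical(s$category, "MISSING")
  expect_equal(s$alert_no, 9L)
  # once-daily oral PPI with no risk factor
  ds2 <- mini_cohort(rx = data.frame(drug_id = "A02BC02", daily_dose = 40))
  expect_identical(discharge_screen(ds2, kb, thr, "C1")$category, "INAPPROPRIATE")
  # PPI covering an NSAID: indicated gastroprotection
  ds3 <- mini_cohort(rx = data.frame(drug_id = c("A02BC02", "M01AE01"),
                                     daily_dose = c(40, 1200)))
  expect_identical(discharge_screen(ds3, kb, thr, "C1")$category, "NONE")
  # open cases cannot be screened
  ds4 <- mini_cohort(discharge = NA)
  expect_error(discharge_screen(ds4, kb, thr, "C1"), class = "domain_error")
})

test_that("the discharge snapshot sits on the last tick strictly before discharge", {
  # exposure ends exactly at discharge: still active at the snapshot
  ds <- mini_cohort(rx = data.frame(drug_id = c("B01AC06", "B01AC04"),
                                    daily_dose = c(100, 75)),
                    discharge = ts_day(2, 0))
  expect_identical(discharge_screen(ds, kb, thr, "C1")$category, "MISSING")
  # exposure ending one step earlier is gone at the snapshot
  ds2 <- mini_cohort(rx = data.frame(drug_id = c("B01AC06", "B01AC04"),
                                     daily_dose = c(100, 75),
                                     end = c(ts_day(1, 22), ts_day(1, 22))),
                     discharge = ts_day(2, 0))
  expect_identical(discharge_screen(ds2, kb, thr, "C1")$category, "NONE")
})

test_that("diagnostic performance reproduces a hand-built confusion matrix", {
  ref <- data.frame(case_id = sprintf("C%02d", 1:20),
                    category = c(rep("MISSING", 14), rep("NONE", 6)))
  # 12 true positives, 2 false negatives, 1 false positive, 5 true negatives
  pos_cases <- c(sprintf("C%02d", 1:12), "C15")
  log <- data.frame(alert_id = seq_along(pos_cases), case_id = pos_cases,
                    alert_no = 9L, category = "MISSING_PPI")
  perf <- diagnostic_performance(log, ref)
  m <- perf[perf$category == "MISSING", ]
  expect_equal(unlist(m[c("tp", "fp", "tn", "fn")]),
               c(tp = 12, fp = 1, tn = 5, fn = 2))
  expect_equal(m$sensitivity, 12 / 14)
  expect_equal(m$specificity, 5 / 6)
  # no inappropriate incidents or alerts: sensitivity undefined, no false alarms
  i <- perf[perf$category == "INAPPROPRIATE", ]
  expect_true(is.na(i$sensitivity))
  expect_equal(i$specificity, 1)
  # mismatched case sets are rejected
  expect_error(diagnostic_performance(
    data.frame(case_id = "C99", alert_no = 9L, category = "MISSING_PPI"), ref),
    class = "domain_error")
})

test_that("diagnostic performance agrees with brute-force counting on random fixtures", {
  set.seed(99)
  for (trial in 1:1000) {
    n <- sample(5:30, 1)
    ref <- data.frame(case_id = sprintf("C%03d", 1:n),
                      category = sample(c("MISSING", "INAPPROPRIATE", "NONE"),
                                        n, TRUE))
    n_al <- sample(0:15, 1)
    log <- data.frame(case_id = sample(ref$case_id, n_al, TRUE),
                      alert_no = sample(1:12, n_al, TRUE))
    log$category <- ifelse(log$alert_no <= 11, "MISSING_PPI", "INAPPROPRIATE_PPI")
    perf <- diagnostic_performance(log, ref)
    for (cat_pair in list(c("MISSING", "MISSING_PPI"),
                          c("INAPPROPRIATE", "INAPPROPRIATE_PPI"))) {
      tp <- fp <- tn <- fn <- 0
      for (i in seq_len(n)) {
        alerted <- any(log$category == cat_pair[2] & log$case_id == ref$case_id[i])
        incident <- ref$category[i] == cat_pair[1]
        if (alerted && incident) tp <- tp + 1
        else if (alerted) fp <- fp + 1
        else if (incident) fn <- fn + 1
        else tn <- tn + 1
      }
      row <- perf[perf$category == cat_pair[1], ]
      expect_equal(unlist(row[c("tp", "fp", "tn", "fn")]),
                   c(tp = tp, fp = fp, tn = tn, fn = fn))
    }
  }
})

test_that("incidence comparison matches the textbook two-proportion chi-square", {
  cmp <- compare_incidence(67, 5178, 24, 5072)
  tab <- matrix(c(67, 5178 - 67, 24, 5072 - 24), 2, byrow = TRUE)
  ct <- chisq.test(tab, correct = FALSE)
  expect_equal(cmp$chi2_statistic, unname(ct$statistic))
  expect_equal(cmp$p_value, ct$p.value)
  cty <- chisq.test(tab, correct = TRUE)
  cmpy <- compare_incidence(67, 5178, 24, 5072, correct = TRUE)
  expect_equal(cmpy$p_value, cty$p.value)
  # identical rates: no signal
  cmp0 <- compare_incidence(50, 1000, 50, 1000)
  expect_equal(cmp0$relative_reduction, 0)
  expect_equal(cmp0$chi2_statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_error(compare_incidence(5, 0, 1, 10), class = "domain_error")
  expect_error(compare_incidence(11, 10, 1, 10), class = "domain_error")
})

test_that("swapping periods negates the relative reduction and keeps the p-value", {
  set.seed(3)
  for (i in 1:25) {
    na <- sample(50:5000, 1); nb <- sample(50:5000, 1)
    ia <- rbinom(1, na, 0.05); ib <- rbinom(1, nb, 0.04)
    if (ia == 0) next
    ab <- compare_incidence(ia, na, ib, nb)
    ba <- compare_incidence(ib, nb, ia, na)
    expect_equal(ab$p_value, ba$p_value)
    if (ib > 0 && ab$rate_a != ab$rate_b)
      expect_equal(sign(ab$relative_reduction),
                   -sign(ba$relative_reduction))
  }
})

test_that("online surveillance and the discharge snapshot agree on stable exposures", {
  gen <- generate_cohort(small_synth_config(n = 150, seed = 13))
  ds <- gen$dataset
  log <- run_surveillance(ds, kb, thr, triage_policy(mode = "always_intervene"))
  scr <- discharge_screen_all(ds, kb, thr)
  # a case screens MISSING at discharge iff a missing-PPI alert was raised
  alerted <- unique(log$case_id[log$category == "MISSING_PPI"])
  expect_setequal(scr$case_id[scr$category == "MISSING"], alerted)
})
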