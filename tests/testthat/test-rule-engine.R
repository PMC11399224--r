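# Alert predicates, suppression, on-demand windowing, PPI status and
# risk-factor profiling.

kb <- default_kb()
thr <- risk_thresholds()

test_that("candidate alerts match the rule table on characteristic constellations", {
  # NSAID + antiplatelet + therapeutic AC, no PPI: alerts 1 and 2, no DAPT
  p <- profile_for(nsaid = TRUE, n_ap_other = 1, ac = TRUE)
  expect_identical(evaluate_case(p, "NONE"), c(1L, 2L))
  expect_identical(suppress_alerts(evaluate_case(p, "NONE")), 1L)
  # DAPT alone
  expect_identical(evaluate_case(profile_for(aspirin = "low", n_ap_other = 1), "NONE"), 9L)
  # once-daily oral PPI, age only: inappropriate-PPI alert
  expect_identical(evaluate_case(profile_for(age65 = TRUE), "ORAL_ONCE_DAILY"), 12L)
  # twice-daily and intravenous PPIs are considered appropriate
  expect_length(evaluate_case(profile_for(age65 = TRUE), "ORAL_TWICE_DAILY"), 0)
  expect_length(evaluate_case(profile_for(), "INTRAVENOUS"), 0)
  # a PPI with any non-age factor is indicated
  expect_length(evaluate_case(profile_for(ssri = TRUE), "ORAL_ONCE_DAILY"), 0)
  # nothing to flag
  expect_length(evaluate_case(profile_for(), "NONE"), 0)
  # corticosteroids are not in the countable factor set: alert 12 still fires
  expect_identical(evaluate_case(profile_for(cs10 = TRUE), "ORAL_ONCE_DAILY"), 12L)
  # alerts 7/8 need a factor beyond their named triggers
  expect_identical(evaluate_case(profile_for(ac = TRUE, aspirin = "low",
                                             n_ap_other = 1), "NONE"), 9L)
  expect_setequal(evaluate_case(profile_for(ac = TRUE, aspirin = "low",
                                            n_ap_other = 1, age65 = TRUE), "NONE"),
                  c(7L, 8L, 9L))
})

test_that("suppression keeps the lowest missing-PPI alert plus alert 12", {
  expect_identical(suppress_alerts(c(1L, 2L)), 1L)
  expect_identical(suppress_alerts(c(4L, 5L, 11L)), 4L)
  expect_identical(suppress_alerts(12L), 12L)
  expect_identical(suppress_alerts(integer()), integer())
  expect_identical(suppress_alerts(c(3L, 12L)), c(3L, 12L))
})

test_that("engine predicates and suppression match the brute-force rule-table oracle", {
  grid <- expand.grid(nsaid = c(FALSE, TRUE), cox2 = c(FALSE, TRUE),
                      ac = c(FALSE, TRUE), cs10 = c(FALSE, TRUE),
                      ssri = c(FALSE, TRUE), age65 = c(FALSE, TRUE),
                      tc30 = c(FALSE, TRUE),
                      aspirin = c("none", "low", "high"),
                      n_ap_other = 0:2,
                      ppi = c("NONE", "ORAL_ONCE_DAILY",
                              "ORAL_TWICE_DAILY", "INTRAVENOUS"),
                      stringsAsFactors = FALSE)
  mismatch <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    want <- oracle_alerts(g$nsaid, g$cox2, g$aspirin, g$n_ap_other, g$ac,
                          g$cs10, g$ssri, g$age65, g$tc30, g$ppi)
    prof <- profile_for(g$nsaid, g$cox2, g$aspirin, g$n_ap_other, g$ac,
                        g$cs10, g$ssri, g$age65, g$tc30)
    got <- evaluate_case(prof, g$ppi)
    if (!identical(got, as.integer(want)) ||
        !identical(suppress_alerts(got), as.integer(oracle_suppress(want))))
      mismatch <- mismatch + 1L
  }
  expect_identical(mismatch, 0L)
})

test_that("on-demand exposure needs at least seven doses inside the 48-h window", {
  mk <- function(times) {
    rx <- data.frame(drug_id = "M01AE01", schedule = "on_demand",
                     start = ts_day(1), end = ts_day(10))
    mini_cohort(rx = rx, admins = data.frame(rx_id = "R1", given_at = times))
  }
  t <- ts_day(5)
  ds7 <- mk(t - hours(seq(2, 44, by = 7)))        # 7 doses inside the window
  expect_true(on_demand_exposure(ds7, thr, "R1", t))
  ds6 <- mk(t - hours(seq(2, 44, by = 8.4)))      # only 6 doses
  expect_false(on_demand_exposure(ds6, thr, "R1", t))
  # 7 doses but two fall outside the trailing 48 h
  ds5 <- mk(c(t - hours(c(50, 49)), t - hours(seq(2, 42, by = 10))))
  expect_false(on_demand_exposure(ds5, thr, "R1", t))
  expect_error(on_demand_exposure(mini_cohort(
    rx = data.frame(drug_id = "M01AE01")), thr, "R1", ts_day(2)),
    class = "domain_error")
})

test_that("PPI status ranks intravenous over twice-daily over once-daily", {
  mk <- function(route = "oral", freq = 1) mini_cohort(
    rx = data.frame(drug_id = "A02BC02", route = route, frequency_per_day = freq))
  expect_identical(ppi_status(mk(), kb, "C1", ts_day(2)), "ORAL_ONCE_DAILY")
  expect_identical(ppi_status(mk(freq = 2), kb, "C1", ts_day(2)), "ORAL_TWICE_DAILY")
  expect_identical(ppi_status(mk(route = "iv"), kb, "C1", ts_day(2)), "INTRAVENOUS")
  expect_identical(ppi_status(mini_cohort(), kb, "C1", ts_day(2)), "NONE")
})

test_that("risk profiling combines prescriptions, labs and age at a time point", {
  rx <- data.frame(drug_id = c("M01AE01", "B01AC04"))
  ds <- mini_cohort(rx = rx, age = 50)
  p <- risk_profile(ds, kb, thr, "C1", ts_day(3))
  expect_true(p$nsaid && p$antiplatelet_non_aspirin && p$antiplatelet_any)
  expect_false(p$dapt || p$age_ge65)
  expect_equal(p$factor_count, 2)
  # age alone
  p2 <- risk_profile(mini_cohort(age = 70), kb, thr, "C1", ts_day(3))
  expect_true(p2$age_ge65); expect_equal(p2$factor_count, 1)
  # latest thrombocyte value below 30 G/L, nothing else
  ds3 <- mini_cohort(labs = data.frame(value = 29, measured_at = ts_day(1, 6)),
                     age = 40)
  p3 <- risk_profile(ds3, kb, thr, "C1", ts_day(2))
  expect_true(p3$thrombocytes_lt30); expect_equal(p3$factor_count, 1)
  # a later normal value clears the flag
  ds4 <- mini_cohort(labs = data.frame(value = c(29, 180),
                                       measured_at = c(ts_day(1), ts_day(2))))
  expect_false(risk_profile(ds4, kb, thr, "C1", ts_day(3))$thrombocytes_lt30)
  # two distinct antiplatelet agents make DAPT; aspirin counts once
  ds5 <- mini_cohort(rx = data.frame(drug_id = c("B01AC06", "B01AC04"),
                                     daily_dose = c(100, 75)))
  expect_true(risk_profile(ds5, kb, thr, "C1", ts_day(2))$dapt)
  ds6 <- mini_cohort(rx = data.frame(drug_id = c("B01AC06", "N02BA01"),
                                     daily_dose = c(100, 100)))
  expect_false(risk_profile(ds6, kb, thr, "C1", ts_day(2))$dapt)
})

test_that("on-demand NSAIDs enter the profile only via the dose-window rule", {
  rx <- data.frame(drug_id = "M01AE01", schedule = "on_demand")
  t <- ts_day(5)
  dense <- data.frame(rx_id = "R1", given_at = t - hours(seq(2, 44, by = 6)))
  ds_dense <- mini_cohort(rx = rx, admins = dense)
  expect_true(risk_profile(ds_dense, kb, thr, "C1", t)$nsaid)
  sparse <- data.frame(rx_id = "R1", given_at = t - hours(c(2, 30)))
  ds_sparse <- mini_cohort(rx = rx, admins = sparse)
  expect_false(risk_profile(ds_sparse, kb, thr, "C1", t)$nsaid)
  # the replicated historical defect counts them unconditionally
  expect_true(risk_profile(ds_sparse, kb, thr, "C1", t,
                           replicate_bug_on_demand = TRUE)$nsaid)
})
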