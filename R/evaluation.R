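# Assessment machinery: discharge-day reference screening, the diagnostic
# performance (sensitivity/specificity) decision pathway, and the
# before/after incidence comparison with the two-proportion chi-square.

INCIDENT_CATEGORIES <- c("MISSING", "INAPPROPRIATE", "NONE")

discharge_snapshot_time <- function(adm_n, dis_n, step_s) {
  k <- floor((dis_n - adm_n) / step_s)
  t <- adm_n + k * step_s
  t[t >= dis_n] <- t[t >= dis_n] - step_s
  pmax(t, adm_n)
}

#' Screen one case for a PPI incident on the day of discharge
#'
#' Evaluates the same alert predicates as the surveillance engine at the
#' discharge-day snapshot (the last surveillance tick, anchored at
#' admission, strictly before the discharge timestamp) and classifies the
#' case: `MISSING` when no PPI is active and at least one missing-PPI
#' predicate holds, `INAPPROPRIATE` when the inappropriate-PPI predicate
#' holds, `NONE` otherwise.
#'
#' @inheritParams risk_profile
#' @param step_hours tick spacing used to place the snapshot (default 1)
#' @return list with `case_id`, `category`, `alert_no` (lowest-numbered
#'   holding predicate, or `NA`), and the `basis` snapshot (risk profile
#'   flags and PPI status)
#' @export
discharge_screen <- function(ds, kb, thresholds = risk_thresholds(), case_id,
                             step_hours = 1, replicate_bug_on_demand = FALSE) {
  cs <- case_row(ds, case_id)
  if (is.na(cs$discharge))
    ppi_stop("domain_error", "case %s is still open; discharge screening needs a discharged case", case_id)
  if (isTRUE(cs$excluded))
    ppi_stop("domain_error", "case %s is excluded from analysis (%s)", case_id,
             cs$exclusion_reason)
  out <- discharge_screen_all(ds, kb, thresholds, step_hours = step_hours,
                              replicate_bug_on_demand = replicate_bug_on_demand,
                              case_ids = case_id)
  list(case_id = case_id, category = out$category, alert_no = out$alert_no,
       basis = as.list(out[1, setdiff(names(out), c("case_id", "category", "alert_no"))]))
}

#' Discharge-day screening of every discharged, included case
#'
#' Vectorised form of [discharge_screen].
#'
#' @inheritParams discharge_screen
#' @param case_ids cases to screen; defaults to all discharged cases not
#'   flagged excluded
#' @return data frame with one row per case: `case_id`, `category`,
#'   `alert_no` plus the snapshot flag columns
#' @export
discharge_screen_all <- function(ds, kb, thresholds = risk_thresholds(),
                                 step_hours = 1,
                                 replicate_bug_on_demand = FALSE,
                                 case_ids = NULL) {
  ann <- annotate_cohort(ds, kb, thresholds)
  cases <- ann$cases
  if (is.null(case_ids)) {
    cases <- cases[!cases$excluded & is.finite(cases$dis_n), , drop = FALSE]
  } else {
    cases <- cases[match(case_ids, cases$case_id), , drop = FALSE]
    if (anyNA(cases$case_id)) ppi_stop("domain_error", "unknown case id(s)")
    if (any(!is.finite(cases$dis_n)))
      ppi_stop("domain_error", "discharge screening needs discharged cases")
  }
  t_snap <- discharge_snapshot_time(cases$adm_n, cases$dis_n, hours(step_hours))
  fl <- snapshot_flags(ann, t_snap, cases$case_id, replicate_bug_on_demand)
  cand <- evaluate_flags(fl, thresholds$multi_factor_min)
  first <- vapply(cand, function(x) if (length(x)) x[[1]] else NA_integer_, 1L)
  fl$alert_no <- first
  fl$category <- ifelse(is.na(first), "NONE",
                 ifelse(first <= 11L, "MISSING", "INAPPROPRIATE"))
  fl[, c("case_id", "category", "alert_no",
         setdiff(names(fl), c("case_id", "category", "alert_no")))]
}

#' Diagnostic performance of the engine against a reference standard
#'
#' A case is test-positive for a category when at least one alert of that
#' category was raised for it during the stay (whatever the alert's final
#' lifecycle state). The reference is the per-case incident classification
#' (`MISSING` / `INAPPROPRIATE` / `NONE`), either from discharge screening
#' of real records or the ground-truth labels of a synthetic cohort.
#' Sensitivity and specificity are computed per category, not per individual
#' alert; undefined ratios (empty denominator) are reported as `NA`.
#'
#' @param log an `alert_log`
#' @param reference data frame with columns `case_id` and `category`
#'   covering exactly the monitored case set
#' @return data frame of class `diagnostic_performance`: one row per
#'   category with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`
#' @export
diagnostic_performance <- function(log, reference) {
  if (!all(c("case_id", "category") %in% names(reference)))
    ppi_stop("validation_error", "reference needs case_id and category columns")
  if (anyDuplicated(reference$case_id))
    ppi_stop("validation_error", "reference has duplicated case ids")
  bad <- setdiff(reference$category, INCIDENT_CATEGORIES)
  if (length(bad))
    ppi_stop("validation_error", "unknown reference categories: %s",
             paste(bad, collapse = ", "))
  monitored <- attr(log, "case_ids")
  if (!is.null(monitored)) {
    if (!setequal(monitored, reference$case_id))
      ppi_stop("domain_error",
               "alert log and reference cover different case sets (%d vs %d cases)",
               length(monitored), nrow(reference))
  } else if (!all(log$case_id %in% reference$case_id)) {
    ppi_stop("domain_error", "alert log contains cases absent from the reference")
  }
  cats <- c(MISSING = "MISSING_PPI", INAPPROPRIATE = "INAPPROPRIATE_PPI")
  out <- do.call(rbind, lapply(names(cats), function(ref_cat) {
    pos_cases <- unique(log$case_id[log$category == cats[[ref_cat]]])
    test_pos <- reference$case_id %in% pos_cases
    ref_pos <- reference$category == ref_cat
    tp <- sum(test_pos & ref_pos); fp <- sum(test_pos & !ref_pos)
    fn <- sum(!test_pos & ref_pos); tn <- sum(!test_pos & !ref_pos)
    data.frame(category = ref_cat, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
  structure(out, class = c("diagnostic_performance", "data.frame"))
}

#' Before/after incidence comparison
#'
#' Compares per-case incidence proportions between two observation periods
#' with the two-proportion Pearson chi-square on the 2x2 contingency table
#' (incident / no incident by period); Yates continuity correction is off by
#' default and available via `correct`. The relative reduction is
#' `(rate_a - rate_b) / rate_a * 100`.
#'
#' @param incidents_a,cases_a incident and case counts of the first
#'   (reference) period
#' @param incidents_b,cases_b counts of the second period
#' @param correct apply Yates continuity correction
#' @return object of class `incidence_comparison` with the counts, rates,
#'   `relative_reduction` (percent), `chi2_statistic`, `p_value` and
#'   `correction_used`
#' @export
compare_incidence <- function(incidents_a, cases_a, incidents_b, cases_b,
                              correct = FALSE) {
  counts <- c(incidents_a, cases_a, incidents_b, cases_b)
  if (any(!vapply(counts, is_scalar_number, TRUE)))
    ppi_stop("validation_error", "all four counts must be single numbers")
  if (cases_a <= 0 || cases_b <= 0)
    ppi_stop("domain_error", "case counts must be positive")
  if (incidents_a < 0 || incidents_b < 0 || incidents_a > cases_a || incidents_b > cases_b)
    ppi_stop("domain_error", "incident counts must lie in [0, cases]")
  tab <- matrix(c(incidents_a, cases_a - incidents_a,
                  incidents_b, cases_b - incidents_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(period = c("a", "b"),
                                outcome = c("incident", "none")))
  rate_a <- incidents_a / cases_a
  rate_b <- incidents_b / cases_b
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  chi2 <- unname(ct$statistic); p <- ct$p.value
  structure(list(incidents_a = incidents_a, cases_a = cases_a,
                 incidents_b = incidents_b, cases_b = cases_b,
                 rate_a = rate_a, rate_b = rate_b,
                 relative_reduction = if (rate_a > 0) (rate_a - rate_b) / rate_a * 100 else NA_real_,
                 chi2_statistic = chi2, p_value = p,
                 correction_used = correct, table = tab),
            class = "incidence_comparison")
}

#' @export
print.incidence_comparison <- function(x, ...) {
  cat(sprintf("Incidence comparison: %d/%d (%.2f%%) vs %d/%d (%.2f%%)\n",
              x$incidents_a, x$cases_a, 100 * x$rate_a,
              x$incidents_b, x$cases_b, 100 * x$rate_b))
  cat(sprintf("  relative reduction: %.1f%% | chi-square %.3f (%s) | p = %s\n",
              x$relative_reduction, x$chi2_statistic,
              if (x$correction_used) "Yates-corrected" else "uncorrected",
              sprintf("%.3g", x$p_value)))
  invisible(x)
}
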