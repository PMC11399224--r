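# Hand-built cohort fixtures and an independently written truth-table
# oracle of the alert rules, used to cross-check the engine.

DAY1 <- as.POSIXct("2021-07-01 00:00:00", tz = "UTC")

ts_day <- function(d, h = 0) DAY1 + (d - 1) * 86400 + h * 3600

# one-patient / one-case cohort with arbitrary prescriptions, labs and
# administrations; rx columns beyond drug_id/start/end get sensible defaults
mini_cohort <- function(rx = NULL, labs = NULL, admins = NULL,
                        age = 50, consent = TRUE,
                        admission = ts_day(1), discharge = ts_day(10),
                        case_id = "C1") {
  patients <- data.frame(patient_id = "P1",
                         birth_date = as.Date(admission) - round(age * 365.25) - 100,
                         sex = "F", consent = consent)
  cases <- data.frame(case_id = case_id, patient_id = "P1",
                      admission = admission, discharge = discharge,
                      period_label = "intervention")
  if (!is.null(rx)) {
    n <- nrow(rx)
    rx$rx_id <- rx$rx_id %||% sprintf("R%d", seq_len(n))
    rx$case_id <- rx$case_id %||% case_id
    rx$daily_dose <- rx$daily_dose %||% rep(100, n)
    rx$dose_unit <- rx$dose_unit %||% rep("mg", n)
    rx$route <- rx$route %||% rep("oral", n)
    rx$frequency_per_day <- rx$frequency_per_day %||% rep(1, n)
    rx$schedule <- rx$schedule %||% rep("regular", n)
    rx$start <- rx$start %||% rep(admission, n)
    rx$end <- rx$end %||% rep(discharge, n)
  }
  if (!is.null(labs)) {
    labs$case_id <- labs$case_id %||% case_id
    labs$analyte <- labs$analyte %||% "thrombocytes"
    labs$unit <- labs$unit %||% "G/L"
  }
  if (!is.null(admins)) {
    admins$admin_id <- admins$admin_id %||% sprintf("AD%d", seq_len(nrow(admins)))
  }
  cohort_dataset(patients, cases, rx, admins, labs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent brute-force transcription of the alert rule table --------
# states: flags plus aspirin in {"none","low","high"} and a count of
# non-aspirin antiplatelet agents; deliberately written as literal per-row
# conditions, separate from the package's vectorised implementation
oracle_alerts <- function(nsaid = FALSE, cox2 = FALSE, aspirin = "none",
                          n_ap_other = 0, ac = FALSE, cs10 = FALSE,
                          ssri = FALSE, age65 = FALSE, tc30 = FALSE,
                          ppi = "NONE", multi_factor_min = 4) {
  n_agents <- (aspirin != "none") + n_ap_other
  ap_any <- n_agents >= 1
  dapt <- n_agents >= 2
  lda <- aspirin == "low"
  other <- nsaid || cox2 || ssri || age65 || tc30
  cand <- integer()
  if (ppi == "NONE") {
    if (nsaid && ap_any) cand <- c(cand, 1L)
    if (nsaid && ac) cand <- c(cand, 2L)
    if (nsaid && cs10) cand <- c(cand, 3L)
    if (nsaid && ssri) cand <- c(cand, 4L)
    if (nsaid && age65) cand <- c(cand, 5L)
    if (nsaid && tc30) cand <- c(cand, 6L)
    if (ac && dapt && other) cand <- c(cand, 7L)
    if (ac && lda && other) cand <- c(cand, 8L)
    if (dapt) cand <- c(cand, 9L)
    if (lda && cs10 && age65) cand <- c(cand, 10L)
    if (sum(nsaid, cox2, ap_any, ac, ssri, age65, tc30) >= multi_factor_min)
      cand <- c(cand, 11L)
  }
  if (ppi == "ORAL_ONCE_DAILY" &&
      !(nsaid || cox2 || ap_any || ac || ssri || tc30))
    cand <- c(cand, 12L)
  cand
}

oracle_suppress <- function(cand) {
  out <- integer()
  low <- cand[cand < 12L]
  if (length(low)) out <- min(low)
  if (any(cand == 12L)) out <- c(out, 12L)
  out
}

# profile object matching an oracle state, via the package constructor
profile_for <- function(nsaid = FALSE, cox2 = FALSE, aspirin = "none",
                        n_ap_other = 0, ac = FALSE, cs10 = FALSE,
                        ssri = FALSE, age65 = FALSE, tc30 = FALSE) {
  risk_profile_flags(
    nsaid = nsaid, cox2 = cox2,
    low_dose_aspirin = aspirin == "low",
    antiplatelet_non_aspirin = n_ap_other >= 1 || aspirin == "high",
    therapeutic_ac = ac, corticosteroid_ge10 = cs10, ssri = ssri,
    age_ge65 = age65, thrombocytes_lt30 = tc30,
    n_antiplatelet_agents = (aspirin != "none") + n_ap_other)
}

# small noise-free synthetic cohort shared across tests
small_synth_config <- function(n = 300, p_missing = 0.05,
                               p_inappropriate = 0.10,
                               p_on_demand_nsaid = 0.3, seed = 42,
                               window = c("2021-07-01", "2021-07-21")) {
  cohort_config(n_baseline = 0, n_intervention = n,
                intervention_window = window,
                p_missing = c(baseline = 0, intervention = p_missing),
                p_inappropriate = c(baseline = 0, intervention = p_inappropriate),
                p_on_demand_nsaid = p_on_demand_nsaid, seed = seed)
}
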