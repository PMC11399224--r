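# The alert engine: risk-factor profiling at a time point, the twelve alert
# predicates, lower-number-wins suppression, the hourly surveillance loop
# with alert lifecycle (pending -> intervention / not relevant / resolved)
# and automatic termination, and triage accounting.
#
# The seven countable risk factors ("the factor set") are: NSAID, COX2
# inhibitor, antiplatelet therapy (one factor however many agents),
# therapeutic anticoagulation, SSRI, age >= 65 years and thrombocytes
# < 30 G/L. Corticosteroids >= 10 mg prednisone equivalent trigger specific
# alerts but are not part of the countable factor set.

ALERT_LABELS <- c(
  "NSAID and antiplatelet therapy",
  "NSAID and therapeutic anticoagulation",
  "NSAID and corticosteroid >= 10 mg prednisone equivalent",
  "NSAID and drug associated with gastrointestinal bleeding",
  "NSAID and age >= 65 years",
  "NSAID and thrombocytes < 30 G/L",
  "Therapeutic anticoagulation + DAPT and risk factor",
  "Therapeutic anticoagulation + low dose aspirin and risk factor",
  "Dual antiplatelet therapy (DAPT)",
  "Low dose aspirin + corticosteroid >= 10 mg prednisone eq. and age >= 65 years",
  ">= 4 risk factors present",
  "PPI without any risk factors (excluding age >= 65 years)")

PPI_STATUSES <- c("NONE", "ORAL_ONCE_DAILY", "ORAL_TWICE_DAILY", "INTRAVENOUS")

#' The twelve alert definitions
#'
#' @return data frame with `alert_no`, `category` (`MISSING_PPI` for alerts
#'   1--11, `INAPPROPRIATE_PPI` for alert 12) and the human-readable trigger
#'   text
#' @export
alert_definitions <- function() {
  data.frame(alert_no = 1:12,
             category = c(rep("MISSING_PPI", 11), "INAPPROPRIATE_PPI"),
             label = ALERT_LABELS)
}

alert_category <- function(alert_no) {
  ifelse(alert_no <= 11, "MISSING_PPI", "INAPPROPRIATE_PPI")
}

#' Construct a risk profile from explicit flags
#'
#' Mainly useful for testing predicates directly; [risk_profile] derives the
#' same structure from a dataset. `n_antiplatelet_agents` counts distinct
#' concurrent antiplatelet agents with aspirin (at any dose) counting as one
#' agent; it defaults to one per aspirin/non-aspirin flag set. Dual
#' antiplatelet therapy (DAPT) means two or more concurrent agents.
#'
#' @param nsaid,cox2,low_dose_aspirin,antiplatelet_non_aspirin,therapeutic_ac,corticosteroid_ge10,ssri,age_ge65,thrombocytes_lt30
#'   logical flags
#' @param n_antiplatelet_agents integer count of distinct antiplatelet agents
#' @return object of class `risk_profile` with derived `dapt`,
#'   `antiplatelet_any` and `factor_count`
#' @export
risk_profile_flags <- function(nsaid = FALSE, cox2 = FALSE,
                               low_dose_aspirin = FALSE,
                               antiplatelet_non_aspirin = FALSE,
                               therapeutic_ac = FALSE,
                               corticosteroid_ge10 = FALSE, ssri = FALSE,
                               age_ge65 = FALSE, thrombocytes_lt30 = FALSE,
                               n_antiplatelet_agents = NULL) {
  n_agents <- n_antiplatelet_agents %||%
    (as.integer(low_dose_aspirin) + as.integer(antiplatelet_non_aspirin))
  antiplatelet_any <- n_agents >= 1L || low_dose_aspirin || antiplatelet_non_aspirin
  structure(list(
    nsaid = nsaid, cox2 = cox2, low_dose_aspirin = low_dose_aspirin,
    antiplatelet_non_aspirin = antiplatelet_non_aspirin,
    therapeutic_ac = therapeutic_ac, corticosteroid_ge10 = corticosteroid_ge10,
    ssri = ssri, age_ge65 = age_ge65, thrombocytes_lt30 = thrombocytes_lt30,
    n_antiplatelet_agents = as.integer(n_agents),
    antiplatelet_any = antiplatelet_any,
    dapt = n_agents >= 2L,
    factor_count = sum(nsaid, cox2, antiplatelet_any, therapeutic_ac, ssri,
                       age_ge65, thrombocytes_lt30)
  ), class = "risk_profile")
}

#' Candidate alerts for a risk profile and PPI status
#'
#' Evaluates all twelve predicates. Alerts 1--11 (missing gastroprotection)
#' require that no PPI is active. Alert 12 (potentially inappropriate PPI)
#' fires only for a once-daily oral PPI -- intravenous and twice-daily
#' prescriptions are considered appropriate -- with no countable risk factor
#' other than age present. "And risk factor" in alerts 7 and 8 means any
#' countable factor not already consumed by the alert's named triggers
#' (i.e. NSAID, COX2, SSRI, age or thrombocytopenia).
#'
#' @param profile a `risk_profile`
#' @param ppi one of `"NONE"`, `"ORAL_ONCE_DAILY"`, `"ORAL_TWICE_DAILY"`,
#'   `"INTRAVENOUS"`
#' @param multi_factor_min factor count triggering alert 11
#' @return ascending integer vector of candidate alert numbers
#' @export
evaluate_case <- function(profile, ppi, multi_factor_min = 4) {
  stopifnot(inherits(profile, "risk_profile"))
  ppi <- match.arg(ppi, PPI_STATUSES)
  p <- profile
  other_factor <- p$nsaid || p$cox2 || p$ssri || p$age_ge65 || p$thrombocytes_lt30
  out <- integer()
  if (ppi == "NONE") {
    pred <- c(
      p$nsaid && p$antiplatelet_any,
      p$nsaid && p$therapeutic_ac,
      p$nsaid && p$corticosteroid_ge10,
      p$nsaid && p$ssri,
      p$nsaid && p$age_ge65,
      p$nsaid && p$thrombocytes_lt30,
      p$therapeutic_ac && p$dapt && other_factor,
      p$therapeutic_ac && p$low_dose_aspirin && other_factor,
      p$dapt,
      p$low_dose_aspirin && p$corticosteroid_ge10 && p$age_ge65,
      p$factor_count >= multi_factor_min)
    out <- which(pred)
  } else if (ppi == "ORAL_ONCE_DAILY") {
    non_age <- p$nsaid || p$cox2 || p$antiplatelet_any || p$therapeutic_ac ||
      p$ssri || p$thrombocytes_lt30
    if (!non_age) out <- 12L
  }
  as.integer(out)
}

#' Suppress duplicate alerts
#'
#' Lower-numbered alerts suppress higher-numbered ones: of the candidate
#' missing-PPI alerts (1--11) only the minimum is retained. Alert 12 is
#' retained when present (its PPI precondition is mutually exclusive with
#' alerts 1--11, so it never competes).
#'
#' @param candidates ascending integer vector of candidate alert numbers
#' @return integer vector with at most one missing-PPI alert plus alert 12
#' @export
suppress_alerts <- function(candidates) {
  stopifnot(!is.unsorted(candidates))
  missing_ppi <- candidates[candidates <= 11L]
  keep <- integer()
  if (length(missing_ppi)) keep <- min(missing_ppi)
  if (12L %in% candidates) keep <- c(keep, 12L)
  as.integer(keep)
}

#' Does an on-demand prescription count as exposure at `t`?
#'
#' An on-demand NSAID counts as risk exposure only when administered "more
#' than six times" within the trailing window: at least
#' `on_demand_min_doses` (default 7) administrations in the half-open window
#' `(t - on_demand_window_hours, t]`.
#'
#' @param ds a `cohort_dataset`
#' @param thresholds a [risk_thresholds] object
#' @param rx_id identifier of an on-demand prescription
#' @param t timestamp
#' @return logical
#' @export
on_demand_exposure <- function(ds, thresholds, rx_id, t) {
  i <- match(rx_id, ds$prescriptions$rx_id)
  if (is.na(i)) ppi_stop("domain_error", "unknown prescription: %s", rx_id)
  if (ds$prescriptions$schedule[i] != "on_demand")
    ppi_stop("domain_error", "prescription %s is not on-demand", rx_id)
  t <- parse_ts(t)
  given <- ds$administrations$given_at[ds$administrations$rx_id == rx_id]
  n <- sum(given > t - hours(thresholds$on_demand_window_hours) & given <= t)
  n >= thresholds$on_demand_min_doses
}

# ---------------------------------------------------------------------------
# annotated cohort: everything precomputed for fast time-point evaluation

annotate_cohort <- function(ds, kb, thresholds) {
  rx <- ds$prescriptions
  n <- nrow(rx)
  code <- character(n); base <- character(n)
  eff <- vector("list", n)
  if (n) {
    key <- paste(rx$drug_id, rx$daily_dose, sep = "\r")
    uk <- !duplicated(key)
    ucode <- vapply(rx$drug_id[uk], function(d) resolve_drug_code(kb, d), "")
    ubase <- vapply(ucode, function(cd) match_class(kb, cd), "")
    ueff <- mapply(function(d, dose) effective_classes(kb, thresholds, d, dose),
                   rx$drug_id[uk], rx$daily_dose[uk], SIMPLIFY = FALSE)
    idx <- match(key, key[uk])
    code <- ucode[idx]; base <- ubase[idx]; eff <- ueff[idx]
  }
  has <- function(tag) vapply(eff, function(e) tag %in% e, TRUE)
  rx_ann <- data.frame(
    rx_id = rx$rx_id, case_id = rx$case_id,
    start_n = as.numeric(rx$start),
    end_n = ifelse(is.na(rx$end), Inf, as.numeric(rx$end)),
    on_demand = rx$schedule == "on_demand",
    stringsAsFactors = FALSE)
  if (n) {
    rx_ann$f_nsaid <- has("NSAID"); rx_ann$f_cox2 <- has("COX2")
    rx_ann$f_lda <- has("LOW_DOSE_ASPIRIN"); rx_ann$f_ap <- has("ANTIPLATELET")
    rx_ann$f_ac <- has("THERAPEUTIC_AC"); rx_ann$f_cs10 <- has("CORTICOSTEROID_GE10")
    rx_ann$f_ssri <- has("SSRI"); rx_ann$f_ppi <- has("PPI")
    rx_ann$ppi_iv <- rx_ann$f_ppi & rx$route == "iv"
    rx_ann$ppi_bid <- rx_ann$f_ppi & !rx_ann$ppi_iv & rx$frequency_per_day >= 2
    rx_ann$agent_key <- ifelse(base == "ASPIRIN", "ASPIRIN", code)
    rx_ann$od_nsaid <- rx_ann$on_demand & base %in% c("NSAID", "COX2")
  } else {
    for (cn in c("f_nsaid", "f_cox2", "f_lda", "f_ap", "f_ac", "f_cs10",
                 "f_ssri", "f_ppi", "ppi_iv", "ppi_bid", "od_nsaid"))
      rx_ann[[cn]] <- logical(0)
    rx_ann$agent_key <- character(0)
  }
  # administration times (sorted, numeric) for on-demand prescriptions
  od_ids <- rx_ann$rx_id[rx_ann$on_demand]
  ad <- ds$administrations[ds$administrations$rx_id %in% od_ids, , drop = FALSE]
  admin_times <- lapply(split(as.numeric(ad$given_at), ad$rx_id), sort)
  # thrombocyte labs per case, sorted by time
  lb <- ds$labs[ds$labs$analyte == "thrombocytes", , drop = FALSE]
  lb <- lb[order(lb$case_id, lb$measured_at), , drop = FALSE]
  lab_split <- split(data.frame(t = as.numeric(lb$measured_at), v = lb$value),
                     lb$case_id)
  cs <- ds$cases
  birth <- ds$patients$birth_date[match(cs$patient_id, ds$patients$patient_id)]
  list(rx = rx_ann, admin_times = admin_times, labs = lab_split,
       cases = data.frame(case_id = cs$case_id,
                          adm_n = as.numeric(cs$admission),
                          dis_n = ifelse(is.na(cs$discharge), Inf,
                                         as.numeric(cs$discharge)),
                          excluded = cs$excluded,
                          age_thr_n = as.numeric(anniversary_ts(birth, thresholds$age_min)),
                          stringsAsFactors = FALSE),
       thresholds = thresholds)
}

# timestamp at which a person attains `years` completed years (the birthday
# itself counts); Feb 29 birthdays roll over to Mar 1 in non-leap years
anniversary_ts <- function(birth_date, years) {
  if (!length(birth_date))
    return(as.POSIXct(character(), tz = "UTC"))
  y <- as.integer(format(birth_date, "%Y")) + years
  md <- format(birth_date, "-%m-%d")
  d <- as.Date(paste0(y, md))
  feb29 <- which(is.na(d) & md == "-02-29")
  if (length(feb29)) d[feb29] <- as.Date(paste0(y[feb29], "-03-01"))
  as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
}

# count administrations in the half-open window (t - w, t]
window_dose_count <- function(times, t, window_s) {
  if (is.null(times) || !length(times)) return(0L)
  sum(times > t - window_s & times <= t)
}

# Flags for a set of cases at time point(s) t (scalar, or one per case).
# Returns a data.frame with one row per case id, in the order of `ids`.
snapshot_flags <- function(ann, t, ids, replicate_bug_on_demand = FALSE) {
  thr <- ann$thresholds
  nids <- length(ids)
  fl <- data.frame(case_id = ids, stringsAsFactors = FALSE)
  flag_cols <- c("nsaid", "cox2", "low_dose_aspirin", "antiplatelet_non_aspirin",
                 "therapeutic_ac", "corticosteroid_ge10", "ssri",
                 "age_ge65", "thrombocytes_lt30", "ppi", "ppi_iv", "ppi_bid")
  for (cn in flag_cols) fl[[cn]] <- logical(nids)
  fl$n_antiplatelet_agents <- integer(nids)
  if (!nids) {
    fl$factor_count <- integer(0); fl$antiplatelet_any <- logical(0)
    fl$dapt <- logical(0); fl$ppi_status <- character(0)
    return(fl)
  }
  t_n <- if (is.numeric(t)) t else as.numeric(parse_ts(t))
  t_by_id <- if (length(t_n) == 1L) rep(t_n, nids) else t_n
  stopifnot(length(t_by_id) == nids)

  rx <- ann$rx
  ci <- match(rx$case_id, ids)
  tt <- t_by_id[ci]
  minexp <- hours(thr$min_exposure_hours)
  active <- !is.na(ci) & rx$start_n <= tt - minexp & tt < rx$end_n
  # on-demand NSAIDs additionally need >= on_demand_min_doses in the window;
  # the historical implementation defect counted them unconditionally
  # (replicate_bug_on_demand = TRUE reproduces that behaviour)
  if (!replicate_bug_on_demand && any(active & rx$od_nsaid)) {
    w <- hours(thr$on_demand_window_hours)
    sel <- which(active & rx$od_nsaid)
    counts <- vapply(sel, function(i)
      window_dose_count(ann$admin_times[[rx$rx_id[i]]], tt[i], w), 0L)
    active[sel] <- counts >= thr$on_demand_min_doses
  }
  agg_any <- function(col) {
    out <- logical(nids)
    out[ci[active & rx[[col]]]] <- TRUE
    out
  }
  fl$nsaid <- agg_any("f_nsaid"); fl$cox2 <- agg_any("f_cox2")
  fl$low_dose_aspirin <- agg_any("f_lda")
  fl$antiplatelet_non_aspirin <- agg_any("f_ap")
  fl$therapeutic_ac <- agg_any("f_ac")
  fl$corticosteroid_ge10 <- agg_any("f_cs10")
  fl$ssri <- agg_any("f_ssri")
  fl$ppi <- agg_any("f_ppi"); fl$ppi_iv <- agg_any("ppi_iv")
  fl$ppi_bid <- agg_any("ppi_bid")
  # distinct antiplatelet agents (aspirin collapses to one agent)
  ap <- which(active & (rx$f_lda | rx$f_ap))
  if (length(ap)) {
    dd <- ap[!duplicated(paste(ci[ap], rx$agent_key[ap]))]
    fl$n_antiplatelet_agents <- tabulate(ci[dd], nbins = nids)
  }
  # age and latest thrombocyte value
  cmeta <- ann$cases[match(ids, ann$cases$case_id), ]
  fl$age_ge65 <- t_by_id >= cmeta$age_thr_n
  fl$thrombocytes_lt30 <- vapply(seq_len(nids), function(i) {
    lab <- ann$labs[[ids[i]]]
    if (is.null(lab)) return(FALSE)
    k <- findInterval(t_by_id[i], lab$t)
    k > 0 && lab$v[k] < thr$thrombocyte_max
  }, TRUE)
  fl$antiplatelet_any <- fl$n_antiplatelet_agents >= 1L
  fl$dapt <- fl$n_antiplatelet_agents >= 2L
  fl$factor_count <- fl$nsaid + fl$cox2 + fl$antiplatelet_any +
    fl$therapeutic_ac + fl$ssri + fl$age_ge65 + fl$thrombocytes_lt30
  fl$ppi_status <- ifelse(!fl$ppi, "NONE",
                   ifelse(fl$ppi_iv, "INTRAVENOUS",
                   ifelse(fl$ppi_bid, "ORAL_TWICE_DAILY", "ORAL_ONCE_DAILY")))
  fl
}

# vectorised candidate evaluation over a snapshot_flags frame;
# returns a list of ascending integer vectors, one per row
evaluate_flags <- function(fl, multi_factor_min = 4) {
  n <- nrow(fl)
  if (!n) return(list())
  no_ppi <- fl$ppi_status == "NONE"
  other <- fl$nsaid | fl$cox2 | fl$ssri | fl$age_ge65 | fl$thrombocytes_lt30
  non_age <- fl$nsaid | fl$cox2 | fl$antiplatelet_any | fl$therapeutic_ac |
    fl$ssri | fl$thrombocytes_lt30
  m <- cbind(
    no_ppi & fl$nsaid & fl$antiplatelet_any,
    no_ppi & fl$nsaid & fl$therapeutic_ac,
    no_ppi & fl$nsaid & fl$corticosteroid_ge10,
    no_ppi & fl$nsaid & fl$ssri,
    no_ppi & fl$nsaid & fl$age_ge65,
    no_ppi & fl$nsaid & fl$thrombocytes_lt30,
    no_ppi & fl$therapeutic_ac & fl$dapt & other,
    no_ppi & fl$therapeutic_ac & fl$low_dose_aspirin & other,
    no_ppi & fl$dapt,
    no_ppi & fl$low_dose_aspirin & fl$corticosteroid_ge10 & fl$age_ge65,
    no_ppi & fl$factor_count >= multi_factor_min,
    fl$ppi_status == "ORAL_ONCE_DAILY" & !non_age)
  lapply(seq_len(n), function(i) which(m[i, ]))
}

flags_to_profile <- function(fl_row) {
  risk_profile_flags(
    nsaid = fl_row$nsaid, cox2 = fl_row$cox2,
    low_dose_aspirin = fl_row$low_dose_aspirin,
    antiplatelet_non_aspirin = fl_row$antiplatelet_non_aspirin,
    therapeutic_ac = fl_row$therapeutic_ac,
    corticosteroid_ge10 = fl_row$corticosteroid_ge10, ssri = fl_row$ssri,
    age_ge65 = fl_row$age_ge65, thrombocytes_lt30 = fl_row$thrombocytes_lt30,
    n_antiplatelet_agents = fl_row$n_antiplatelet_agents)
}

#' Risk profile of a case at a time point
#'
#' Derives the risk-factor flags from prescriptions active at `t` (with
#' on-demand NSAID window gating), the patient's age at `t` and the latest
#' thrombocyte value at or before `t` (no value means the factor is absent).
#'
#' @inheritParams on_demand_exposure
#' @param kb a [ppi_kb] object
#' @param case_id case identifier
#' @param t timestamp within the stay
#' @param replicate_bug_on_demand count on-demand NSAIDs as exposure
#'   unconditionally, reproducing the historical implementation defect
#' @return a `risk_profile`
#' @export
risk_profile <- function(ds, kb, thresholds, case_id, t,
                         replicate_bug_on_demand = FALSE) {
  cs <- case_row(ds, case_id)
  t <- parse_ts(t)
  check_in_stay(cs, t)
  ann <- annotate_cohort(ds, kb, thresholds)
  fl <- snapshot_flags(ann, t, case_id, replicate_bug_on_demand)
  flags_to_profile(fl[1, ])
}

#' PPI prescription status of a case at a time point
#'
#' Any active intravenous PPI dominates, then twice-daily oral, then
#' once-daily oral; intravenous and twice-daily modes are considered
#' appropriate by the inappropriate-PPI alert.
#'
#' @inheritParams risk_profile
#' @return one of `"NONE"`, `"ORAL_ONCE_DAILY"`, `"ORAL_TWICE_DAILY"`,
#'   `"INTRAVENOUS"`
#' @export
ppi_status <- function(ds, kb, case_id, t) {
  cs <- case_row(ds, case_id)
  t <- parse_ts(t)
  check_in_stay(cs, t)
  ann <- annotate_cohort(ds, kb, risk_thresholds())
  snapshot_flags(ann, t, case_id)$ppi_status
}
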