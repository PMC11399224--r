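# Seeded generator of two-period synthetic inpatient cohorts with the
# study-period margins (age and stay distributions, ~33% PPI prescription
# rate, per-factor exposure counts) and injected, labelled missing-PPI /
# inappropriate-PPI incidents. Incidents are injected by construction:
# the generator picks the alert row to realise and emits the minimal
# prescriptions/labs making exactly that predicate true at discharge, so
# ground-truth labels are exact. Non-incident cases are built so that no
# alert predicate holds at any time during the stay (risk constellations
# are covered by a PPI; indication-free PPIs use the appropriate
# twice-daily or intravenous modes).

#' Synthetic cohort configuration
#'
#' Defaults encode the two-period study conditions: a baseline quarter
#' (no decision support; July--September 2020, 5178 cases, incident rates
#' 67/5178 missing and 329/5178 inappropriate) and an intervention quarter
#' (July--September 2021, 5072 cases, 24/5072 and 270/5072), with the
#' intervention period's exposure margins (e.g. 443/5072 NSAID cases,
#' 833/5072 low-dose aspirin, 2240/5072 aged >= 65), mean age about 58.3
#' years, mean stay about 5.4 days, a 33% PPI prescription rate and an 8%
#' consent-refusal rate. Background factor probabilities are inflated by
#' 1/(1 - p_inappropriate) because inappropriate-PPI cases carry no risk
#' factors by construction.
#'
#' @param n_baseline,n_intervention cases per period (0 drops the period)
#' @param baseline_window,intervention_window admission date ranges
#' @param p_missing,p_inappropriate named per-period incident injection rates
#' @param age_bands data frame `lo`, `hi`, `p`: completed-years bands and
#'   sampling weights (uniform within band)
#' @param stay_bands data frame `lo`, `hi`, `p`: stay length in days
#' @param p_female probability of female sex
#' @param factor_probs named per-case probabilities of background exposure
#'   to each risk-factor class
#' @param p_ppi target proportion of cases with any PPI prescription
#' @param p_ppi_iv_share among indication-free appropriate-mode PPIs, the
#'   intravenous (vs twice-daily oral) share
#' @param p_consent_refusal probability a patient refuses general consent
#' @param p_on_demand_nsaid probability that a PPI-carrying case also has an
#'   on-demand NSAID prescription (sparsely administered, so it never meets
#'   the dose-window rule)
#' @param missing_row_weights named sampling weights over the alert rows
#'   used to realise injected missing-PPI incidents
#' @param seed mandatory generator seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(
    n_baseline = 5178, n_intervention = 5072,
    baseline_window = c("2020-07-01", "2020-09-30"),
    intervention_window = c("2021-07-01", "2021-09-30"),
    p_missing = c(baseline = 67 / 5178, intervention = 24 / 5072),
    p_inappropriate = c(baseline = 329 / 5178, intervention = 270 / 5072),
    age_bands = data.frame(lo = c(18, 30, 55, 65), hi = c(30, 55, 65, 90),
                           p = c(0.10614, 0.29205, 0.16017, 0.44164)),
    stay_bands = data.frame(lo = c(0.25, 3, 6, 15), hi = c(3, 6, 15, 24),
                            p = c(0.39707, 0.34022, 0.20492, 0.05779)),
    p_female = 0.51,
    factor_probs = c(nsaid = 443, cox2 = 9, low_dose_aspirin = 833,
                     antiplatelet = 185, anticoagulant = 421,
                     corticosteroid = 45, ssri = 222,
                     thrombocytopenia = 39) / 5072,
    p_ppi = 0.33, p_ppi_iv_share = 0.3,
    p_consent_refusal = 0.08, p_on_demand_nsaid = 0.05,
    missing_row_weights = c(`1` = 2, `2` = 2, `3` = 1, `4` = 1, `5` = 3,
                            `6` = 0.5, `9` = 4, `10` = 1),
    seed = 1L) {
  probs <- c(p_missing, p_inappropriate, age_bands$p, stay_bands$p, p_female,
             factor_probs, p_ppi, p_ppi_iv_share, p_consent_refusal,
             p_on_demand_nsaid)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    ppi_stop("validation_error", "all probabilities must lie in [0, 1]")
  if (any(p_missing + p_inappropriate > 1))
    ppi_stop("validation_error", "incident rates exceed 1 in some period")
  if (is.null(seed) || is.na(seed))
    ppi_stop("validation_error", "a generator seed is mandatory")
  age_bands$p <- age_bands$p / sum(age_bands$p)
  stay_bands$p <- stay_bands$p / sum(stay_bands$p)
  structure(list(
    n_baseline = n_baseline, n_intervention = n_intervention,
    baseline_window = baseline_window, intervention_window = intervention_window,
    p_missing = p_missing, p_inappropriate = p_inappropriate,
    age_bands = age_bands, stay_bands = stay_bands, p_female = p_female,
    factor_probs = factor_probs, p_ppi = p_ppi,
    p_ppi_iv_share = p_ppi_iv_share,
    p_consent_refusal = p_consent_refusal,
    p_on_demand_nsaid = p_on_demand_nsaid,
    missing_row_weights = missing_row_weights, seed = as.integer(seed)
  ), class = "cohort_config")
}

# drug products the generator prescribes, per factor class
SYNTH_DRUGS <- list(
  nsaid = data.frame(drug_id = c("M01AE01", "M01AB05", "M01AE02"),
                     daily_dose = c(1200, 100, 750), freq = c(3, 2, 2)),
  cox2 = data.frame(drug_id = "M01AH01", daily_dose = 200, freq = 2),
  low_dose_aspirin = data.frame(drug_id = "B01AC06", daily_dose = 100, freq = 1),
  antiplatelet = data.frame(drug_id = c("B01AC04", "B01AC24"),
                            daily_dose = c(75, 180), freq = c(1, 2)),
  anticoagulant = data.frame(drug_id = c("B01AF01", "B01AF02", "B01AB05"),
                             daily_dose = c(20, 10, 160), freq = c(1, 2, 2)),
  corticosteroid = data.frame(drug_id = "H02AB07", daily_dose = c(20, 50),
                              freq = c(1, 1)),
  ssri = data.frame(drug_id = c("N06AB10", "N06AB06"),
                    daily_dose = c(10, 50), freq = c(1, 1))
)

DRUG_FACTORS <- c("nsaid", "cox2", "low_dose_aspirin", "antiplatelet",
                  "anticoagulant", "corticosteroid", "ssri")

#' Generate a labelled synthetic cohort
#'
#' Produces a referentially intact [cohort_dataset] for the configured
#' period(s) together with exact ground-truth discharge labels. All injected
#' exposures span the whole stay, so every incident case satisfies its
#' intended alert predicate at discharge (and from admission on), and every
#' non-incident case satisfies no predicate at any time. Identical seeds
#' give byte-identical output.
#'
#' @param config a [cohort_config]
#' @param seed RNG seed; defaults to the seed stored in the configuration
#' @return list with `dataset` (a `cohort_dataset`) and `labels` (data frame
#'   `case_id`, `category`, `alert_no`, `indicated`, `period_label`)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  periods <- list()
  if (config$n_baseline > 0)
    periods$baseline <- list(label = "baseline", n = config$n_baseline,
                             window = config$baseline_window,
                             p_missing = unname(config$p_missing["baseline"]),
                             p_inappropriate = unname(config$p_inappropriate["baseline"]))
  if (config$n_intervention > 0)
    periods$intervention <- list(label = "intervention", n = config$n_intervention,
                                 window = config$intervention_window,
                                 p_missing = unname(config$p_missing["intervention"]),
                                 p_inappropriate = unname(config$p_inappropriate["intervention"]))
  parts <- with_private_seed(seed, lapply(periods, function(p)
    generate_period(config, p)))
  bind <- function(nm) do.call(rbind, lapply(parts, `[[`, nm))
  ds <- cohort_dataset(bind("patients"), bind("cases"), bind("prescriptions"),
                       bind("administrations"), bind("labs"),
                       provenance = list(generator = "ppisentinel synthetic cohort",
                                         seed = seed,
                                         config_hash = config_hash(unclass(config))))
  labels <- bind("labels")
  rownames(labels) <- NULL
  list(dataset = ds, labels = labels)
}

generate_period <- function(cfg, per) {
  n <- per$n
  pfx <- toupper(substr(per$label, 1, 1))
  ab <- cfg$age_bands; sb <- cfg$stay_bands
  band <- sample.int(nrow(ab), n, replace = TRUE, prob = ab$p)
  age <- floor(runif(n, ab$lo[band], ab$hi[band]))
  sband <- sample.int(nrow(sb), n, replace = TRUE, prob = sb$p)
  stay_d <- runif(n, sb$lo[sband], sb$hi[sband])
  w0 <- as.POSIXct(paste(per$window[1], "00:00:00"), tz = "UTC")
  w1 <- as.POSIXct(paste(per$window[2], "23:59:59"), tz = "UTC")
  adm_hours <- floor(runif(n, 0, as.numeric(difftime(w1, w0, units = "hours"))))
  admission <- w0 + hours(adm_hours)
  discharge <- admission + hours(pmax(2, round(stay_d * 24)))
  # birthday placed 30-300 days before admission so completed age is stable
  # across the whole stay (stays are far shorter than the gap to the next
  # birthday)
  birth_date <- as.Date(admission) - round(age * 365.25) - sample(30:300, n, TRUE)
  sex <- ifelse(runif(n) < cfg$p_female, "F", "M")
  consent <- runif(n) >= cfg$p_consent_refusal
  age65 <- age >= 65

  u <- runif(n)
  label <- ifelse(u < per$p_missing, "MISSING",
           ifelse(u < per$p_missing + per$p_inappropriate, "INAPPROPRIATE", "NONE"))

  # background exposure draws, inflated for the factor-free inappropriate
  # cases so period-level margins stay calibrated
  infl <- 1 / (1 - per$p_inappropriate)
  fp <- cfg$factor_probs * infl
  fp[fp > 1] <- 1
  fnames <- c(DRUG_FACTORS, "thrombocytopenia")
  flags <- as.data.frame(lapply(setNames(fnames, fnames), function(f)
    runif(n) < fp[[f]]))
  flags[label == "INAPPROPRIATE", ] <- FALSE

  trigger_any <- function(fl) {
    ap_any <- fl$low_dose_aspirin | fl$antiplatelet
    dapt <- fl$low_dose_aspirin & fl$antiplatelet
    other <- fl$nsaid | fl$cox2 | fl$ssri | age65 | fl$thrombocytopenia
    count <- fl$nsaid + fl$cox2 + ap_any + fl$anticoagulant + fl$ssri +
      age65 + fl$thrombocytopenia
    (fl$nsaid & (ap_any | fl$anticoagulant | fl$corticosteroid | fl$ssri |
                   age65 | fl$thrombocytopenia)) |
      (fl$anticoagulant & dapt & other) |
      (fl$anticoagulant & fl$low_dose_aspirin & other) |
      dapt |
      (fl$low_dose_aspirin & fl$corticosteroid & age65) |
      count >= 4
  }

  # missing-PPI incidents: make sure at least one alert row holds; realise a
  # sampled row when the background draw does not already trigger
  inject_row <- rep(NA_integer_, n)
  need <- which(label == "MISSING" & !trigger_any(flags))
  for (i in need) {
    w <- cfg$missing_row_weights
    feasible <- names(w)[!(names(w) %in% c("5", "10")) | age65[i]]
    row <- as.integer(sample(feasible, 1, prob = w[feasible]))
    inject_row[i] <- row
    if (row %in% 1:6) flags$nsaid[i] <- TRUE
    if (row == 1) {
      if (runif(1) < 0.5) flags$low_dose_aspirin[i] <- TRUE else flags$antiplatelet[i] <- TRUE
    }
    if (row == 2) flags$anticoagulant[i] <- TRUE
    if (row == 3) flags$corticosteroid[i] <- TRUE
    if (row == 4) flags$ssri[i] <- TRUE
    if (row == 6) flags$thrombocytopenia[i] <- TRUE
    if (row == 9) { flags$low_dose_aspirin[i] <- TRUE; flags$antiplatelet[i] <- TRUE }
    if (row == 10) { flags$low_dose_aspirin[i] <- TRUE; flags$corticosteroid[i] <- TRUE }
  }

  triggered <- trigger_any(flags)
  # PPI assignment: incidents of the inappropriate category always carry a
  # once-daily oral PPI; triggered non-incident cases get a covering PPI;
  # further indication-free PPIs are added to hit the target PPI rate, in
  # the appropriate twice-daily/intravenous modes (or once-daily when a
  # drug risk factor documents the indication)
  has_ppi <- label == "INAPPROPRIATE" | (label == "NONE" & triggered)
  eligible <- which(label == "NONE" & !triggered)
  n_extra <- max(0, round(cfg$p_ppi * n) - sum(has_ppi))
  p_extra <- if (length(eligible)) min(1, n_extra / length(eligible)) else 0
  extra <- eligible[runif(length(eligible)) < p_extra]
  has_ppi[extra] <- TRUE
  non_age_drug <- flags$nsaid | flags$cox2 | flags$low_dose_aspirin |
    flags$antiplatelet | flags$anticoagulant | flags$ssri
  ppi_mode <- rep(NA_character_, n)
  ppi_mode[has_ppi] <- "once"
  appr <- intersect(extra, which(!non_age_drug))
  ppi_mode[appr] <- ifelse(runif(length(appr)) < cfg$p_ppi_iv_share, "iv", "bid")
  has_ppi[label == "MISSING"] <- FALSE

  case_id <- sprintf("C%s%05d", pfx, seq_len(n))
  patient_id <- sprintf("P%s%05d", pfx, seq_len(n))
  patients <- data.frame(patient_id = patient_id, birth_date = birth_date,
                         sex = sex, consent = consent)
  cases <- data.frame(case_id = case_id, patient_id = patient_id,
                      admission = admission, discharge = discharge,
                      period_label = per$label)

  # ---- prescriptions, emitted in bulk per factor class -------------------
  rx_parts <- list()
  for (f in DRUG_FACTORS) {
    sel <- which(flags[[f]])
    if (!length(sel)) next
    prod <- SYNTH_DRUGS[[f]]
    pick <- sample.int(nrow(prod), length(sel), replace = TRUE)
    rx_parts[[f]] <- data.frame(
      case_id = case_id[sel], drug_id = prod$drug_id[pick],
      daily_dose = prod$daily_dose[pick], dose_unit = "mg", route = "oral",
      frequency_per_day = prod$freq[pick], schedule = "regular",
      start = admission[sel], end = discharge[sel])
  }
  sel <- which(has_ppi)
  if (length(sel)) {
    mode <- ppi_mode[sel]
    rx_parts$ppi <- data.frame(
      case_id = case_id[sel], drug_id = "A02BC02", daily_dose = 40,
      dose_unit = "mg", route = ifelse(mode == "iv", "iv", "oral"),
      frequency_per_day = ifelse(mode == "bid", 2, 1), schedule = "regular",
      start = admission[sel], end = discharge[sel])
  }
  # on-demand NSAIDs ride along on PPI carriers only, administered at most
  # about once a day -- far below the more-than-six-in-48-h exposure rule
  od <- which(has_ppi & runif(n) < cfg$p_on_demand_nsaid)
  admins <- data.frame(admin_id = character(), rx_id = character(),
                       given_at = as.POSIXct(character(), tz = "UTC"))
  if (length(od)) {
    rx_parts$od <- data.frame(
      case_id = case_id[od], drug_id = "M01AE01", daily_dose = 400,
      dose_unit = "mg", route = "oral", frequency_per_day = 1,
      schedule = "on_demand", start = admission[od], end = discharge[od])
    ad_list <- lapply(seq_along(od), function(j) {
      i <- od[j]
      max_doses <- max(0, floor(as.numeric(difftime(discharge[i], admission[i],
                                                    units = "days"))))
      k <- min(max_doses, rpois(1, max_doses * 0.4))
      if (!k) return(NULL)
      data.frame(case_idx = j,
                 given_at = admission[i] + hours(24 * (seq_len(k) - 1) +
                                                   sample(1:6, k, TRUE)))
    })
    ad <- do.call(rbind, ad_list)
    if (!is.null(ad)) admins <- data.frame(admin_id = NA_character_,
                                           rx_id = ad$case_idx,
                                           given_at = ad$given_at)
  }
  rx <- do.call(rbind, rx_parts)
  if (is.null(rx)) {
    rx <- data.frame(case_id = character(), drug_id = character(),
                     daily_dose = numeric(), dose_unit = character(),
                     route = character(), frequency_per_day = numeric(),
                     schedule = character(),
                     start = as.POSIXct(character(), tz = "UTC"),
                     end = as.POSIXct(character(), tz = "UTC"))
  }
  rownames(rx) <- NULL
  rx <- cbind(rx_id = sprintf("R%s%06d", pfx, seq_len(nrow(rx))), rx)
  # administrations referenced the j-th on-demand prescription; resolve ids
  if (nrow(admins)) {
    od_rx_ids <- rx$rx_id[rx$schedule == "on_demand"]
    admins$rx_id <- od_rx_ids[as.integer(admins$rx_id)]
    admins$admin_id <- sprintf("AD%s%06d", pfx, seq_len(nrow(admins)))
  }

  # ---- labs --------------------------------------------------------------
  tc <- which(flags$thrombocytopenia)
  normal <- which(!flags$thrombocytopenia & runif(n) < 0.6)
  labs <- data.frame(
    case_id = case_id[c(tc, normal)], analyte = "thrombocytes",
    value = c(round(runif(length(tc), 5, 25), 1),
              round(runif(length(normal), 150, 400))),
    unit = "G/L",
    measured_at = c(admission[tc] + hours(1), admission[normal] + hours(1)))

  labels <- data.frame(case_id = case_id, category = label,
                       alert_no = inject_row,
                       indicated = label == "NONE" & triggered,
                       period_label = per$label)
  list(patients = patients, cases = cases, prescriptions = rx,
       administrations = admins, labs = labs, labels = labels)
}

#' Per-period exposure margins of a cohort
#'
#' Counts, per period, the cases carrying each risk-factor exposure class at
#' least once during the stay (regular prescriptions classified through the
#' knowledge base; any thrombocyte value below the threshold; age at
#' admission), mirroring the per-case characteristics table the generator
#' is calibrated against.
#'
#' @inheritParams run_surveillance
#' @param include_excluded count consent-refused/minor cases too (default
#'   TRUE: margins are properties of the generated cohort)
#' @return data frame: one row per period, columns `n_cases`, one count per
#'   factor class, `age_ge65`, `thrombocytes_lt30`, `ppi`, and `mean_age`
#' @export
exposure_margins <- function(ds, kb, thresholds = risk_thresholds(),
                             include_excluded = TRUE) {
  ann <- annotate_cohort(ds, kb, thresholds)
  cs <- ds$cases
  if (!include_excluded) cs <- cs[!cs$excluded, , drop = FALSE]
  rx <- ann$rx[!ann$rx$on_demand, , drop = FALSE]
  birth <- ds$patients$birth_date[match(cs$patient_id, ds$patients$patient_id)]
  one <- function(per) {
    ids <- cs$case_id[cs$period_label == per]
    sub <- rx[rx$case_id %in% ids, , drop = FALSE]
    cnt <- function(col) length(unique(sub$case_id[sub[[col]]]))
    lb <- ds$labs[ds$labs$case_id %in% ids & ds$labs$analyte == "thrombocytes" &
                    ds$labs$value < thresholds$thrombocyte_max, , drop = FALSE]
    sel <- cs$period_label == per
    ages <- age_at(birth[sel], cs$admission[sel])
    data.frame(period_label = per, n_cases = length(ids),
               nsaid = cnt("f_nsaid"), cox2 = cnt("f_cox2"),
               low_dose_aspirin = cnt("f_lda"),
               antiplatelet_non_aspirin = cnt("f_ap"),
               therapeutic_ac = cnt("f_ac"),
               corticosteroid_ge10 = cnt("f_cs10"), ssri = cnt("f_ssri"),
               age_ge65 = sum(ages >= thresholds$age_min),
               thrombocytes_lt30 = length(unique(lb$case_id)),
               ppi = cnt("f_ppi"), mean_age = mean(ages))
  }
  out <- do.call(rbind, lapply(unique(cs$period_label), one))
  rownames(out) <- NULL
  out
}

#' Write a labelled cohort to a directory
#'
#' Emits the five cohort CSV tables plus `labels.csv` and a provenance
#' manifest (`manifest.json`: package version, generator seed, configuration
#' hash, creation time).
#'
#' @param ds a `cohort_dataset`
#' @param labels the ground-truth label table from [generate_cohort]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(ds, labels, dir) {
  write_cohort_tables(ds, dir)
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE, na = "")
  manifest <- list(
    tool = "ppisentinel",
    version = as.character(utils::packageVersion("ppisentinel")),
    seed = ds$provenance$seed,
    config_hash = ds$provenance$config_hash,
    created_at = format_ts(Sys.time()))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_labels <- function(dir) {
  path <- file.path(dir, "labels.csv")
  if (!file.exists(path)) ppi_stop("io_error", "labels file not found: %s", path)
  out <- read.csv(path, colClasses = "character")
  out$alert_no <- suppressWarnings(as.integer(out$alert_no))
  out$indicated <- parse_flag(out$indicated)
  out
}
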