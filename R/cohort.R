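# Longitudinal data model: patients, hospital cases, prescriptions,
# administrations and laboratory results, with CSV readers/writers and
# time-point query helpers. All intervals are half-open [start, end);
# timestamps are ISO-8601 in one implicit timezone per dataset.

COHORT_SCHEMAS <- list(
  patients = c("patient_id", "birth_date", "sex", "consent"),
  cases = c("case_id", "patient_id", "admission", "discharge", "period_label"),
  prescriptions = c("rx_id", "case_id", "drug_id", "daily_dose", "dose_unit",
                    "route", "frequency_per_day", "schedule", "start", "end"),
  administrations = c("admin_id", "rx_id", "given_at"),
  labs = c("case_id", "analyte", "value", "unit", "measured_at")
)

#' Assemble and validate a cohort dataset
#'
#' Bundles the five event tables into one validated object. Validation
#' enforces unique identifiers, full referential integrity (every
#' prescription resolves to a case, every case to a patient, every
#' administration to a prescription), temporal sanity (admission before
#' discharge, prescription start before end, administrations within the
#' enclosing stay) and flags cases excluded from analysis: patients who
#' refused general consent and patients younger than 18 at admission,
#' mirroring the surveillance system's own exclusions.
#'
#' @param patients data frame with columns
#'   `patient_id, birth_date, sex, consent`
#' @param cases data frame with columns
#'   `case_id, patient_id, admission, discharge, period_label` (empty
#'   discharge = still open)
#' @param prescriptions data frame with columns `rx_id, case_id, drug_id,
#'   daily_dose, dose_unit, route, frequency_per_day, schedule, start, end`
#' @param administrations data frame with columns `admin_id, rx_id, given_at`
#' @param labs data frame with columns
#'   `case_id, analyte, value, unit, measured_at`
#' @param provenance free-form list recorded with the dataset (source files,
#'   knowledge-base version, generator seed)
#' @return object of class `cohort_dataset`; cases gain logical `excluded`
#'   and character `exclusion_reason` columns
#' @export
cohort_dataset <- function(patients, cases, prescriptions = NULL,
                           administrations = NULL, labs = NULL,
                           provenance = list()) {
  empty <- function(cols) as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  prescriptions <- prescriptions %||% empty(COHORT_SCHEMAS$prescriptions)
  administrations <- administrations %||% empty(COHORT_SCHEMAS$administrations)
  labs <- labs %||% empty(COHORT_SCHEMAS$labs)
  tabs <- list(patients = patients, cases = cases, prescriptions = prescriptions,
               administrations = administrations, labs = labs)
  for (nm in names(tabs)) {
    missing_cols <- setdiff(COHORT_SCHEMAS[[nm]], names(tabs[[nm]]))
    if (length(missing_cols))
      ppi_stop("load_error", "%s: missing column(s) %s", nm,
               paste(missing_cols, collapse = ", "))
    tabs[[nm]] <- as.data.frame(tabs[[nm]], stringsAsFactors = FALSE)
    rownames(tabs[[nm]]) <- NULL
  }
  p <- tabs$patients; cs <- tabs$cases; rx <- tabs$prescriptions
  ad <- tabs$administrations; lb <- tabs$labs

  p$patient_id <- as.character(p$patient_id)
  p$birth_date <- parse_date(p$birth_date)
  p$sex <- as.character(p$sex)
  p$consent <- parse_flag(p$consent)
  cs$case_id <- as.character(cs$case_id)
  cs$patient_id <- as.character(cs$patient_id)
  cs$admission <- parse_ts(cs$admission)
  cs$discharge <- parse_ts(cs$discharge)
  cs$period_label <- as.character(cs$period_label)
  rx$rx_id <- as.character(rx$rx_id)
  rx$case_id <- as.character(rx$case_id)
  rx$drug_id <- as.character(rx$drug_id)
  rx$daily_dose <- as.numeric(rx$daily_dose)
  rx$dose_unit <- as.character(rx$dose_unit)
  rx$route <- as.character(rx$route)
  rx$frequency_per_day <- as.numeric(rx$frequency_per_day)
  rx$schedule <- as.character(rx$schedule)
  rx$start <- parse_ts(rx$start)
  rx$end <- parse_ts(rx$end)
  ad$admin_id <- as.character(ad$admin_id)
  ad$rx_id <- as.character(ad$rx_id)
  ad$given_at <- parse_ts(ad$given_at)
  lb$case_id <- as.character(lb$case_id)
  lb$analyte <- as.character(lb$analyte)
  lb$value <- as.numeric(lb$value)
  lb$unit <- as.character(lb$unit)
  lb$measured_at <- parse_ts(lb$measured_at)

  problems <- character()
  bad_rows <- function(tab, idx, why) {
    if (any(idx)) sprintf("%s row %s: %s", tab, which(idx), why) else character()
  }
  problems <- c(problems,
    bad_rows("patients", duplicated(p$patient_id), "duplicate patient_id"),
    bad_rows("patients", is.na(p$birth_date), "unparseable birth_date"),
    bad_rows("patients", !p$sex %in% c("M", "F"), "sex must be M or F"),
    bad_rows("cases", duplicated(cs$case_id), "duplicate case_id"),
    bad_rows("cases", !cs$patient_id %in% p$patient_id, "unknown patient_id"),
    bad_rows("cases", is.na(cs$admission), "unparseable admission"),
    bad_rows("cases", !is.na(cs$discharge) & cs$discharge <= cs$admission,
             "discharge not after admission"),
    bad_rows("prescriptions", duplicated(rx$rx_id), "duplicate rx_id"),
    bad_rows("prescriptions", !rx$case_id %in% cs$case_id, "unknown case_id"),
    bad_rows("prescriptions", is.na(rx$start), "unparseable start"),
    bad_rows("prescriptions", !is.na(rx$end) & rx$end <= rx$start,
             "end not after start"),
    bad_rows("prescriptions", !is.na(rx$daily_dose) & rx$daily_dose < 0,
             "negative daily_dose"),
    bad_rows("prescriptions", !rx$schedule %in% c("regular", "on_demand"),
             "schedule must be regular or on_demand"),
    bad_rows("prescriptions", rx$schedule == "regular" &
               (is.na(rx$frequency_per_day) | rx$frequency_per_day < 1),
             "regular schedule needs frequency_per_day >= 1"),
    bad_rows("administrations", duplicated(ad$admin_id), "duplicate admin_id"),
    bad_rows("administrations", !ad$rx_id %in% rx$rx_id, "unknown rx_id"),
    bad_rows("administrations", is.na(ad$given_at), "unparseable given_at"),
    bad_rows("labs", !lb$case_id %in% cs$case_id, "unknown case_id"),
    bad_rows("labs", !is.na(lb$value) & lb$value < 0, "negative value")
  )
  # administrations must fall within the enclosing case's stay
  if (nrow(ad)) {
    rx_case <- setNames(rx$case_id, rx$rx_id)
    ci <- match(rx_case[ad$rx_id], cs$case_id)
    adm <- cs$admission[ci]; dis <- cs$discharge[ci]
    outside <- !is.na(ad$given_at) & !is.na(adm) &
      (ad$given_at < adm | (!is.na(dis) & ad$given_at >= dis))
    outside[is.na(outside)] <- FALSE
    problems <- c(problems, bad_rows("administrations", outside,
                                     "given_at outside the case's stay"))
  }
  if (length(problems))
    ppi_stop("load_error", "cohort validation failed:\n%s",
             paste(problems, collapse = "\n"))

  # analysis exclusions: refused consent, minor at admission
  consent_by_patient <- setNames(p$consent, p$patient_id)
  birth_by_patient <- setNames(p$birth_date, p$patient_id)
  no_consent <- !consent_by_patient[cs$patient_id]
  minor <- age_at(as.Date(birth_by_patient[cs$patient_id],
                          origin = "1970-01-01"), cs$admission) < 18
  cs$excluded <- no_consent | minor
  cs$exclusion_reason <- ifelse(minor, "age_lt_18",
                         ifelse(no_consent, "no_consent", NA_character_))
  structure(list(patients = p, cases = cs, prescriptions = rx,
                 administrations = ad, labs = lb, provenance = provenance),
            class = "cohort_dataset")
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d patients, %d cases (%d excluded), %d prescriptions, %d administrations, %d labs\n",
    nrow(x$patients), nrow(x$cases), sum(x$cases$excluded),
    nrow(x$prescriptions), nrow(x$administrations), nrow(x$labs)))
  if (length(x$provenance))
    cat("provenance:", paste(names(x$provenance),
                             vapply(x$provenance, function(v) paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Load a cohort from CSV files
#'
#' Reads the five documented CSV tables (`patients.csv`, `cases.csv`,
#' `prescriptions.csv`, `administrations.csv`, `labs.csv`; UTF-8, RFC-4180,
#' empty string = missing) from a directory and validates them with
#' [cohort_dataset]. Rows violating the schema or referential integrity
#' abort the load with a line-numbered report.
#'
#' @param dir directory containing the five CSV files
#' @return a validated `cohort_dataset`
#' @export
load_cohort <- function(dir) {
  if (!dir.exists(dir)) ppi_stop("io_error", "cohort directory not found: %s", dir)
  read_tab <- function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) ppi_stop("load_error", "missing cohort file: %s", path)
    read.csv(path, colClasses = "character", check.names = TRUE)
  }
  tabs <- lapply(setNames(names(COHORT_SCHEMAS), names(COHORT_SCHEMAS)), read_tab)
  cohort_dataset(tabs$patients, tabs$cases, tabs$prescriptions,
                 tabs$administrations, tabs$labs,
                 provenance = list(source = normalizePath(dir)))
}

# write the five CSV tables; shared by write_cohort()
write_cohort_tables <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (nm in names(df)) {
      if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_ts(df[[nm]])
      if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
      if (is.logical(df[[nm]])) df[[nm]] <- ifelse(df[[nm]], "true", "false")
    }
    df
  }
  for (nm in names(COHORT_SCHEMAS))
    write.csv(fmt(ds[[nm]][, COHORT_SCHEMAS[[nm]], drop = FALSE]),
              file.path(dir, paste0(nm, ".csv")), row.names = FALSE, na = "")
  invisible(dir)
}

#' Completed age in years at a time point
#'
#' Whole completed years, with the birthday itself counting as attained age.
#' Vectorised over both arguments.
#'
#' @param birth_date `Date` vector (or a patient row with `birth_date`)
#' @param t timestamp(s) at which to evaluate
#' @return integer years
#' @export
age_at <- function(birth_date, t) {
  if (is.data.frame(birth_date)) birth_date <- birth_date$birth_date
  birth_date <- as.Date(birth_date)
  d <- as.Date(as.POSIXct(t, tz = "UTC"), tz = "UTC")
  if (any(!is.na(d) & !is.na(birth_date) & d < birth_date))
    ppi_stop("domain_error", "time point precedes birth date")
  by <- as.integer(format(birth_date, "%Y")); bm <- as.integer(format(birth_date, "%m"))
  bd <- as.integer(format(birth_date, "%d"))
  ty <- as.integer(format(d, "%Y")); tm <- as.integer(format(d, "%m"))
  td <- as.integer(format(d, "%d"))
  ty - by - as.integer(tm < bm | (tm == bm & td < bd))
}

case_row <- function(ds, case_id) {
  i <- match(case_id, ds$cases$case_id)
  if (is.na(i)) ppi_stop("domain_error", "unknown case: %s", case_id)
  ds$cases[i, ]
}

check_in_stay <- function(cs, t) {
  if (t < cs$admission || (!is.na(cs$discharge) && t > cs$discharge))
    ppi_stop("domain_error", "time point outside the stay of case %s", cs$case_id)
}

#' Prescriptions active at a time point
#'
#' Regular prescriptions are active on the half-open interval
#' `[start, end)` (an open end means still running). On-demand
#' prescriptions are returned with `on_demand = TRUE`; whether they count as
#' risk exposure is decided by the rule engine's trailing-window dose count,
#' not here.
#'
#' @param ds a `cohort_dataset`
#' @param case_id case identifier
#' @param t timestamp within the case's stay
#' @param min_exposure_hours prescriptions active for less than this many
#'   hours at `t` are not returned (default 0)
#' @return data frame of prescription rows plus an `on_demand` column
#' @export
active_prescriptions <- function(ds, case_id, t, min_exposure_hours = 0) {
  cs <- case_row(ds, case_id)
  t <- parse_ts(t)
  check_in_stay(cs, t)
  rx <- ds$prescriptions[ds$prescriptions$case_id == case_id, , drop = FALSE]
  keep <- rx$start <= t - hours(min_exposure_hours) & (is.na(rx$end) | t < rx$end)
  out <- rx[keep, , drop = FALSE]
  out$on_demand <- out$schedule == "on_demand"
  rownames(out) <- NULL
  out
}

#' Most recent laboratory result at or before a time point
#'
#' @inheritParams active_prescriptions
#' @param analyte analyte name, e.g. `"thrombocytes"`
#' @return a one-row data frame, or `NULL` when no result exists (the
#'   corresponding risk factor is then absent)
#' @export
latest_lab <- function(ds, case_id, analyte, t) {
  cs <- case_row(ds, case_id)
  t <- parse_ts(t)
  check_in_stay(cs, t)
  lb <- ds$labs[ds$labs$case_id == case_id & ds$labs$analyte == analyte &
                  ds$labs$measured_at <= t, , drop = FALSE]
  if (!nrow(lb)) return(NULL)
  lb[which.max(as.numeric(lb$measured_at)), , drop = FALSE]
}
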