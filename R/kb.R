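# Drug-class knowledge base: config-driven classification of drug products
# into the risk-relevant classes used by the alert rules, with dose-dependent
# qualifiers (low-dose aspirin, therapeutic anticoagulation, prednisone-
# equivalent corticosteroid dose).

KB_BASE_CLASSES <- c("NSAID", "COX2", "ASPIRIN", "ANTIPLATELET_NON_ASPIRIN",
                     "ANTICOAGULANT", "CORTICOSTEROID", "SSRI", "PPI", "OTHER")

KB_RISK_CLASSES <- setdiff(KB_BASE_CLASSES, c("PPI", "OTHER"))

#' Construct and validate a drug-class knowledge base
#'
#' The knowledge base maps ATC codes (exact or prefix, longest match wins) to
#' base drug classes, carries prednisone-equivalence potency factors for
#' corticosteroids, per-agent minimum daily doses counted as therapeutic
#' anticoagulation, and the low-dose aspirin cut-off. All of these are
#' hospital-consensus parameters, so everything is configuration, not code.
#'
#' @param classes named character vector: ATC code or prefix -> base class
#'   tag (one of `r paste(KB_BASE_CLASSES, collapse = ", ")`)
#' @param aliases named character vector: lower-case drug name -> ATC code
#' @param corticosteroid_potency named numeric: ATC code -> prednisone
#'   equivalence factor (mg prednisone per mg drug), all > 0
#' @param anticoagulant_thresholds named numeric: ATC code -> minimum daily
#'   dose (native unit) counted as therapeutic
#' @param aspirin_low_dose_max mg/day; aspirin at or below this daily dose is
#'   "low dose" (antiplatelet use), above it plain antiplatelet therapy
#' @param version free-text version tag recorded in manifests
#' @return object of class `ppi_kb`
#' @export
ppi_kb <- function(classes, aliases = character(), corticosteroid_potency = numeric(),
                   anticoagulant_thresholds = numeric(), aspirin_low_dose_max = 325,
                   version = "unversioned") {
  classes <- unlist(classes)
  aliases <- unlist(aliases)
  corticosteroid_potency <- unlist(corticosteroid_potency)
  anticoagulant_thresholds <- unlist(anticoagulant_thresholds)
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    ppi_stop("kb_config_error", "every class entry must be named by an ATC code or prefix")
  if (anyDuplicated(names(classes)))
    ppi_stop("kb_config_error", "duplicate class entries for code(s): %s",
             paste(unique(names(classes)[duplicated(names(classes))]), collapse = ", "))
  bad <- setdiff(unique(classes), KB_BASE_CLASSES)
  if (length(bad))
    ppi_stop("kb_config_error", "unknown base class tag(s): %s", paste(bad, collapse = ", "))
  if (length(corticosteroid_potency) && any(corticosteroid_potency <= 0))
    ppi_stop("kb_config_error", "corticosteroid potency factors must be > 0")
  if (length(anticoagulant_thresholds) && any(anticoagulant_thresholds <= 0))
    ppi_stop("kb_config_error", "anticoagulant thresholds must be > 0")
  if (!is_scalar_number(aspirin_low_dose_max) || aspirin_low_dose_max <= 0)
    ppi_stop("kb_config_error", "aspirin_low_dose_max must be a positive number")
  kb <- structure(list(
    version = as.character(version),
    classes = classes[order(names(classes))],
    aliases = setNames(as.character(aliases), tolower(names(aliases))),
    corticosteroid_potency = corticosteroid_potency,
    anticoagulant_thresholds = anticoagulant_thresholds,
    aspirin_low_dose_max = as.numeric(aspirin_low_dose_max)
  ), class = "ppi_kb")
  # every potency entry must itself classify as a corticosteroid; same for AC
  for (code in names(kb$corticosteroid_potency))
    if (classify_drug(kb, code) != "CORTICOSTEROID")
      ppi_stop("kb_config_error", "potency entry %s is not a corticosteroid", code)
  for (code in names(kb$anticoagulant_thresholds))
    if (classify_drug(kb, code) != "ANTICOAGULANT")
      ppi_stop("kb_config_error", "anticoagulant threshold entry %s is not an anticoagulant", code)
  kb
}

#' Risk thresholds of the alert rules
#'
#' Numeric cut-offs shared by all alert predicates. Defaults encode the rule
#' set as deployed: corticosteroids count from 10 mg prednisone equivalent per
#' day, age from 65 years, thrombocytopenia below 30 G/L, the multi-factor
#' alert from 4 concurrent risk factors, and an on-demand NSAID counts as
#' exposure only when administered more than six times (i.e. at least 7) in
#' the trailing 48 hours.
#'
#' @param corticosteroid_min_prednisone_eq mg prednisone equivalent per day
#' @param age_min years
#' @param thrombocyte_max G/L (exclusive upper bound for the risk flag)
#' @param multi_factor_min count of concurrent risk factors
#' @param on_demand_min_doses administrations within the window ("more than
#'   six" = 7)
#' @param on_demand_window_hours trailing window length in hours
#' @param min_exposure_hours minimum time a prescription must have been active
#'   before it counts as a risk factor (0 = immediately)
#' @return object of class `ppi_thresholds`
#' @export
risk_thresholds <- function(corticosteroid_min_prednisone_eq = 10, age_min = 65,
                            thrombocyte_max = 30, multi_factor_min = 4,
                            on_demand_min_doses = 7, on_demand_window_hours = 48,
                            min_exposure_hours = 0) {
  vals <- list(corticosteroid_min_prednisone_eq = corticosteroid_min_prednisone_eq,
               age_min = age_min, thrombocyte_max = thrombocyte_max,
               multi_factor_min = multi_factor_min,
               on_demand_min_doses = on_demand_min_doses,
               on_demand_window_hours = on_demand_window_hours,
               min_exposure_hours = min_exposure_hours)
  for (nm in setdiff(names(vals), "min_exposure_hours"))
    if (!is_scalar_number(vals[[nm]]) || vals[[nm]] <= 0)
      ppi_stop("threshold_error", "%s must be a positive number", nm)
  if (!is_scalar_number(min_exposure_hours) || min_exposure_hours < 0)
    ppi_stop("threshold_error", "min_exposure_hours must be >= 0")
  if (vals$on_demand_min_doses < 1)
    ppi_stop("threshold_error", "on_demand_min_doses must be >= 1")
  structure(lapply(vals, as.numeric), class = "ppi_thresholds")
}

#' Classify a drug identifier into its base class
#'
#' Resolves free-text aliases through the knowledge base's explicit alias
#' table (never fuzzily), then matches ATC codes by longest prefix.
#'
#' @param kb a [ppi_kb] object
#' @param drug_id ATC-code-like string or an aliased drug name
#' @return one base class tag; `"OTHER"` when nothing matches
#' @export
classify_drug <- function(kb, drug_id) {
  stopifnot(inherits(kb, "ppi_kb"))
  if (length(drug_id) != 1L || is.na(drug_id) || !is.character(drug_id) || !nzchar(trimws(drug_id)))
    ppi_stop("validation_error", "drug_id must be a single non-empty string")
  code <- resolve_drug_code(kb, drug_id)
  match_class(kb, code)
}

resolve_drug_code <- function(kb, drug_id) {
  drug_id <- trimws(drug_id)
  alias <- kb$aliases[tolower(drug_id)]
  if (length(alias) == 1L && !is.na(alias)) toupper(alias) else toupper(drug_id)
}

# longest-prefix match of `code` against names(kb$classes); "OTHER" if none
match_class <- function(kb, code) {
  keys <- names(kb$classes)
  hits <- keys[startsWith(code, keys)]
  if (!length(hits)) return("OTHER")
  unname(kb$classes[hits[which.max(nchar(hits))]])
}

lookup_prefix <- function(tbl, code) {
  keys <- names(tbl)
  hits <- keys[startsWith(code, keys)]
  if (!length(hits)) return(NA_real_)
  unname(tbl[hits[which.max(nchar(hits))]])
}

#' Prednisone-equivalent daily dose of a corticosteroid
#'
#' Multiplies the daily dose by the agent's equipotency factor from the
#' knowledge base (e.g. 0.75 mg dexamethasone is equipotent to 5 mg
#' prednisone, factor 20/3). Linear in dose.
#'
#' @inheritParams classify_drug
#' @param daily_dose mg/day
#' @return mg prednisone equivalent per day
#' @export
prednisone_equivalent <- function(kb, drug_id, daily_dose) {
  if (classify_drug(kb, drug_id) != "CORTICOSTEROID")
    ppi_stop("domain_error", "%s is not a corticosteroid in this knowledge base", drug_id)
  code <- resolve_drug_code(kb, drug_id)
  factor <- lookup_prefix(kb$corticosteroid_potency, code)
  if (is.na(factor))
    ppi_stop("kb_config_error", "no prednisone-equivalence factor configured for %s", drug_id)
  daily_dose * factor
}

#' Risk-relevant effective classes of a prescription
#'
#' Applies the dose-dependent qualifiers on top of the base class: aspirin
#' splits into low-dose aspirin vs plain antiplatelet therapy at the
#' configured cut-off; anticoagulants count only at or above their per-agent
#' therapeutic daily dose; corticosteroids count from the configured
#' prednisone-equivalent dose. NSAID, COX2, SSRI and PPI pass through.
#'
#' @inheritParams prednisone_equivalent
#' @param thresholds a [risk_thresholds] object
#' @param daily_dose daily dose in the drug's native unit, >= 0
#' @param route `"oral"`, `"iv"` or `"other"` (carried for PPI mode logic;
#'   does not change class membership)
#' @return character vector (possibly empty) of qualifiers among
#'   `NSAID, COX2, LOW_DOSE_ASPIRIN, ANTIPLATELET, THERAPEUTIC_AC,
#'   CORTICOSTEROID_GE10, SSRI, PPI`
#' @export
effective_classes <- function(kb, thresholds, drug_id, daily_dose, route = "oral") {
  stopifnot(inherits(thresholds, "ppi_thresholds"))
  if (!is_scalar_number(daily_dose) || daily_dose < 0)
    ppi_stop("validation_error", "daily_dose must be a single number >= 0")
  base <- classify_drug(kb, drug_id)
  code <- resolve_drug_code(kb, drug_id)
  switch(base,
    ASPIRIN = if (daily_dose <= kb$aspirin_low_dose_max) "LOW_DOSE_ASPIRIN" else "ANTIPLATELET",
    ANTIPLATELET_NON_ASPIRIN = "ANTIPLATELET",
    ANTICOAGULANT = {
      thr <- lookup_prefix(kb$anticoagulant_thresholds, code)
      if (is.na(thr))
        ppi_stop("kb_config_error", "no therapeutic-dose threshold configured for anticoagulant %s", drug_id)
      if (daily_dose >= thr) "THERAPEUTIC_AC" else character()
    },
    CORTICOSTEROID = {
      if (prednisone_equivalent(kb, drug_id, daily_dose) >=
          thresholds$corticosteroid_min_prednisone_eq) "CORTICOSTEROID_GE10" else character()
    },
    NSAID = "NSAID", COX2 = "COX2", SSRI = "SSRI", PPI = "PPI",
    character()
  )
}

#' Load / save a knowledge base as YAML
#'
#' The on-disk document has sections `version`, `classes`, `aliases`,
#' `corticosteroid_potency`, `anticoagulant_thresholds` and `limits`
#' (`aspirin_low_dose_max`); it is schema-validated on load by [ppi_kb].
#'
#' @param path YAML file path
#' @return `kb_load` returns a validated `ppi_kb`; `kb_save` its path,
#'   invisibly
#' @export
kb_load <- function(path) {
  if (!file.exists(path)) ppi_stop("io_error", "knowledge base file not found: %s", path)
  doc <- yaml::read_yaml(path)
  ppi_kb(classes = doc$classes,
         aliases = doc$aliases %||% character(),
         corticosteroid_potency = doc$corticosteroid_potency %||% numeric(),
         anticoagulant_thresholds = doc$anticoagulant_thresholds %||% numeric(),
         aspirin_low_dose_max = doc$limits$aspirin_low_dose_max %||% 325,
         version = doc$version %||% "unversioned")
}

#' @rdname kb_load
#' @param kb a [ppi_kb] object
#' @export
kb_save <- function(kb, path) {
  stopifnot(inherits(kb, "ppi_kb"))
  doc <- list(version = kb$version,
              classes = as.list(kb$classes),
              aliases = as.list(kb$aliases),
              corticosteroid_potency = as.list(kb$corticosteroid_potency),
              anticoagulant_thresholds = as.list(kb$anticoagulant_thresholds),
              limits = list(aspirin_low_dose_max = kb$aspirin_low_dose_max))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The packaged default knowledge base
#'
#' Loads the versioned default knowledge base shipped with the package
#' (`inst/extdata/ppi_kb_default.yaml`). Its class membership follows ATC:
#' NSAIDs under M01A (with the coxibs M01AH carried as a separate COX2
#' class), aspirin B01AC06/N02BA01, other antiplatelets under B01AC,
#' anticoagulants under B01AA/AB/AE/AF, corticosteroids under H02AB, SSRIs
#' under N06AB and PPIs under A02BC. Potency factors and therapeutic-dose
#' thresholds are hospital-consensus defaults and can be replaced wholesale
#' by loading a different YAML document.
#'
#' @return a validated `ppi_kb`
#' @export
default_kb <- function() {
  kb_load(system.file("extdata", "ppi_kb_default.yaml", package = "ppisentinel",
                      mustWork = TRUE))
}
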