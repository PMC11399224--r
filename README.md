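# ppisentinel

Rule-based surveillance of proton pump inhibitor (PPI) gastroprotection in
longitudinal inpatient medication records — for hospital pharmacists,
medication-safety teams and CDSS developers who want a tested, fully
configurable implementation of a PPI e-algorithm together with the
machinery to evaluate it.

The engine screens every in-hospital case, hourly, for two complementary
prescribing problems:

* **Missing gastroprotection** (alerts 1–11): no PPI despite a
  drug-related gastrointestinal bleeding risk — NSAID plus another risk
  factor, therapeutic anticoagulation plus (dual) antiplatelet therapy,
  low-dose aspirin plus corticosteroid in patients ≥ 65 years, or ≥ 4
  concurrent risk factors. Lower-numbered alerts suppress higher-numbered
  ones, so each case carries at most one open missing-PPI alert.
* **Potentially inappropriate PPI** (alert 12): a once-daily oral PPI with
  no drug-related risk factor (age alone excluded); intravenous and
  twice-daily prescriptions count as appropriate.

The countable risk factors are NSAID, COX2 inhibitor, antiplatelet therapy
(one factor regardless of agent count), therapeutic-dose anticoagulation,
SSRI, age ≥ 65 y and thrombocytes < 30 G/L. Dose-dependent qualifiers —
low-dose aspirin ≤ 325 mg/d, per-agent therapeutic anticoagulation
cut-offs, corticosteroid ≥ 10 mg prednisone equivalent/d — come from a
YAML knowledge base keyed by ATC prefixes (longest match wins). An
on-demand NSAID counts as exposure only when administered more than six
times in the trailing 48 h; the historical implementation defect that let
rarely-used on-demand NSAIDs suppress alert 12 can be replicated on
purpose (`replicate_bug_on_demand = TRUE`) to quantify its effect.

Alerts live through `PENDING → INTERVENTION / NOT_RELEVANT / RESOLVED`
(automatic termination when the trigger lapses or the case is discharged),
with the pharmacist step modelled as a seeded stochastic triage policy.
Evaluation utilities compute per-category sensitivity/specificity against
a reference standard, triage/acceptance accounting, and the before/after
incidence comparison `(rate_a − rate_b)/rate_a × 100` with a
two-proportion chi-square. A seeded synthetic cohort generator produces
two-period cohorts with calibrated margins and exact ground-truth labels,
so the whole pipeline is testable without real EHR data.

## Worked example

```r
library(ppisentinel)
kb  <- default_kb()
thr <- risk_thresholds()

classify_drug(kb, "ibuprofen")
#> [1] "NSAID"
effective_classes(kb, thr, "dexamethasone", 1.5)   # 10 mg prednisone eq.
#> [1] "CORTICOSTEROID_GE10"

cfg <- cohort_config(n_baseline = 0, n_intervention = 300,
                     p_missing = c(baseline = 0, intervention = 0.05),
                     p_inappropriate = c(baseline = 0, intervention = 0.10),
                     seed = 42)
gen <- generate_cohort(cfg)
gen$dataset
#> <cohort_dataset> 300 patients, 300 cases (24 excluded), 251 prescriptions, 0 administrations, 180 labs

log <- run_surveillance(gen$dataset, kb, thr, triage_policy(seed = 1))
triage_summary(log)
#> Alert triage summary
#>   total alerts: 45 | interventions: 26 | acceptance rate: 42.3%
#>   MISSING_PPI       alerts   14 | intervention    9 | not relevant    5 | auto-resolved    0 | accepted 44%
#>   INAPPROPRIATE_PPI alerts   31 | intervention   17 | not relevant   12 | auto-resolved    2 | accepted 41%

included <- gen$dataset$cases$case_id[!gen$dataset$cases$excluded]
ref <- gen$labels[gen$labels$case_id %in% included, c("case_id", "category")]
diagnostic_performance(log, ref)
#>        category tp fp  tn fn sensitivity specificity
#> 1       MISSING 14  0 262  0           1           1
#> 2 INAPPROPRIATE 31  0 245  0           1           1

compare_incidence(67, 5178, 24, 5072)
#> Incidence comparison: 67/5178 (1.29%) vs 24/5072 (0.47%)
#>   relative reduction: 63.4% | chi-square 19.615 (uncorrected) | p = 9.47e-06
```

Reading the output: the 300-case noise-free synthetic cohort contains 14
injected missing-PPI and 31 inappropriate-PPI incidents among the 276
consent-included cases; hourly surveillance recovers every one of them
with no false alarms (sensitivity and specificity 1.0 in both categories —
a plumbing check, not a claim about real data). The stochastic triage
policy turned 26 alerts into intervention messages. The incidence
comparison reproduces a 63.4% relative reduction (p ≈ 1e−5) from the
period counts given to it.

A command-line wrapper covers the same pipeline
(`simulate → run → evaluate → table3 → report`):

```sh
Rscript inst/cli/ppisentinel.R simulate --config inst/extdata/study_cohort.yaml --out cohort/
Rscript inst/cli/ppisentinel.R run --cohort cohort/ --out alerts.jsonl
Rscript inst/cli/ppisentinel.R evaluate --alerts alerts.jsonl --cohort cohort/ \
    --labels cohort/labels.csv --out report.json
Rscript inst/cli/ppisentinel.R table3 67 5178 24 5072
```

## Package layout

* `R/kb.R` — drug-class knowledge base, dose qualifiers, thresholds
* `R/cohort.R` — data model, CSV I/O, time-point queries
* `R/engine.R`, `R/surveillance.R` — alert predicates, suppression,
  surveillance loop, triage, JSON-Lines alert logs
* `R/evaluation.R` — discharge screening, diagnostic performance,
  incidence comparison
* `R/synth.R` — calibrated synthetic cohort generator with labels
* `R/cli.R`, `inst/cli/ppisentinel.R` — command-line interface
* `vignettes/gastroprotection-surveillance.Rmd` — methods notes: model
  assumptions, parameter semantics, generator design, limitations
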