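---
title: "Methods: rule-based surveillance of PPI gastroprotection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based surveillance of PPI gastroprotection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem and the model

Proton pump inhibitors (PPIs) are under- and over-prescribed in hospitals at
the same time: patients whose drug combinations raise their gastrointestinal
bleeding risk are discharged without gastroprotection, while many PPIs run
without any documented indication. `ppisentinel` implements a rule-based
surveillance engine over longitudinal inpatient medication records that
raises two categories of alert:

* **Missing gastroprotection (alerts 1–11).** No PPI is active while a
  high-risk drug constellation is: an NSAID combined with another risk
  factor (alerts 1–6), antiplatelet/anticoagulant combinations (7–9),
  low-dose aspirin with a corticosteroid in an older patient (10), or an
  accumulation of at least four risk factors (11).
* **Potentially inappropriate PPI (alert 12).** A once-daily oral PPI with
  no drug-related risk factor. Age alone does not protect a PPI from this
  alert; intravenous and twice-daily prescriptions are treated as
  appropriate because those modes imply an active therapeutic indication
  (and because screening them would flood the pharmacist with alerts).

The countable risk-factor set is: NSAID, COX2 inhibitor, antiplatelet
therapy (one factor however many agents are on board), therapeutic-dose
anticoagulation, SSRI (the configured "drugs associated with
gastrointestinal bleeding" class, extensible in the knowledge base), age ≥
65 years, and thrombocytes < 30 G/L. Corticosteroids at ≥ 10 mg prednisone
equivalent per day trigger the specific alerts that name them but are
deliberately not part of the countable set, mirroring the deployed rule
set. In alerts 7 and 8, "and risk factor" means a countable factor *not
already consumed* by the alert's named triggers, so an alert never fires
off its own precondition.

Lower-numbered alerts suppress higher-numbered ones, so a case produces at
most one open missing-PPI alert at a time; alert 12 cannot compete with
1–11 because their PPI preconditions are mutually exclusive.

## Drug knowledge base

Drug products are classified by ATC code with longest-prefix matching
(e.g. `M01AH` coxibs carve themselves out of the `M01A` NSAID prefix);
free-text names resolve only through an explicit alias table, never
fuzzily. Three qualifiers are dose-dependent:

* **Low-dose aspirin**: ≤ 325 mg/day (common cardiology convention;
  configurable), otherwise plain antiplatelet therapy.
* **Therapeutic anticoagulation**: per-agent minimum daily doses (e.g.
  enoxaparin 120 mg/day, rivaroxaban 15 mg/day). These cut-offs are
  hospital-consensus parameters, not guideline constants, so they live in
  the YAML knowledge base rather than in code.
* **Corticosteroid ≥ 10 mg prednisone equivalent**: daily dose times a
  per-agent equipotency factor (0.75 mg dexamethasone ≡ 5 mg prednisone,
  20 mg hydrocortisone ≡ 5 mg prednisone, ...), linear in dose.

Dual antiplatelet therapy (DAPT) is defined as ≥ 2 distinct concurrent
antiplatelet agents, with aspirin counting as one agent at any dose. The
rule set never defines DAPT membership beyond that; the qualifying agents
are whatever the knowledge base classifies as antiplatelet.

## Data model and temporal conventions

Five plain CSV tables (patients, cases, prescriptions, administrations,
labs) form a validated `cohort_dataset`. Conventions that matter:

* All prescription intervals are half-open `[start, end)`: the end
  timestamp is the first moment a drug no longer counts, which avoids
  double-counting at switch times.
* Timestamps are ISO-8601 in one implicit timezone per dataset; no DST
  arithmetic. Completed age counts the birthday itself as attained.
* A missing thrombocyte value means the factor is absent — triggers fire on
  observed values only, using the latest value at or before the query time.
* Consent-refusing patients and patients under 18 at admission are flagged
  excluded (and minors are never monitored), but their rows are kept.
* `min_exposure_hours` (default 0) optionally delays when a prescription
  starts counting as a risk factor; the deployed system's minimum validity
  period was an unstated consensus parameter, so it is exposed as
  configuration with an inclusive default.

## The on-demand rule and the replicated defect

An on-demand (pro re nata) NSAID counts as risk exposure at time *t* only
when it was administered **more than six times** (≥ 7) in the trailing
48-hour window `(t − 48 h, t]`, counted over administration events — the
"taken" wording points at administrations, not prescriptions. The package
applies the rule to on-demand NSAIDs and coxibs (pharmacologically NSAIDs);
other on-demand drugs count as active for as long as their prescription is
open. The original deployment of this rule contained a programming error
that let rarely-used on-demand NSAIDs count as risk factors, silently
suppressing inappropriate-PPI alerts; the engine implements the rule
correctly but offers `replicate_bug_on_demand = TRUE` to reproduce the
defect, which is how the package demonstrates that the resulting
sensitivity loss is confined to the inappropriate-PPI category.

## Surveillance loop and alert lifecycle

Ticks run at `t0 + k · step` (default hourly, matching an hourly review of
patient files); an event between ticks is observed at the next tick. At
each tick, for every included in-hospital case: profile → candidate alerts
→ suppression → raise (deduplicated) → triage → automatic termination.
Lifecycle states:

* `PENDING` → `INTERVENTION` (message sent; outcome accepted / not
  accepted / unknown), or
* `PENDING` → `NOT_RELEVANT` (pharmacist dismissal; terminal — the same
  alert number is not re-raised for that case), or
* `PENDING`/`INTERVENTION` → `RESOLVED` when the trigger predicate no
  longer holds or the case is discharged.

The pharmacist step is modelled as a seeded stochastic triage policy
(per-tick review probability, per-alert intervention probability,
per-category acceptance and unknown-outcome probabilities). Identical
inputs and seeds produce byte-identical logs. A degenerate
`always_intervene` mode (immediate review, always intervene, always
accepted) is used for validation runs, where the human step must not add
noise.

## Evaluation machinery

*Discharge screening* evaluates the same predicates at the last
surveillance tick (anchored at admission) strictly before discharge — the
rule set speaks only of "the day of discharge", and the last tick is the
closest machine-checkable reading. *Diagnostic performance* calls a case
test-positive for a category when at least one alert of that category was
raised during the stay, whatever its final lifecycle state, and computes
sensitivity and specificity per category (never per individual alert);
empty denominators are reported as `NA`, never silently as 0/0. The
*incidence comparison* runs the two-proportion Pearson chi-square on the
2×2 incident-by-period table; Yates continuity correction is off by
default and available by flag, since "chi-square test" alone does not pin
the variant down. The published p-value of 0.022 for the inappropriate
category is not exactly recoverable from the printed marginals under
either variant (uncorrected: 0.026; corrected: 0.029), so the package
treats such printed p-values as bounded claims and documents both
statistics. Relative reduction is `(rate_a − rate_b)/rate_a × 100`.

## Synthetic cohort generator

The generator emulates the two observation quarters: per-band age
distribution renormalised so the ≥ 65 band matches the per-case risk-factor
margin (band means land at 58.3 years), per-band stay lengths (mean ≈ 5.4
days), a 49/51 sex split, per-factor exposure probabilities calibrated to
the published per-case counts at n = 5072, a 33% PPI prescription rate and
an 8% consent-refusal rate. Ages and stays are sampled per band and
jittered uniformly within the band; exactness of the joint distribution is
not a goal, only the margins.

Incidents are *injected by construction*, not rejection-sampled: a
missing-PPI case either already draws a triggering constellation or gets
the minimal prescriptions realising a sampled alert row, and never a PPI;
an inappropriate-PPI case gets a once-daily oral PPI and no risk-factor
exposure at all. Non-incident cases are constructed so that **no predicate
holds at any time during the stay**: triggering background constellations
are covered by a PPI from admission, and indication-free PPIs added to
reach the PPI-rate margin use the appropriate twice-daily/intravenous
modes. Because injected exposures span the whole stay, ground-truth labels
are exact both at discharge and online. Consequences worth stating plainly:

* label soundness (discharge screening reproduces the labels with zero
  disagreements) and perfect noise-free end-to-end accuracy are *design
  checks of the plumbing* — time windows, dose thresholds, lab lookups,
  suppression, lifecycle — not evidence about real EHR data, where
  exposures start and stop mid-stay, doses change, and documentation lags;
* the generator reproduces margins, not the real cohort's joint
  correlation structure, readmissions, or diagnosis-driven indications
  (an "indicated PPI" is a hidden label field, since the source system
  also lacked coded diagnoses).

On-demand NSAIDs are attached only to PPI-carrying cases and administered
at most about once a day — far below the dose-window rule — so they are
label-neutral under correct logic, and enabling the replicated defect
degrades exactly the inappropriate-PPI sensitivity.

Background factor probabilities are inflated by `1/(1 − p_inappropriate)`
to compensate for the factor-free inappropriate-PPI cases, keeping
period-level margins calibrated; the few factors added by missing-PPI
injection (≈ 0.5% of cases) are left uncompensated as they sit well inside
the binomial 99% intervals the calibration is checked against.

## Numerical choices and problem sizes

* Thresholds are compared inclusively where the rule text says "≥" and
  exclusively for "< 30 G/L"; the on-demand window is half-open
  `(t − 48 h, t]`.
* Degenerate inputs: empty cohorts yield empty logs; screening an open
  case, unknown identifiers, or a non-corticosteroid in the equipotency
  query raise typed errors rather than returning defaults.
* The tests exercise the rule engine exhaustively over all 4 608
  enumerable risk states against an independently written truth-table
  oracle; label soundness runs on the full 5 072-case calibrated preset;
  end-to-end surveillance validation uses 300–350-case cohorts over a
  quarter at hourly ticks, which keeps the whole suite under a minute
  while still covering thousands of case-ticks.
* The calibration check uses the packaged preset at its stored seed; each
  margin is asserted inside the central 99% binomial interval of its
  target count, and the mean age within ±1 year.

## Known limitations

The engine checks neither PPI dosage correctness nor
prophylactic-versus-therapeutic intent, has no diagnosis input, and models
the pharmacist as a probability, not a clinician. Alert-volume properties
observed on synthetic cohorts do not transfer to real hospitals, whose
exposure dynamics are richer. The incidence comparison is a plain 2×2
chi-square; it does not adjust for case mix between periods.
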