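# Default engine configuration: rule thresholds, surveillance step and the
# stochastic triage policy standing in for the pharmacist assessment.
thresholds:
  corticosteroid_min_prednisone_eq: 10   # mg prednisone equivalent / day
  age_min: 65                            # years
  thrombocyte_max: 30                    # G/L
  multi_factor_min: 4                    # concurrent risk factors
  on_demand_min_doses: 7                 # "more than six" in the window
  on_demand_window_hours: 48
  min_exposure_hours: 0
step_hours: 1
replicate_bug_on_demand: false
triage:
  mode: stochastic
  p_intervention: [0.73, 0.73, 0.73, 0.73, 0.73, 0.73, 0.73, 0.73, 0.73, 0.73, 0.73, 0.44]
  p_accept:
    MISSING_PPI: 0.73
    INAPPROPRIATE_PPI: 0.34
  p_unknown:
    MISSING_PPI: 0.10
    INAPPROPRIATE_PPI: 0.10
  p_review_per_tick: 0.125
  seed: 1
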