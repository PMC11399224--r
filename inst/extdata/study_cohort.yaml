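# Two-period synthetic cohort preset calibrated to the study-period
# characteristics table: per-band age and stay distributions, per-factor
# exposure probabilities, PPI prescription rate and incident rates.
# Identical to the package defaults of cohort_config(); kept as an explicit
# document for CLI use and as the reference calibration.
n_baseline: 5178
n_intervention: 5072
baseline_window: ["2020-07-01", "2020-09-30"]
intervention_window: ["2021-07-01", "2021-09-30"]
p_missing:
  baseline: 0.012939359      # 67 / 5178
  intervention: 0.004731861  # 24 / 5072
p_inappropriate:
  baseline: 0.063537890      # 329 / 5178
  intervention: 0.053233438  # 270 / 5072
age_bands:
  lo: [18, 30, 55, 65]
  hi: [30, 55, 65, 90]
  p: [0.10614, 0.29205, 0.16017, 0.44164]
stay_bands:
  lo: [0.25, 3, 6, 15]
  hi: [3, 6, 15, 24]
  p: [0.39707, 0.34022, 0.20492, 0.05779]
p_female: 0.51
factor_probs:
  nsaid: 0.087342272             # 443 / 5072
  cox2: 0.001774448              # 9 / 5072
  low_dose_aspirin: 0.164234385  # 833 / 5072
  antiplatelet: 0.036474763      # 185 / 5072
  anticoagulant: 0.083004732     # 421 / 5072
  corticosteroid: 0.008872240    # 45 / 5072
  ssri: 0.043769716              # 222 / 5072
  thrombocytopenia: 0.007689274  # 39 / 5072
p_ppi: 0.33
p_ppi_iv_share: 0.3
p_consent_refusal: 0.08
p_on_demand_nsaid: 0.05
missing_row_weights:
  "1": 2
  "2": 2
  "3": 1
  "4": 1
  "5": 3
  "6": 0.5
  "9": 4
  "10": 1
seed: 1
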