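# Default drug-class knowledge base (ATC prefixes, longest match wins).
# Dose thresholds and potency factors are hospital-consensus defaults;
# replace this document to change any of them without touching code.
version: "1.0.0"
classes:
  # non-selective NSAIDs (M01A), coxibs carved out below
  M01A: NSAID
  M01AH: COX2
  # aspirin in antiplatelet and analgesic ATC positions
  B01AC06: ASPIRIN
  N02BA01: ASPIRIN
  # other antiplatelet agents (clopidogrel, prasugrel, ticagrelor, ...)
  B01AC: ANTIPLATELET_NON_ASPIRIN
  # anticoagulants: VKA, heparins, direct thrombin and factor Xa inhibitors
  B01AA: ANTICOAGULANT
  B01AB: ANTICOAGULANT
  B01AE: ANTICOAGULANT
  B01AF: ANTICOAGULANT
  # systemic glucocorticoids
  H02AB: CORTICOSTEROID
  # drugs associated with gastrointestinal bleeding: SSRIs
  # (list may be expanded through this configuration)
  N06AB: SSRI
  # proton pump inhibitors
  A02BC: PPI
aliases:
  ibuprofen: M01AE01
  naproxen: M01AE02
  diclofenac: M01AB05
  ketorolac: M01AB15
  celecoxib: M01AH01
  etoricoxib: M01AH05
  aspirin: B01AC06
  acetylsalicylic acid: B01AC06
  clopidogrel: B01AC04
  prasugrel: B01AC22
  ticagrelor: B01AC24
  dipyridamole: B01AC07
  warfarin: B01AA03
  phenprocoumon: B01AA04
  acenocoumarol: B01AA07
  heparin: B01AB01
  dalteparin: B01AB04
  enoxaparin: B01AB05
  dabigatran: B01AE07
  rivaroxaban: B01AF01
  apixaban: B01AF02
  edoxaban: B01AF03
  prednisone: H02AB07
  prednisolone: H02AB06
  methylprednisolone: H02AB04
  dexamethasone: H02AB02
  betamethasone: H02AB01
  triamcinolone: H02AB08
  hydrocortisone: H02AB09
  fluoxetine: N06AB03
  citalopram: N06AB04
  paroxetine: N06AB05
  sertraline: N06AB06
  escitalopram: N06AB10
  omeprazole: A02BC01
  pantoprazole: A02BC02
  lansoprazole: A02BC03
  rabeprazole: A02BC04
  esomeprazole: A02BC05
corticosteroid_potency:
  # mg prednisone equivalent per mg of drug
  H02AB07: 1.0        # prednisone
  H02AB06: 1.0        # prednisolone
  H02AB04: 1.25       # methylprednisolone (4 mg ~ 5 mg prednisone)
  H02AB08: 1.25       # triamcinolone
  H02AB02: 6.6666667  # dexamethasone (0.75 mg ~ 5 mg prednisone)
  H02AB01: 6.6666667  # betamethasone
  H02AB09: 0.25       # hydrocortisone (20 mg ~ 5 mg prednisone)
anticoagulant_thresholds:
  # minimum daily dose (native unit) counted as therapeutic anticoagulation
  B01AA: 0.5          # vitamin K antagonists: any maintenance dose
  B01AB01: 15000      # unfractionated heparin, IU/day
  B01AB04: 10000      # dalteparin, IU/day
  B01AB05: 120        # enoxaparin, mg/day (prophylaxis 40 mg/day is below)
  B01AE07: 300        # dabigatran, mg/day
  B01AF01: 15         # rivaroxaban, mg/day (prophylaxis 10 mg/day is below)
  B01AF02: 10         # apixaban, mg/day (prophylaxis 5 mg/day is below)
  B01AF03: 30         # edoxaban, mg/day
limits:
  aspirin_low_dose_max: 325
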