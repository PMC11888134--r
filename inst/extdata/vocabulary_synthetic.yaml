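# Synthetic stand-in vocabulary (no licensed MedDRA content): an editable
# flat term list for the hypertension event, the nine SRI target drugs with
# ATC codes, and the covariate / population ATC code sets.
smq_terms:
  - Hypertension
  - Blood pressure increased
  - Hypertensive crisis
  - Blood pressure systolic increased
  - Blood pressure diastolic increased
  - Essential hypertension
  - Hypertensive emergency
  - Hypertensive encephalopathy
  - Labile hypertension
  - Blood pressure abnormal
target_drugs:
  alaproclate: [N06AB01]
  citalopram: [N06AB04]
  escitalopram: [N06AB10]
  etoperidone: [N06AX09]
  fluoxetine: [N06AB03]
  fluvoxamine: [N06AB08]
  paroxetine: [N06AB05]
  sertraline: [N06AB06]
  zimeldine: [N06AB02]
antihypertensive_codes: [C02]
hypertensive_inducer_codes: [H02AB04, M01AE01, R01BA02, L04AD01, G03AA07]
comparator_population_codes: [N06A]
stroke_terms:
  - Cerebrovascular accident
  - Ischaemic stroke
  - Haemorrhagic stroke
mi_terms:
  - Myocardial infarction
  - Acute myocardial infarction
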