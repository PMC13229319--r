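# Operational cutoff configuration for the 13 CSSI risk factors.
# The embedded vo2max_reference bands are synthetic placeholders, not the
# KOSHA H-43-2021 / CPHA guideline values (which are not redistributed here).
obesity:
  bmi: 25.0
  waist_male: 90.0
  waist_female: 85.0
hypertension:
  sbp: 140.0
  dbp: 90.0
diabetes:
  glucose: 126.0
  hba1c: 6.5
dyslipidemia:
  ldl: 160.0
  hdl: 40.0
  total_chol: 240.0
liver_enzymes:
  ast: 40.0
  alt: 40.0
  ggtp: 50.0
abnormal_hr:
  low: 50.0
  high: 100.0
anemia:
  hb_male: 13.0
  hb_female: 12.0
hearing_loss:
  pta: 25.0
pulmonary:
  fev1_fvc: 70.0
  fev1_pred: 80.0
smoking:
  pack_years: 20.0
alcohol:
  per_week: 2.0
vo2max_reference:
- sex: male
  age_min: 18.0
  age_max: 30.0
  lower_bound: 33.0
- sex: male
  age_min: 30.0
  age_max: 40.0
  lower_bound: 31.0
- sex: male
  age_min: 40.0
  age_max: 50.0
  lower_bound: 29.0
- sex: male
  age_min: 50.0
  age_max: 60.0
  lower_bound: 26.0
- sex: male
  age_min: 60.0
  age_max: 120.0
  lower_bound: 23.0
- sex: female
  age_min: 18.0
  age_max: 30.0
  lower_bound: 28.0
- sex: female
  age_min: 30.0
  age_max: 40.0
  lower_bound: 26.0
- sex: female
  age_min: 40.0
  age_max: 50.0
  lower_bound: 24.0
- sex: female
  age_min: 50.0
  age_max: 60.0
  lower_bound: 21.0
- sex: female
  age_min: 60.0
  age_max: 120.0
  lower_bound: 18.0
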