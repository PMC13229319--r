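# Synthetic placeholder VO2max lower bounds (mL/kg/min) by sex and age band.
# Not the KOSHA H-43-2021 / Canadian Public Health Association values.
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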