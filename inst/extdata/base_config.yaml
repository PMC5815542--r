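parameters:
  p_uti_pvc: 0.6248
  rr_uti: 0.84
  r1: 0.34
  r2: 0.034
  p_bladder_stones: 0.0012
  p_kidney_stones: 0.0012
  p_urethral_injury: 0.0019
  p_urosepsis: 0.0032
  rr_other: 0.9
  p_renal_progression: 0.0004
  p_renal_failure: 0.0029
  m_uti_first: 0.0
  m_uti_resistant: 145.27
  m_uti_weighted: 49.3918
  m_urosepsis: 797.6
  m_significant: 18.0
  m_renal_failure: 54.0
  uti_mortality_mode: weighted
  prop_male: 0.8
  entry_age: 36.0
  rate_to_prob: no
  accrual: midpoint
costs:
  catheter_pvc: 74.27
  catheter_hydro: 608.27
  lubricant_month: 132.75
  tubes_per_day: 2.0
  uti_event: 554.16
  uti_antibiotics: 60.5
  urosepsis: 708.36
  urethral_injury: 605.33
  kidney_stones: 524.3
  bladder_stones: 721.95
  significant_month: 82.6
  renal_failure_month: 2589.02
utilities:
  u0: 0.5
  uti: 0.06
  uti_resistant: 0.104
  kidney_stones: 0.05
  bladder_stones: 0.05
  urethral_injury: 0.104
  urosepsis: 0.16
  significant: 0.155
  renal_failure: 0.25
run:
  analysis: primary
  annual_rate: 0.05
  threshold: 147000.0
  life_tables: synthetic
  seed: 1
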