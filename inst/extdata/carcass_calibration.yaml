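# Calibration of the synthetic phenotype generator: published main-effect
# means and SDs for shear force (N) by grade and aging day, and per-grade
# carcass trait means/SDs for the red-faced Hereford steer cohort.
# Marbling scale: 200 = Traces, 300 = Slight, 400 = Small, 500 = Modest.
grades: [Standard, Select, Choice]
aging_days: [1, 3, 7, 14, 21]
shear:
  grade_means: {Standard: 66.3, Select: 84.3, Choice: 71.3}
  grade_sds: {Standard: 12.4, Select: 13.9, Choice: 13.0}
  aging_means: {"1": 89.9, "3": 80.7, "7": 71.0, "14": 65.3, "21": 62.9}
traits:
  hcw_kg:
    mean: {Standard: 250.6, Select: 282.9, Choice: 283.2}
    sd: {Standard: 33.0, Select: 23.0, Choice: 15.9}
  fat_cm:
    mean: {Standard: 0.43, Select: 0.64, Choice: 0.58}
    sd: {Standard: 0.21, Select: 0.21, Choice: 0.23}
  rea_cm2:
    mean: {Standard: 57.68, Select: 67.23, Choice: 72.13}
    sd: {Standard: 5.27, Select: 2.72, Choice: 4.87}
  kph_pct:
    mean: {Standard: 1.60, Select: 1.80, Choice: 2.08}
    sd: {Standard: 0.22, Select: 2.27, Choice: 0.38}
  yield_grade:
    mean: {Standard: 2.46, Select: 2.62, Choice: 2.35}
    sd: {Standard: 0.4, Select: 0.37, Choice: 0.24}
  marbling:
    mean: {Standard: 266, Select: 330, Choice: 463}
    sd: {Standard: 16.7, Select: 18.7, Choice: 15.0}
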