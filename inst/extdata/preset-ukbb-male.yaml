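# Synthetic cohort preset: males, UK-Biobank-like study conditions.
name: ukbb-male
sex: male
cancers: [bladder, colorectum, kidney, lung, melanoma, nhl, pancreas,
          prostate]
cancer_share:
  prostate: 0.45
  colorectum: 0.14
  lung: 0.13
  melanoma: 0.09
  nhl: 0.06
  bladder: 0.06
  kidney: 0.04
  pancreas: 0.03
snps_per_cancer: 25
null_snps_per_cancer: 75
gwas_n: 120000
effect_dist: {mean: 0.12, sd: 0.04}
raf_range: [0.05, 0.95]
ld: {block_size: 8, spacing_bp: 20000, decay_bp: 50000}
risk_factors:
  bmi: {mean: 27.6, sd: 4.2}
  smoking: {p_never: 0.45, p_former: 0.42, p_current: 0.13}
  pack_years: {shape: 1.5, mean: 22.0}
  family_history: {breast: 0.11, colorectum: 0.04, prostate: 0.06}
relative_log_hr:
  prs_per_sd: 0.6
  bmi_per_sd: 0.3
  smoking_former: 0.3
  smoking_current: 0.9
  pack_years_per_year: 0.025
  family_history: 0.4
target_hr_per_sd: 1.43
baseline: {age_min: 40, age_max: 90, rate_at_min: 0.0012, log_slope: 0.072}
death: {rate_at_min: 0.0013, log_slope: 0.088}
other_cancer_rate: 0.004
enrollment: [40, 69]
followup: [6, 10]
missingness: {pack_years: 0.16, bmi: 0.015, smoking: 0.015, family_history: 0.005}
age_weight_slope: -0.013
seed: 102
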