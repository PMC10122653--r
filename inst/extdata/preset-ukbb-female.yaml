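# Synthetic cohort preset: females, UK-Biobank-like study conditions.
# All numeric ground truth for the female generator lives here, not in code.
# The relative log hazard ratios are scaled at load time so that the true
# standardized pan-cancer risk score hazard ratio equals target_hr_per_sd.
name: ukbb-female
sex: female
cancers: [bladder, breast, colorectum, endometrium, kidney, lung, melanoma,
          nhl, ovary, pancreas]
cancer_share:
  breast: 0.42
  colorectum: 0.12
  lung: 0.12
  melanoma: 0.09
  endometrium: 0.07
  nhl: 0.05
  ovary: 0.05
  kidney: 0.03
  pancreas: 0.03
  bladder: 0.02
snps_per_cancer: 25
null_snps_per_cancer: 75
gwas_n: 120000
effect_dist: {mean: 0.12, sd: 0.04}
raf_range: [0.05, 0.95]
ld: {block_size: 8, spacing_bp: 20000, decay_bp: 50000}
risk_factors:
  bmi: {mean: 27.0, sd: 4.7}
  smoking: {p_never: 0.55, p_former: 0.35, p_current: 0.10}
  pack_years: {shape: 1.5, mean: 18.0}
  family_history: {breast: 0.11, colorectum: 0.04, lung: 0.05}
relative_log_hr:
  prs_per_sd: 0.6
  bmi_per_sd: 0.3
  smoking_former: 0.3
  smoking_current: 0.9
  pack_years_per_year: 0.025
  family_history: 0.4
target_hr_per_sd: 1.39
baseline: {age_min: 40, age_max: 90, rate_at_min: 0.0015, log_slope: 0.064}
death: {rate_at_min: 0.0010, log_slope: 0.085}
other_cancer_rate: 0.004
enrollment: [40, 69]
followup: [6, 10]
missingness: {pack_years: 0.16, bmi: 0.015, smoking: 0.015, family_history: 0.005}
age_weight_slope: -0.012
seed: 101
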