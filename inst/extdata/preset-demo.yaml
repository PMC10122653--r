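# Small synthetic preset for fast end-to-end smoke runs and examples.
name: demo
sex: female
cancers: [breast, colorectum, lung]
cancer_share: {breast: 0.55, colorectum: 0.25, lung: 0.20}
snps_per_cancer: 10
null_snps_per_cancer: 30
gwas_n: 60000
effect_dist: {mean: 0.15, sd: 0.05}
raf_range: [0.05, 0.95]
ld: {block_size: 5, spacing_bp: 20000, decay_bp: 50000}
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
target_hr_per_sd: 1.40
baseline: {age_min: 40, age_max: 90, rate_at_min: 0.0015, log_slope: 0.064}
death: {rate_at_min: 0.0010, log_slope: 0.085}
other_cancer_rate: 0.004
enrollment: [40, 69]
followup: [6, 10]
missingness: {pack_years: 0.16, bmi: 0.015, smoking: 0.015, family_history: 0.005}
age_weight_slope: -0.012
seed: 103
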