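# mcedrisk

Risk-stratified projection of multicancer early-detection (MCED) test
performance.

MCED blood tests (e.g. Galleri, DETECT-A) screen for many cancer types at
once. They are highly specific, but in an unstratified population the
short-term probability of developing any cancer is so low that most
positive results are false — the positive predictive value (PPV) is poor.
This package implements, end to end, the modelling chain that quantifies
how much risk stratification can help, for epidemiologists and
biostatisticians studying screening policy:

1. **Polygenic risk scores.** GWAS summary statistics are quality-
   controlled (MAF, ambiguous-strand, frequency-concordance, allele-
   resolution and info-score filters), LD-clumped at p ≤ 5×10⁻⁸ / r² 0.1 /
   1000 kb, and scored as the standardized weighted dosage sum
   `PRS_j = Σ_i β_i SNP_ij`.
2. **Pan-cancer risk score (PCRS).** A sex-specific Cox proportional-
   hazards model with age as timescale (left-truncated, right-censored),
   `λ(t|z) = λ₀(t) exp(β'z)`, combines the per-cancer PRSs with BMI,
   smoking status, pack-years, and family history; the PCRS is the
   fitted linear predictor `β'z`, evaluated on a held-out test split with
   standardized hazard ratios, Harrell's C, and a 5-year IPCW
   cumulative/dynamic AUC.
3. **Absolute risk.** The age-indexed baseline hazard is calibrated to
   external marginal incidence rates via a simulated reference population
   (with a depletion-of-susceptibles correction), and each stratum's
   short-window absolute risk is
   `x = 1 − exp(−Σ_t λ₀(t) e^{PCRS} Δt)`.
4. **Screening projection.** Bayes' theorem converts absolute risk into
   `PPV(x) = Se·x / (Se·x + (1−Sp)(1−x))` and
   `NPV(x) = Sp·(1−x) / ((1−Se)·x + Sp·(1−x))` over age × PCRS-percentile
   grids, with empirical-PPV time-window calibration and PPV-threshold
   eligibility ages.

Because the real inputs (prospective biobank cohorts, registry incidence
rates, census age distributions) are access-restricted, a first-class
synthetic-data module generates all of them from a known ground truth, so
the whole pipeline is testable anywhere. Preset study conditions encode a
UK-Biobank-like cohort: enrollment at 40–69, ~4% incident cases over 6–10
years of follow-up, ~19% complete-case removal, and true standardized
PCRS hazard ratios of 1.39 (females) and 1.43 (males).

## Worked example

```r
library(mcedrisk)

cfg    <- truth_config("ukbb-female")          # preset ground truth
cohort <- generate_cohort(cfg, 20000, seed = 1)
cc     <- filter_complete_cases(cohort)        # removes 3787 of 20000 (~19%)
parts  <- split_train_test(cc$cohort, seed = 1)

model  <- fit_hazard_model(parts$train)
scores <- compute_pcrs(model, parts$test)
standardized_hr(parts$test, scores$pcrs)
#> HR per SD: 1.39 (95% CI 1.21-1.60)
harrells_c(parts$test, scores$pcrs)            #> 0.586
auc_at_horizon(parts$test, scores$pcrs, 5)     #> 0.606

inc  <- shift_incidence(generate_incidence_table(cfg, seed = 2))
ref  <- reference_distribution(model, seed = 3)
base <- calibrate_baseline(inc, ref)
surf <- risk_surface(base, ref, ages = 75, bins = c(0, 5, 10, 90, 95, 100))
project_screening(test_characteristics("galleri"), surf)
#>   age    bin   risk    ppv    npv
#> 1  75    0-5 0.0073 0.4311 0.9964
#> 2  75   5-10 0.0089 0.4811 0.9956
#> 3  75  10-90 0.0148 0.6079 0.9927
#> 4  75  90-95 0.0246 0.7224 0.9878
#> 5  75 95-100 0.0305 0.7641 0.9849
```

Read: a 75-year-old woman in the 5–10th PCRS percentile has a simulated
1-year risk of any of the ten modelled cancers of 0.89%, at which a
Galleri-like test (sensitivity 51.5%, specificity 99.5%) would have a PPV
of 48% — while her 90–95th-percentile contemporary, at 2.5% risk, reaches
72%. NPV stays above 98.5% everywhere. `run_pipeline()` drives the same
chain (plus genotype-level PRS construction, model comparison, window
calibration, and eligibility grids) from a single YAML config; see
`inst/extdata/run-demo.yaml` and the vignette for the methods.

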