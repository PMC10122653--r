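---
title: "Risk-stratified projection of multicancer screening tests: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-stratified projection of multicancer screening tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcedrisk)
```

## The problem

Multicancer early-detection (MCED) blood tests screen for many cancer
types at once from circulating analytes such as cell-free DNA. They are
highly specific but, in a general population where the short-term
probability of developing any cancer is small, their positive predictive
value (PPV) is low: most positives are false. `mcedrisk` implements the
modelling chain needed to ask a sharper question — *for whom* is such a
test worth doing: it stratifies a population by age and by a pan-cancer
risk score (PCRS) built from per-cancer polygenic risk scores (PRSs) and
conventional risk factors, converts the relative risks into short-window
absolute risks calibrated to registry incidence rates, and pushes those
risks through Bayes' theorem to obtain PPV and NPV grids, screening
eligibility ages, and time-window calibrations for specific tests.

Because the cohort, registry, and census inputs this kind of analysis
consumes are access-restricted, the package ships a synthetic-data module
that generates every input from a fully known ground truth. All claims
the test suite makes are claims about recovering that truth.

## The generative model and its parameters

The synthetic cohort follows a proportional-hazards model on an **age
timescale**:

$$\lambda(t \mid z) = \lambda_0(t)\,\exp(\beta_1 z_1 + \dots + \beta_n z_n),$$

with $t$ age in years, $\lambda_0(t)$ a piecewise-constant baseline
hazard on 1-year strata, and $z$ the covariates: one standardized PRS per
cancer type, BMI (kg/m²), smoking status (never/former/current), pack-years,
and binary family-history indicators. Ten principal components are carried
as adjustment covariates with null true effects. Subjects enrol at a
uniform age on 40–69, and exit at the earliest of the first in-scope
cancer (the event), an out-of-scope cancer, non-cancer death, or the
administrative end of follow-up (6–10 years after entry) — so records are
left-truncated and right-censored exactly like a prospective cohort with
registry linkage. Event ages are drawn by exact inverse-transform
sampling on the piecewise-linear cumulative hazard, which keeps
parameter-recovery tests sharp (no discretization bias) and yields
continuous ages with essentially no ties. Death and other-cancer exits
are independent of the covariates (non-informative censoring).

The presets (`ukbb-female`, `ukbb-male`, `demo`) keep every generative
number in one YAML file each. Two aspects deserve emphasis:

* **Effect-size scaling.** The presets state *relative* covariate
  effects; at load time these are rescaled so that the standard deviation
  of the true linear predictor equals $\log(\text{target HR per SD})$ —
  1.39 for females, 1.43 for males. The scaling uses the closed-form
  variance of $\beta' z$ under the configured covariate distribution
  (independent unit-normal PRSs, normal BMI, a three-level smoking
  categorical with gamma pack-years for ever-smokers, independent
  Bernoulli family histories), so `exp(pcrs_truth_sd(cfg))` equals the
  target exactly.
* **Covariate distributions.** BMI mean/SD, smoking prevalences,
  pack-years shape/mean, and family-history prevalences are realistic
  stand-ins for a UK cohort of this age range; no public source states
  the exact values, so they were chosen once and are not tuned. The
  baseline hazard is exponential in age (Gompertz-like), set so the
  marginal any-included-cancer incidence reaches roughly 1.4–1.7% per
  year at age 75 and the cohort accrues about 4% incident cases — in line
  with registry rates for a 10-cancer composite and with the source
  cohort's case fraction.

Missingness is injected completely at random, dominated by pack-years
(16%), for a combined ~19% of subjects missing at least one risk factor;
this exercises the complete-case filter at its documented rate.

What the generator deliberately does *not* emulate: realistic human LD
maps (LD is block-diagonal with exponential decay), ancestry structure,
pleiotropy across cancers, informative censoring, and calendar-time
effects. Passing tests therefore demonstrate correctness of the
machinery, not performance on real data.

## PRS construction

`qc_filter_variants()` applies the published filters in a fixed order so
every removed variant is attributed to exactly one rule: MAF < 0.01;
strand-ambiguous pairs (A/T, G/C) with MAF > 0.40 (strict inequality, so
MAF = 0.40 survives); variants missing from the cohort table
("unmatchable", a distinct audit count); minor-allele-frequency
difference ≥ 0.10 versus the cohort — computed on the minor allele, which
makes the comparison orientation-invariant, since the source analysis
does not say which allele it used; unresolvable allele mismatches, after
attempting a strand flip (complement, effect unchanged) and a dosage flip
(swap alleles, negate the effect, reflect the frequency); and imputation
info < 0.90. Retained records come back aligned to the cohort
orientation, which makes the filter idempotent. For ambiguous pairs a
swap and a strand flip are indistinguishable; the letter-exact
(dosage-flip) reading wins.

`ld_clump()` is the standard greedy procedure at p ≤ 5×10⁻⁸, r² ≥ 0.1,
±1000 kb (the window is interpreted as one-sided distance from the index,
i.e. a 2-Mb span, the common convention); p-value ties break by
(chromosome, position) for reproducibility. r² comes from squared Pearson
correlation of reference dosage columns when a genotype matrix is
supplied. `compute_prs()` is the weighted dosage sum, standardized to
zero mean and unit variance over the scored cohort.

## Model fitting and the PCRS

`fit_hazard_model()` maximizes the Cox partial likelihood with age as
timescale — each subject enters risk sets only between entry and exit age
— with Efron's approximation for ties (the source is silent; Efron has
lower bias than Breslow when event ages cluster). Smoking enters as two
indicator contrasts against "never" plus continuous pack-years. The PCRS
is the coefficient-weighted sum of the risk-factor covariates; principal
components are excluded from the score by default (they are confounder
adjustments, not risk factors — a config switch includes them).
Percentiles are computed against the training-split score distribution.

`compare_models()` refits with three covariate subsets (combined,
risk-factors-only, PRS-only) and evaluates on the held-out third:
standardized hazard ratio (HR per 1 SD of the score, single-covariate
age-timescale fit), Harrell's C with left truncation respected (pairs
compare only where both subjects are under observation), and a
cumulative/dynamic AUC at a 5-year horizon. The horizon is measured in
follow-up time from entry, not attained age, matching the "up to five
years of follow-up" framing. Cases are events within the horizon,
controls subjects still at risk beyond it, and subjects censored earlier
contribute via inverse-probability-of-censoring weights from a
Kaplan-Meier fit to the censoring distribution; with no censoring before
the horizon the estimator reduces exactly to the rank-sum AUC, which is
how the tests pin it down. Bootstrap CIs (200 seeded resamples) are
available via `boot_metric_ci()`; the pipeline reports point estimates by
default to keep the demo fast.

## Absolute risk

Relative risks become absolute risks in three steps, following the
individualized coherent absolute-risk estimation (iCARE) approach:

1. **Reference distribution** — 10,000 normal draws with the training
   PCRS mean and SD stand in for the population score distribution.
2. **Baseline calibration** — per 1-year stratum,
   $\lambda_0(t) = \lambda_m(t) / E_w[e^{PCRS}]$, where $\lambda_m$ is
   the external marginal incidence rate. By default the expectation
   weights each reference draw by its model-implied probability of still
   being cancer-free at $t$, updated from the youngest stratum upward
   (depletion of susceptibles: high-risk draws leave the pool faster, so
   the implied baseline at older ages rises relative to the naive ratio).
   Disabling the correction gives the closed-form ratio used by the
   algebraic tests. Before calibration, `shift_incidence()` advances the
   rate lookup by one year of age — the test is taken at the *start* of
   the follow-up window, so the year ahead is governed by next year's
   registry rate; the top stratum reuses its own rate as the boundary
   convention.
3. **Window risk** — $x = 1 - \exp(-\sum_t \lambda_0(t)\,e^{PCRS}\,
   \Delta t)$ with $\Delta t$ the prorated fraction of each stratum
   inside the window, so 11-month windows split strata linearly.
   Competing mortality is *not* subtracted for these ≤ 1-year windows (at
   these magnitudes it changes risks in the fourth decimal); an optional
   life-table-style adjustment is available for 10-year trajectories,
   default off, since the source describes no such adjustment.

`risk_surface()` grids mean risk by age × PCRS-percentile bin (default
edges 0, 5, 10, 25, 50, 75, 90, 95, 100), evaluating each bin at its mean
reference PCRS.

## Screening projection

PPV and NPV follow Bayes' theorem with the published operating points —
Galleri: sensitivity 51.5% at 99.5% specificity, 1-year window; DETECT-A:
27.1% at 98.9%, 11-month window:

$$PPV(x) = \frac{Se\,x}{Se\,x + (1-Sp)(1-x)}, \qquad
  NPV(x) = \frac{Sp\,(1-x)}{(1-Se)\,x + Sp\,(1-x)}.$$

Sensitivity and specificity are treated as constants across age and risk
strata, as the source assumes. `weighted_ppv()` pools strata by the
Bayes-correct convention — evaluate PPV at the weight-averaged risk —
because that is the PPV of the mixed population a single empirical study
observes; since the phrase "weighted average PPV" is ambiguous, the
average-of-PPVs convention is also implemented and both are reported side
by side in pipeline summaries. `calibrate_window()` is an exhaustive grid
search (default 6–18 months) for the window whose weighted PPV over
females 65–75 (census-like age weights × reference PCRS mixture) best
matches an empirical target such as DETECT-A's 19.4%; ties break toward
12 months, and a boundary optimum warns that the target is out of range.
`eligibility_grid()` returns, per percentile bin, the earliest age at
which projected PPV reaches a policy threshold (e.g. 40%), with `NA`
for "never". DETECT-A projections are meaningful for females only (the
test does not cover prostate cancer); the male preset simply omits it.

## Numerical choices and degenerate inputs

* Stratum probabilities above 1 during calibration raise an error rather
  than clip.
* A zero-variance raw PRS (all null weights) refuses to standardize.
* Coefficients above 15 in absolute value are treated as separation and
  refuse to return.
* Monomorphic simulated variants are flagged and warned, not dropped.
* The degenerate zero-follow-up configuration yields an all-censored
  cohort with exit equal to entry; the model fitter rejects such records.
* All stage seeds derive deterministically from one master seed
  (`derive_seed`), and every generator called twice with the same seed
  returns identical output.

## Problem sizes used by the checks

Parameter-recovery runs use n = 50,000 subjects × 20 replicates per sex
(the scale at which Monte-Carlo error on the mean HR is ~0.01); coverage
checks use 100 replicates at n = 1,500–4,000; oracle comparisons use
≤ 50-subject instances where exhaustive enumeration is exact; the
contingency Monte-Carlo uses 10⁶ draws. The end-to-end demo runs at
n = 1,500–3,000 with 5,000 reference draws. A note on interpretation: the
fitted-model path standardizes an *estimated* PCRS on held-out data, so
its mean HR per SD sits ~1–3% below the generative target at these sizes
(finite-training shrinkage); the oracle path with true coefficients is
unbiased, and both checks appear in the tests.

## Known limitations

Site-specific per-cancer absolute-risk models, competing-risk
(cause-specific) modelling, time-varying covariates, interaction terms,
multi-ancestry transfer, and X-chromosome variants are out of scope. The
synthetic LD structure makes clumping nontrivial but is far simpler than
real human LD; QC pass rates on real summary statistics will differ.
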