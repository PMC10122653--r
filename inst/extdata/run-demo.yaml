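# Small end-to-end run configuration for smoke tests and examples.
preset: demo
n_subjects: 3000
seed: 42
use_genotypes: true
window_months: 12
reference_n: 5000
ages: [50, 55, 60, 65, 70, 75]
bins: [0, 5, 10, 25, 50, 75, 90, 95, 100]
tests:
  - {name: galleri}
  - {name: detect-a}
ppv_thresholds: [0.40, 0.60]
horizon_years: 5
clump: {p_threshold: 5.0e-8, r2: 0.1, window_kb: 1000}
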