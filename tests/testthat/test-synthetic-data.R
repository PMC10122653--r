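test_that("truth config resolves to the target standardized hazard ratio", {
  for (preset in c("ukbb-female", "ukbb-male", "demo")) {
    cfg <- truth_config(preset)
    expect_equal(exp(pcrs_truth_sd(cfg)), cfg$target_hr_per_sd,
                 tolerance = 1e-10)
  }
})

test_that("analytic PCRS moments match a large empirical draw", {
  cfg <- truth_config("ukbb-female")
  lp <- withr::with_seed(4, {
    cv <- mcedrisk:::draw_covariates(cfg, 200000)
    mcedrisk:::true_linear_predictor(cfg, cv)
  })
  expect_equal(sd(lp), pcrs_truth_sd(cfg), tolerance = 0.01)
  expect_equal(mean(lp), 0, tolerance = 0.01)
})

test_that("truth config round-trips through YAML identically", {
  cfg <- truth_config("ukbb-female")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_config(cfg, path)
  back <- read_truth_config(path)
  expect_equal(back, cfg, tolerance = 1e-12)
})

test_that("invalid configs are rejected", {
  expect_error(truth_config("demo", overrides = list(snps_per_cancer = 0)),
               "positive")
  expect_error(truth_config("demo", overrides = list(raf_range = c(0, 0.9))),
               "allele frequencies")
  expect_error(truth_config("demo", overrides = list(enrollment = c(20, 69))),
               "enrollment")
})

test_that("summary statistics honour configured counts and determinism", {
  cfg <- truth_config("demo")
  ss <- generate_summary_stats(cfg, n_causal = 10, n_null = 0, seed = 1)
  expect_equal(nrow(ss$stats), 10)
  expect_true(all(ss$truth$causal))

  a <- generate_summary_stats(cfg, seed = 7)
  b <- generate_summary_stats(cfg, seed = 7)
  expect_identical(a, b)

  expect_error(generate_summary_stats(cfg, n_causal = 0), "configuration")

  # degenerate effect distribution: every causal truth effect at the mean
  cfg0 <- truth_config("demo", overrides = list(
    effect_dist = list(mean = 0.2, sd = 0)))
  ss0 <- generate_summary_stats(cfg0, seed = 2)
  expect_true(all(ss0$truth$beta_true[ss0$truth$causal] == 0.2))
  expect_true(all(ss0$truth$beta_true[!ss0$truth$causal] == 0))

  # identifiers unique, alleles valid and distinct, p-values in (0, 1]
  expect_false(anyDuplicated(ss$stats$rsid) > 0)
  expect_true(all(ss$stats$effect_allele != ss$stats$other_allele))
  expect_true(all(ss$stats$pval > 0 & ss$stats$pval <= 1))
})

test_that("genotype dosages follow the stated allele frequencies", {
  cfg <- truth_config("demo")
  stats <- make_variant(sprintf("v%d", 1:3), pos = c(1e6, 4e6, 7e6),
                        raf = 0.5)
  geno <- generate_genotypes(stats, 10000, cfg, seed = 3)
  expect_true(all(geno >= 0 & geno <= 2))
  # binomial tolerance: 4 SD of a mean of 20,000 Bernoulli(0.5) draws
  expect_true(all(abs(attr(geno, "observed_freq") - 0.5) < 0.02))
})

test_that("single-variant blocks are empirically independent", {
  cfg <- truth_config("demo", overrides = list(
    ld = list(block_size = 1, spacing_bp = 20000, decay_bp = 50000)))
  # positions > 1 Mb apart: every variant its own block
  stats <- make_variant(sprintf("v%d", 1:4), pos = c(1, 3, 5, 7) * 2e6,
                        raf = 0.4)
  geno <- generate_genotypes(stats, 10000, cfg, seed = 5)
  r2 <- cor(geno)^2
  expect_true(all(r2[upper.tri(r2)] < 0.05))
})

test_that("near-zero allele frequency yields a flagged monomorphic column", {
  cfg <- truth_config("demo")
  stats <- make_variant("rare1", raf = 1e-6)
  expect_warning(geno <- generate_genotypes(stats, 500, cfg, seed = 1),
                 "monomorphic")
  expect_true(all(geno == 0))
  expect_identical(attr(geno, "monomorphic"), "rare1")
  expect_error(generate_genotypes(stats[0, ], 10, cfg), "empty")
})

test_that("cohort generation is deterministic and left-truncated", {
  cfg <- truth_config("demo")
  a <- generate_cohort(cfg, 500, seed = 11)
  b <- generate_cohort(cfg, 500, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$exit_age > a$entry_age))
  expect_true(all(a$event %in% 0:1))
  expect_true(all(!is.na(a$cancer_type[a$event == 1])))
  expect_true(all(is.na(a$cancer_type[a$event == 0])))
  expect_true(all(a$cancer_type[a$event == 1] %in% cfg$cancers))
})

test_that("administrative censoring at entry leaves zero events", {
  cfg <- truth_config("demo", overrides = list(followup = c(0, 0)))
  coh <- generate_cohort(cfg, 300, seed = 2)
  expect_equal(sum(coh$event), 0)
})

test_that("null-effect cohort reproduces the configured baseline hazard", {
  # beta = 0 via a unit target hazard ratio; no competing censoring, fixed
  # follow-up, so each subject's event probability has a closed form
  cfg <- truth_config("ukbb-female", overrides = list(
    target_hr_per_sd = 1.0,
    death = list(rate_at_min = 0, log_slope = 0),
    other_cancer_rate = 0,
    followup = c(5, 5),
    missingness = list(pack_years = 0, bmi = 0, smoking = 0,
                       family_history = 0)))
  n <- 50000
  coh <- generate_cohort(cfg, n, seed = 9)
  cum0 <- c(0, cumsum(cfg$baseline_rates))
  cum_at <- function(a) {
    k <- findInterval(a, c(cfg$baseline_ages, max(cfg$baseline_ages) + 1))
    cum0[k] + (a - cfg$baseline_ages[k]) * cfg$baseline_rates[k]
  }
  p_event <- 1 - exp(-(vapply(coh$entry_age + 5, cum_at, numeric(1)) -
                         vapply(coh$entry_age, cum_at, numeric(1))))
  expected <- mean(p_event)
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(coh$event) - expected), 4 * mc_se)
})

test_that("incidence table equals the baseline hazard when effects are null", {
  cfg0 <- truth_config("demo", overrides = list(target_hr_per_sd = 1.0))
  inc0 <- generate_incidence_table(cfg0, n_ref = 5000, seed = 1)
  expect_equal(inc0$rate, cfg0$baseline_rates, tolerance = 1e-12)

  cfg <- truth_config("demo")
  inc <- generate_incidence_table(cfg, n_ref = 5000, seed = 1)
  expect_true(all(inc$rate >= 0))
  # with positive effects the marginal rate exceeds the baseline at entry
  expect_gt(inc$rate[1], cfg$baseline_rates[1])

  zero <- truth_config("demo", overrides = list(
    baseline = list(age_min = 40, age_max = 90, rate_at_min = 0,
                    log_slope = 0)))
  expect_true(all(generate_incidence_table(zero, n_ref = 1000,
                                           seed = 1)$rate == 0))
})

test_that("age weights are positive and normalized", {
  w <- generate_age_weights(truth_config("demo"))
  expect_true(all(w$weight > 0))
  expect_equal(sum(w$weight), 1)
})

test_that("tables survive a disk round trip", {
  cfg <- truth_config("demo")
  ss <- generate_summary_stats(cfg, seed = 1)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss$stats, p1)
  expect_equal(read_summary_stats(p1), ss$stats, tolerance = 1e-12)

  geno <- generate_genotypes(ss$stats[1:5, ], 50, cfg, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".tsv.gz")
  write_genotypes(geno, p2)
  back <- read_genotypes(p2)
  expect_equal(unname(back), unname(geno[, colnames(back)]),
               ignore_attr = TRUE)

  coh <- generate_cohort(cfg, 50, seed = 1)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, p3)
  coh2 <- read_cohort(p3)
  expect_equal(coh2$exit_age, coh$exit_age, tolerance = 1e-12)
  expect_identical(levels(coh2$smoking), levels(coh$smoking))

  inc <- generate_incidence_table(cfg, n_ref = 500, seed = 1)
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(inc, p4)
  expect_equal(read_rate_table(p4, "rate")$rate, inc$rate, tolerance = 1e-12)
})
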