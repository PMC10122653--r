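test_that("QC applies each removal rule and attributes it once", {
  stats <- rbind(
    make_variant("keep1", raf = 0.30),
    make_variant("lowmaf", raf = 0.005),
    make_variant("ambig_hi", ea = "A", oa = "T", raf = 0.45),
    make_variant("ambig_lo", ea = "A", oa = "T", raf = 0.10),
    make_variant("lowinfo", info = 0.85),
    make_variant("drift", raf = 0.30),
    make_variant("mismatch", ea = "A", oa = "G")
  )
  freqs <- cohort_freqs_from_stats(stats)
  freqs$freq[freqs$rsid == "drift"] <- 0.45        # MAF differs by 0.15
  freqs[freqs$rsid == "mismatch", c("effect_allele", "other_allele")] <-
    c("C", "A")                                    # unresolvable pair
  res <- qc_filter_variants(stats, freqs)
  expect_setequal(res$stats$rsid, c("keep1", "ambig_lo"))
  rem <- res$report$removed
  expect_equal(unname(rem[c("maf", "ambiguous", "maf_diff",
                            "allele_mismatch", "info")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(rem))
})

test_that("QC boundary conventions follow the printed thresholds", {
  # ambiguous pair at MAF exactly 0.40 is retained (strict inequality)
  stats <- rbind(make_variant("edge", ea = "G", oa = "C", raf = 0.40),
                 make_variant("maf_edge", raf = 0.01),
                 make_variant("info_edge", info = 0.90))
  res <- qc_filter_variants(stats, cohort_freqs_from_stats(stats))
  expect_setequal(res$stats$rsid, c("edge", "maf_edge", "info_edge"))
})

test_that("unmatchable variants are removed with a distinct count", {
  stats <- rbind(make_variant("known"), make_variant("unknown"))
  freqs <- cohort_freqs_from_stats(stats[1, ])
  expect_warning(res <- qc_filter_variants(stats, freqs), "missing")
  expect_equal(unname(res$report$removed["unmatchable"]), 1L)
  expect_equal(res$stats$rsid, "known")
})

test_that("allele mismatches resolve by strand flip or dosage flip", {
  stats <- rbind(
    make_variant("strand", ea = "A", oa = "G", beta = 0.2, raf = 0.3),
    make_variant("dosage", ea = "A", oa = "G", beta = 0.2, raf = 0.3),
    make_variant("both", ea = "A", oa = "G", beta = 0.2, raf = 0.3)
  )
  freqs <- data.frame(
    rsid = c("strand", "dosage", "both"),
    effect_allele = c("T", "G", "C"),
    other_allele = c("C", "A", "T"),
    freq = c(0.3, 0.7, 0.7),
    stringsAsFactors = FALSE
  )
  res <- qc_filter_variants(stats, freqs)
  expect_equal(nrow(res$stats), 3)
  out <- res$stats[match(c("strand", "dosage", "both"), res$stats$rsid), ]
  # strand flip: complemented alleles, effect unchanged
  expect_equal(out$effect_allele[1], "T")
  expect_equal(out$beta[1], 0.2)
  expect_equal(out$raf[1], 0.3)
  # dosage flip: swapped alleles, negated effect, reflected frequency
  expect_equal(out$effect_allele[2], "G")
  expect_equal(out$beta[2], -0.2)
  expect_equal(out$raf[2], 0.7)
  # strand + dosage flip
  expect_equal(out$effect_allele[3], "C")
  expect_equal(out$beta[3], -0.2)
})

test_that("QC is idempotent on its own output", {
  set.seed(42)
  cfg <- truth_config("demo")
  ss <- generate_summary_stats(cfg, seed = 8)
  freqs <- cohort_freqs_from_stats(
    ss$stats, freq = pmin(pmax(ss$stats$raf + rnorm(nrow(ss$stats), 0, 0.05),
                               0.001), 0.999))
  # scramble some orientations so flips are exercised
  flip <- seq_len(nrow(freqs)) %% 3 == 0
  tmp <- freqs$effect_allele[flip]
  freqs$effect_allele[flip] <- freqs$other_allele[flip]
  freqs$other_allele[flip] <- tmp
  freqs$freq[flip] <- 1 - freqs$freq[flip]
  first <- qc_filter_variants(ss$stats, freqs)
  second <- qc_filter_variants(first$stats, freqs)
  expect_equal(second$stats, first$stats)
  expect_equal(sum(second$report$removed), 0L)
})

test_that("clumping follows the greedy hand-run example", {
  # A best p; B correlated and nearby; C weak LD to both
  stats <- rbind(
    make_variant("A", pos = 1000000L, pval = 1e-10),
    make_variant("B", pos = 1010000L, pval = 1e-9),
    make_variant("C", pos = 1200000L, pval = 1e-8)
  )
  r2 <- matrix(0.05, 3, 3, dimnames = list(stats$rsid, stats$rsid))
  diag(r2) <- 1
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  out <- ld_clump(stats, r2)
  expect_setequal(out$rsid, c("A", "C"))

  single <- ld_clump(stats[1, ], r2)
  expect_equal(single$rsid, "A")

  weak <- stats
  weak$pval <- 1e-7
  expect_equal(nrow(ld_clump(weak, r2)), 0)
})

test_that("clumping ignores correlated variants outside the window", {
  stats <- rbind(
    make_variant("near", pos = 1e6, pval = 1e-10),
    make_variant("far", pos = as.integer(1e6 + 1.5e6), pval = 1e-9),
    make_variant("otherchr", chr = 2L, pos = 1e6, pval = 1e-9)
  )
  r2 <- matrix(1, 3, 3, dimnames = list(stats$rsid, stats$rsid))
  out <- ld_clump(stats, r2, window_kb = 1000)
  expect_setequal(out$rsid, c("near", "far", "otherchr"))
})

test_that("clumping matches brute-force greedy enumeration", {
  set.seed(2024)
  for (trial in 1:200) {
    m <- sample(2:12, 1)
    stats <- make_variant(sprintf("v%02d", 1:m),
                          chr = sample(1:2, m, replace = TRUE),
                          pos = sample.int(3e6, m),
                          pval = 10^runif(m, -12, -4))
    z <- matrix(rnorm(m * 5), 5)
    r2 <- cor(z)^2
    dimnames(r2) <- list(stats$rsid, stats$rsid)
    got <- ld_clump(stats, r2, p_threshold = 1e-7, r2_threshold = 0.3,
                    window_kb = 500)
    want <- brute_force_clump(stats, r2, p_threshold = 1e-7,
                              r2_threshold = 0.3, window_kb = 500)
    expect_identical(got$rsid, want)
  }
})

test_that("PRS is the dosage-weighted sum, standardized over the cohort", {
  geno <- rbind(c(0, 1, 2), c(2, 0, 1), c(1, 2, 0))
  colnames(geno) <- c("a", "b", "c")
  w <- c(a = 0.1, b = -0.2, c = 0.3)
  res <- compute_prs(geno, w)
  expect_equal(res$raw[1], 0.4)
  expect_equal(mean(res$standardized), 0, tolerance = 1e-10)
  expect_equal(var(res$standardized), 1, tolerance = 1e-6)

  doubled <- compute_prs(geno, 2 * w)
  expect_equal(doubled$raw, 2 * res$raw)
  expect_equal(doubled$standardized, res$standardized)

  expect_error(compute_prs(geno, c(a = 0, b = 0, c = 0)), "zero-variance")
  expect_warning(res2 <- compute_prs(geno, c(a = 0.1, zz = 1)), "absent")
  expect_equal(attr(res2, "n_missing_variants"), 1L)
  expect_error(suppressWarnings(compute_prs(geno, c(zz = 1))), "no weighted")
})

test_that("pipeline PRS associates positively with the genetic liability", {
  cfg <- truth_config("demo")
  ss <- generate_summary_stats(cfg, seed = 31)
  geno <- generate_genotypes(ss$stats, 10000, cfg, seed = 32)
  freqs <- cohort_freqs_from_stats(ss$stats,
                                   freq = attr(geno, "observed_freq"))
  qc <- qc_filter_variants(ss$stats, freqs)
  idx <- ld_clump(qc$stats, geno)
  expect_gt(nrow(idx), 0)
  prs <- compute_prs(geno, idx)
  liability <- drop(geno[, ss$truth$rsid[ss$truth$causal]] %*%
                      ss$truth$beta_true[ss$truth$causal])
  expect_gt(cor(prs$standardized, liability, method = "spearman"), 0.3)
})
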