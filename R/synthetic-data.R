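#' Simulate GWAS summary statistics for one cancer
#'
#' Draws a mixture of causal and null variants laid out in LD blocks along
#' the genome, with risk-allele frequencies uniform on the configured
#' range. Observed effect sizes are the true log-odds effects plus sampling
#' noise at the standard error implied by the GWAS sample size
#' (`se = 1/sqrt(2 N f (1-f))` for allele frequency `f`), and p-values are
#' the corresponding two-sided Wald p-values, so effect/SE/p triples are
#' internally consistent.
#'
#' @param config A [truth_config()].
#' @param cancer Cancer label; defaults to the first configured cancer.
#' @param seed Integer seed.
#' @param n_causal,n_null Variant counts; default from the config.
#' @return A list with `stats` (the summary-statistics table: `rsid`, `chr`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `raf`, `pval`, `info`)
#'   and `truth` (per-variant `rsid`, `causal`, `beta_true`).
#' @export
generate_summary_stats <- function(config, cancer = config$cancers[[1]],
                                   seed = config$seed,
                                   n_causal = config$snps_per_cancer,
                                   n_null = config$null_snps_per_cancer) {
  assert_that(n_causal > 0, "configuration error: causal SNP count must be > 0")
  assert_that(n_null >= 0, "configuration error: null SNP count must be >= 0")
  n <- n_causal + n_null
  with_seed(seed, {
    block_size <- config$ld$block_size
    n_blocks <- ceiling(n / block_size)
    block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n)]
    chr <- ((block - 1L) %% 22L) + 1L
    within <- stats::ave(seq_len(n), block, FUN = seq_along)
    # blocks on the same chromosome sit > 2 Mb apart so the clumping window
    # never spans two blocks
    block_on_chr <- stats::ave(block, chr, FUN = function(b)
      match(b, unique(b)))
    pos <- as.integer(1e6 + (block_on_chr - 1L) * 3e6 +
                        (within - 1L) * config$ld$spacing_bp)
    raf <- stats::runif(n, config$raf_range[1], config$raf_range[2])
    causal <- seq_len(n) %in% sample.int(n, n_causal)
    # risk-allele coding: causal effects centred on a positive mean
    beta_true <- ifelse(
      causal,
      stats::rnorm(n, config$effect_dist$mean, config$effect_dist$sd),
      0)
    se <- 1 / sqrt(2 * config$gwas_n * raf * (1 - raf))
    beta_hat <- beta_true + stats::rnorm(n, 0, se)
    pval <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300)
    pair <- replicate(n, sample(c("A", "C", "G", "T"), 2L))
    stats_df <- data.frame(
      rsid = sprintf("%s_snp%04d", cancer, seq_len(n)),
      chr = chr,
      pos = pos,
      effect_allele = pair[1L, ],
      other_allele = pair[2L, ],
      beta = beta_hat,
      raf = raf,
      pval = pval,
      info = stats::runif(n, 0.92, 1),
      stringsAsFactors = FALSE
    )
    list(
      stats = stats_df,
      truth = data.frame(rsid = stats_df$rsid, causal = causal,
                         beta_true = beta_true, stringsAsFactors = FALSE)
    )
  })
}

#' Simulate genotype dosages with block LD
#'
#' Dosages are sums of two haplotypes; each haplotype is generated by
#' thresholding a latent Gaussian whose within-block correlation decays
#' exponentially with base-pair distance (`exp(-d / decay_bp)`), so
#' marginal frequencies follow Hardy-Weinberg at the stated risk-allele
#' frequency while nearby variants are correlated. Blocks are delimited by
#' chromosome changes or position gaps above 1 Mb.
#'
#' @param stats Summary-statistics table (`rsid`, `chr`, `pos`, `raf`, ...).
#' @param n_subjects Number of subjects (rows).
#' @param config A [truth_config()] supplying `ld$decay_bp`.
#' @param seed Integer seed.
#' @return A numeric matrix (subjects x variants, colnames = rsid) with
#'   attributes `observed_freq` (per-variant dosage mean / 2) and
#'   `monomorphic` (rsids of all-zero or all-two columns).
#' @export
generate_genotypes <- function(stats, n_subjects, config,
                               seed = config$seed + 1L) {
  assert_that(is.data.frame(stats) && nrow(stats) > 0,
              "input error: empty summary-statistics table")
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  ord <- order(stats$chr, stats$pos)
  stats <- stats[ord, ]
  newblock <- c(TRUE, diff(stats$chr) != 0 | diff(stats$pos) > 1e6)
  block <- cumsum(newblock)
  geno <- matrix(0, n_subjects, nrow(stats),
                 dimnames = list(NULL, stats$rsid))
  with_seed(seed, {
    for (b in unique(block)) {
      idx <- which(block == b)
      d <- abs(outer(stats$pos[idx], stats$pos[idx], "-"))
      R <- exp(-d / config$ld$decay_bp)
      L <- chol(R)
      thr <- stats::qnorm(stats$raf[idx])
      for (h in 1:2) {
        z <- matrix(stats::rnorm(n_subjects * length(idx)), n_subjects) %*% L
        geno[, idx] <- geno[, idx] + (z < rep(thr, each = n_subjects))
      }
    }
  })
  freq <- colMeans(geno) / 2
  mono <- colnames(geno)[freq == 0 | freq == 1]
  if (length(mono)) {
    warning(length(mono), " monomorphic variant(s) in simulated genotypes")
  }
  attr(geno, "observed_freq") <- freq
  attr(geno, "monomorphic") <- mono
  geno
}

# draw risk-factor covariates for n subjects under the truth config;
# PRS columns come from `prs` when supplied (e.g. scored genotypes),
# otherwise they are drawn as independent standard normals
draw_covariates <- function(config, n, prs = NULL) {
  rf <- config$risk_factors
  if (is.null(prs)) {
    prs <- matrix(stats::rnorm(n * length(config$cancers)), n)
  }
  colnames(prs) <- paste0("prs_", config$cancers)
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = unlist(rf$smoking))
  ever <- smoking != "never"
  pack_years <- numeric(n)
  pack_years[ever] <- stats::rgamma(sum(ever), shape = rf$pack_years$shape,
                                    scale = rf$pack_years$mean /
                                      rf$pack_years$shape)
  fh <- sapply(unlist(rf$family_history), function(p)
    stats::rbinom(n, 1L, p))
  colnames(fh) <- paste0("fh_", names(rf$family_history))
  pcs <- matrix(stats::rnorm(n * 10L), n,
                dimnames = list(NULL, paste0("pc", 1:10)))
  out <- data.frame(
    bmi = stats::rnorm(n, rf$bmi$mean, rf$bmi$sd),
    smoking = factor(smoking, levels = c("never", "former", "current")),
    pack_years = pack_years,
    stringsAsFactors = FALSE
  )
  cbind(as.data.frame(prs), out, as.data.frame(fh), as.data.frame(pcs))
}

# true linear predictor beta' z, centred at its analytic population mean
true_linear_predictor <- function(config, covars) {
  beta <- config$log_hr
  prs_cols <- paste0("prs_", config$cancers)
  lp <- as.matrix(covars[, prs_cols]) %*% beta$prs +
    beta$bmi * covars$bmi +
    beta$smoking_former * (covars$smoking == "former") +
    beta$smoking_current * (covars$smoking == "current") +
    beta$pack_years * covars$pack_years +
    as.matrix(covars[, paste0("fh_", names(beta$family_history)),
                     drop = FALSE]) %*% beta$family_history
  drop(lp) - pcrs_truth_mean(config)
}

# invert the piecewise-constant cumulative hazard: given entry ages and
# per-subject relative risks rr, draw event ages T with
# Lambda0(T) - Lambda0(entry) = E / rr, E ~ Exp(1). Exact inverse-transform
# sampling on the piecewise-linear cumulative hazard; Inf when the target
# exceeds the grid.
draw_piecewise_event_age <- function(entry, rr, ages, rates) {
  knots <- c(ages, ages[length(ages)] + 1L)
  cum <- c(0, cumsum(rates))
  cum_at <- function(a) {
    k <- pmin(pmax(findInterval(a, knots), 1L), length(rates))
    cum[k] + (a - knots[k]) * rates[k]
  }
  target <- cum_at(entry) + stats::rexp(length(entry)) / rr
  k <- findInterval(target, cum, left.open = FALSE)
  k <- pmin(k, length(rates) + 1L)
  t_out <- rep(Inf, length(entry))
  inside <- k <= length(rates) & target < cum[length(cum)]
  ki <- k[inside]
  ki[ki < 1L] <- 1L
  t_out[inside] <- knots[ki] + (target[inside] - cum[ki]) / rates[ki]
  t_out
}

#' Simulate a left-truncated, right-censored cohort
#'
#' Subjects enrol at a uniform age on the configured enrollment range and
#' are followed until the earliest of: first in-scope cancer (the event),
#' an out-of-scope cancer, non-cancer death, or administrative censoring at
#' the end of follow-up. Event ages are drawn exactly by inverse-transform
#' sampling from the piecewise-constant hazard
#' \eqn{\lambda_0(t) \exp(\beta' z)}; death uses the configured age-indexed
#' rates and other-cancer censoring a constant rate, both independent of
#' the covariates (non-informative censoring). Risk-factor missingness is
#' injected completely at random at the configured per-variable rates.
#'
#' @param config A [truth_config()].
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param prs Optional n x n_cancers matrix of standardized per-cancer PRS
#'   values (e.g. scored from simulated genotypes); drawn as standard
#'   normals when omitted.
#' @param inject_missing Inject missing values per the config rates
#'   (default `TRUE`).
#' @return A data.frame with columns `subject_id`, `sex`, `entry_age`,
#'   `exit_age`, `event`, `cancer_type`, `prs_*`, `bmi`, `smoking`,
#'   `pack_years`, `fh_*`, `pc1`..`pc10`, carrying the true centred linear
#'   predictor in `attr(, "true_pcrs")`.
#' @export
generate_cohort <- function(config, n, seed = config$seed + 2L, prs = NULL,
                            inject_missing = TRUE) {
  assert_that(n >= 1, "n must be >= 1")
  horizon <- config$enrollment[2] + config$followup[2]
  assert_that(horizon <= max(config$baseline_ages) + 1L,
              "baseline hazard must cover enrollment plus follow-up")
  assert_that(any(config$baseline_rates > 0) || all(is.finite(config$followup)),
              "simulation error: zero hazard with infinite horizon")
  with_seed(seed, {
    covars <- draw_covariates(config, n, prs = prs)
    lp <- true_linear_predictor(config, covars)
    entry <- stats::runif(n, config$enrollment[1], config$enrollment[2])
    admin <- entry + stats::runif(n, config$followup[1], config$followup[2])
    t_event <- draw_piecewise_event_age(entry, exp(lp),
                                        config$baseline_ages,
                                        config$baseline_rates)
    t_death <- draw_piecewise_event_age(entry, rep(1, n),
                                        config$baseline_ages,
                                        config$death_rates)
    t_other <- if (config$other_cancer_rate > 0) {
      entry + stats::rexp(n, config$other_cancer_rate)
    } else {
      rep(Inf, n)
    }
    exit <- pmin(t_event, t_death, t_other, admin)
    event <- as.integer(t_event <= exit & is.finite(t_event))
    shares <- unlist(config$cancer_share)[config$cancers]
    cancer_type <- rep(NA_character_, n)
    if (any(event == 1L)) {
      cancer_type[event == 1L] <- sample(config$cancers, sum(event),
                                         replace = TRUE,
                                         prob = shares / sum(shares))
    }
    out <- cbind(
      data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                 sex = config$sex,
                 entry_age = entry, exit_age = exit,
                 event = event, cancer_type = cancer_type,
                 stringsAsFactors = FALSE),
      covars
    )
    if (inject_missing) {
      m <- config$missingness
      out$pack_years[stats::runif(n) < m$pack_years] <- NA_real_
      out$bmi[stats::runif(n) < m$bmi] <- NA_real_
      out$smoking[stats::runif(n) < m$smoking] <- NA
      fh_cols <- grep("^fh_", names(out))
      out[stats::runif(n) < m$family_history, fh_cols] <- NA
    }
    attr(out, "true_pcrs") <- lp
    out
  })
}

#' Marginal age-specific incidence implied by the truth
#'
#' Computes, per 1-year age stratum, the event rate a registry would
#' observe in the simulated population: the baseline hazard times the mean
#' relative risk among subjects still cancer-free at that age. The mean is
#' taken over a large Monte-Carlo draw of covariates whose survival weights
#' are depleted stratum by stratum from the youngest age upward, so the
#' depletion of susceptibles is reflected exactly as a registry would see
#' it. With all true effects zero the output equals the baseline hazard.
#'
#' @param config A [truth_config()].
#' @param n_ref Monte-Carlo draw size (default 200000).
#' @param seed Integer seed.
#' @return A data.frame `age`, `sex`, `rate` over the configured age grid.
#' @export
generate_incidence_table <- function(config, n_ref = 200000L,
                                     seed = config$seed + 3L) {
  with_seed(seed, {
    covars <- draw_covariates(config, n_ref)
    rr <- exp(true_linear_predictor(config, covars))
    w <- rep(1, n_ref)
    rates <- numeric(length(config$baseline_ages))
    for (k in seq_along(config$baseline_ages)) {
      mean_rr <- sum(w * rr) / sum(w)
      rates[k] <- config$baseline_rates[k] * mean_rr
      w <- w * exp(-config$baseline_rates[k] * rr)
    }
    data.frame(age = config$baseline_ages, sex = config$sex, rate = rates,
               stringsAsFactors = FALSE)
  })
}

#' Census-like population age weights
#'
#' Population weight per 1-year age stratum, declining geometrically with
#' age at the configured slope and normalized to sum to one over the grid.
#'
#' @param config A [truth_config()].
#' @return A data.frame `age`, `sex`, `weight`.
#' @export
generate_age_weights <- function(config) {
  ages <- config$baseline_ages
  w <- exp(config$age_weight_slope * (ages - min(ages)))
  data.frame(age = ages, sex = config$sex, weight = w / sum(w),
             stringsAsFactors = FALSE)
}
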