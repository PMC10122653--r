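# Shared fixtures built in code: tiny summary-statistics tables, hand-sized
# cohorts, and independent brute-force oracles used against the package's
# implementations.

# a summary-stats row with overridable fields
make_variant <- function(rsid, chr = 1L, pos = 1000L, ea = "A", oa = "G",
                         beta = 0.1, raf = 0.3, pval = 1e-9, info = 0.99) {
  data.frame(rsid = rsid, chr = chr, pos = pos, effect_allele = ea,
             other_allele = oa, beta = beta, raf = raf, pval = pval,
             info = info, stringsAsFactors = FALSE)
}

cohort_freqs_from_stats <- function(stats, freq = stats$raf) {
  data.frame(rsid = stats$rsid, effect_allele = stats$effect_allele,
             other_allele = stats$other_allele, freq = freq,
             stringsAsFactors = FALSE)
}

# minimal survival cohort (already complete cases)
make_survival_cohort <- function(entry, exit, event, scores = NULL) {
  df <- data.frame(subject_id = seq_along(entry), sex = "female",
                   entry_age = entry, exit_age = exit, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(scores)) df$score <- scores
  df
}

# independent greedy-clumping oracle: plain loops on an explicit r2 matrix
brute_force_clump <- function(stats, r2_matrix, p_threshold, r2_threshold,
                              window_kb) {
  cand <- stats[stats$pval <= p_threshold, , drop = FALSE]
  ord <- order(cand$pval, cand$chr, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  chosen <- character(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    chosen <- c(chosen, cand$rsid[i])
    if (i == nrow(cand)) break
    for (j in seq(i + 1L, nrow(cand))) {
      if (!alive[j]) next
      same_chr <- cand$chr[j] == cand$chr[i]
      near <- abs(cand$pos[j] - cand$pos[i]) <= window_kb * 1000
      if (same_chr && near &&
          r2_matrix[cand$rsid[i], cand$rsid[j]] >= r2_threshold) {
        alive[j] <- FALSE
      }
    }
  }
  chosen
}

# exhaustive concordance enumeration with left truncation: pair (i, j) is
# comparable when the earlier exit is an event and the other subject is
# under observation at that age
brute_force_concordance <- function(entry, exit, event, scores) {
  conc <- 0
  comp <- 0
  n <- length(exit)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- i
      b <- j
      if (exit[b] < exit[a]) {
        a <- j
        b <- i
      }
      if (exit[a] == exit[b]) next  # continuous fixtures: skip exact ties
      if (event[a] != 1L) next
      if (entry[b] >= exit[a]) next  # b not yet under observation
      comp <- comp + 1
      if (scores[a] > scores[b]) {
        conc <- conc + 1
      } else if (scores[a] == scores[b]) {
        conc <- conc + 0.5
      }
    }
  }
  list(concordance = conc / comp, comparable = comp)
}

# plain rank-sum AUC (cases vs controls), the censoring-free oracle
rank_sum_auc <- function(case_scores, control_scores) {
  s <- 0
  for (x in case_scores) {
    s <- s + sum(x > control_scores) + 0.5 * sum(x == control_scores)
  }
  s / (length(case_scores) * length(control_scores))
}

# constant-hazard baseline over an age span, for closed-form risk checks
make_constant_baseline <- function(rate, ages = 40:89) {
  structure(list(age = ages, lambda0 = rep(rate, length(ages)),
                 deplete = FALSE), class = "baseline_hazard")
}

make_reference <- function(pcrs) {
  structure(list(pcrs = pcrs, mean = mean(pcrs), sd = stats::sd(pcrs),
                 seed = NA), class = "reference_distribution")
}
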