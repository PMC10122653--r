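COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Quality-control filtering of GWAS variants against a scoring cohort
#'
#' Applies the variant filters in a fixed order, attributing each removed
#' variant to the first rule it triggers, so audit counts are
#' deterministic: (1) minor allele frequency (MAF) < 0.01 in the summary
#' statistics; (2) strand-ambiguous variants (A/T or G/C pairs) with
#' MAF > 0.40 (strict: MAF exactly 0.40 is retained); (3) variants absent
#' from the cohort frequency table ("unmatchable", warned); (4) MAF
#' difference >= 0.10 between summary statistics and cohort, computed on
#' the minor allele so the comparison is orientation-invariant; (5) allele
#' mismatches, resolved where possible by a strand flip (complement both
#' alleles, effect unchanged) or a dosage flip (swap alleles, negate the
#' effect, reflect the frequency), else removed; (6) imputation info
#' score < 0.90. Retained records are returned with alleles aligned to the
#' cohort orientation, so the filter is idempotent.
#'
#' @param stats Summary-statistics table (see [read_summary_stats()]).
#' @param cohort_freqs data.frame `rsid`, `effect_allele`, `other_allele`,
#'   `freq` — the cohort's dosage-allele frequency per variant.
#' @param maf_min,ambiguous_maf_max,maf_diff_max,info_min Rule thresholds.
#' @return A list with `stats` (filtered, allele-aligned table) and
#'   `report` (a `qc_report`: per-rule removal counts and the retained
#'   count).
#' @export
qc_filter_variants <- function(stats, cohort_freqs,
                               maf_min = 0.01, ambiguous_maf_max = 0.40,
                               maf_diff_max = 0.10, info_min = 0.90) {
  n <- nrow(stats)
  rule <- rep(NA_character_, n)
  maf <- pmin(stats$raf, 1 - stats$raf)

  rule[is.na(rule) & maf < maf_min] <- "maf"
  ambig <- is_ambiguous_pair(stats$effect_allele, stats$other_allele)
  rule[is.na(rule) & ambig & maf > ambiguous_maf_max] <- "ambiguous"

  m <- match(stats$rsid, cohort_freqs$rsid)
  rule[is.na(rule) & is.na(m)] <- "unmatchable"
  if (any(rule == "unmatchable", na.rm = TRUE)) {
    warning(sum(rule == "unmatchable", na.rm = TRUE),
            " variant(s) missing from the cohort frequency table")
  }

  cf <- cohort_freqs[m, ]
  cohort_maf <- pmin(cf$freq, 1 - cf$freq)
  rule[is.na(rule) & abs(maf - cohort_maf) >= maf_diff_max] <- "maf_diff"

  # allele alignment relative to the cohort orientation
  ea <- stats$effect_allele
  oa <- stats$other_allele
  direct <- ea == cf$effect_allele & oa == cf$other_allele
  swap <- ea == cf$other_allele & oa == cf$effect_allele
  strand <- COMPLEMENT[ea] == cf$effect_allele & COMPLEMENT[oa] == cf$other_allele
  strand_swap <- COMPLEMENT[ea] == cf$other_allele &
    COMPLEMENT[oa] == cf$effect_allele
  resolvable <- direct | swap | strand | strand_swap
  rule[is.na(rule) & !resolvable] <- "allele_mismatch"

  rule[is.na(rule) & stats$info < info_min] <- "info"

  keep <- is.na(rule)
  out <- stats[keep, , drop = FALSE]
  # one interpretation per variant, letter-exact matches first: for
  # ambiguous pairs a swap and a strand flip are indistinguishable, so the
  # dosage-flip reading wins
  interp <- ifelse(direct, "none",
                   ifelse(swap, "swap",
                          ifelse(strand, "strand",
                                 ifelse(strand_swap, "both", "fail"))))
  do_strand <- keep & interp %in% c("strand", "both")
  do_swap <- keep & interp %in% c("swap", "both")
  ks <- do_strand[keep]
  out$effect_allele[ks] <- COMPLEMENT[out$effect_allele[ks]]
  out$other_allele[ks] <- COMPLEMENT[out$other_allele[ks]]
  kw <- do_swap[keep]
  tmp <- out$effect_allele[kw]
  out$effect_allele[kw] <- out$other_allele[kw]
  out$other_allele[kw] <- tmp
  out$beta[kw] <- -out$beta[kw]
  out$raf[kw] <- 1 - out$raf[kw]

  counts <- vapply(c("maf", "ambiguous", "unmatchable", "maf_diff",
                     "allele_mismatch", "info"),
                   function(r) sum(rule == r, na.rm = TRUE), integer(1))
  report <- structure(
    list(n_input = n, removed = counts, n_retained = sum(keep),
         n_strand_flipped = sum(do_strand), n_dosage_flipped = sum(do_swap)),
    class = "qc_report")
  list(stats = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$n_input, "variants in,", x$n_retained, "retained\n")
  for (r in names(x$removed)) cat(sprintf("  removed [%s]: %d\n", r,
                                          x$removed[[r]]))
  cat("  strand-flipped:", x$n_strand_flipped,
      " dosage-flipped:", x$n_dosage_flipped, "\n")
  invisible(x)
}

# normalize an LD source into a pairwise-r2 lookup over a stats table:
# accepts a genotype dosage matrix (r2 = squared Pearson correlation of
# dosage columns), a precomputed r2 matrix with rsid dimnames, or a
# function(id1, id2)
make_r2_provider <- function(ld) {
  if (is.function(ld)) return(ld)
  if (is.matrix(ld) && !is.null(colnames(ld)) &&
      (is.null(rownames(ld)) || nrow(ld) != ncol(ld) ||
       !identical(rownames(ld), colnames(ld)))) {
    geno <- ld
    return(function(id1, id2) {
      suppressWarnings(stats::cor(geno[, id1], geno[, id2]))^2
    })
  }
  r2m <- ld
  function(id1, id2) r2m[id1, id2]
}

#' Greedy LD clumping at a fixed p-value threshold
#'
#' Selects index variants greedily: among variants with
#' `pval <= p_threshold`, repeatedly take the smallest remaining p-value
#' (ties broken by chromosome then position) as an index and discard every
#' remaining variant on the same chromosome within `window_kb` kilobases
#' on either side whose squared correlation with the index is at least
#' `r2_threshold`. The returned index set therefore has all pairwise
#' r-squared below the threshold within the window.
#'
#' @param stats Filtered summary-statistics table.
#' @param ld LD source: a genotype dosage matrix with rsid colnames (r2 is
#'   the squared Pearson correlation of dosage columns), a precomputed
#'   r2 matrix with rsid dimnames, or a `function(id1, id2)`.
#' @param p_threshold,r2_threshold,window_kb Clumping parameters; defaults
#'   5e-8, 0.1, 1000.
#' @return The rows of `stats` for the index variants (possibly 0 rows),
#'   ordered by selection.
#' @export
ld_clump <- function(stats, ld, p_threshold = 5e-8, r2_threshold = 0.1,
                     window_kb = 1000) {
  if (nrow(stats) == 0L) return(stats)
  r2 <- make_r2_provider(ld)
  cand <- stats[stats$pval <= p_threshold, , drop = FALSE]
  cand <- cand[order(cand$pval, cand$chr, cand$pos), , drop = FALSE]
  picked <- integer(0)
  window_bp <- window_kb * 1000
  while (nrow(cand) > 0L) {
    idx <- cand[1L, ]
    picked <- c(picked, match(idx$rsid, stats$rsid))
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    near <- cand$chr == idx$chr & abs(cand$pos - idx$pos) <= window_bp
    if (any(near)) {
      drop_r2 <- vapply(cand$rsid[near], function(id)
        r2(idx$rsid, id) >= r2_threshold, logical(1))
      cand <- cand[!(near & replace(logical(nrow(cand)), which(near),
                                    drop_r2)), , drop = FALSE]
    }
  }
  stats[picked, , drop = FALSE]
}

#' Weighted-sum polygenic risk score
#'
#' Scores each subject as the dosage-weighted sum of effect sizes,
#' `PRS_j = sum_i beta_i * SNP_ij`, over the index variants, then
#' standardizes to zero mean and unit variance over the scored cohort.
#'
#' @param genotypes Subjects x variants dosage matrix (colnames = rsid).
#' @param weights Named numeric vector of effect sizes keyed by rsid, or a
#'   data.frame with `rsid` and `beta` columns (e.g. [ld_clump()] output).
#' @return data.frame `subject`, `raw`, `standardized` with attribute
#'   `n_missing_variants` (weighted variants absent from the genotypes).
#' @export
compute_prs <- function(genotypes, weights) {
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$beta, weights$rsid)
  }
  present <- names(weights) %in% colnames(genotypes)
  if (!all(present)) {
    warning(sum(!present), " weighted variant(s) absent from genotypes; dropped")
  }
  assert_that(any(present), "no weighted variants present in genotypes")
  w <- weights[present]
  raw <- drop(genotypes[, names(w), drop = FALSE] %*% w)
  s <- stats::sd(raw)
  assert_that(s > 0, "zero-variance raw PRS: standardization undefined")
  out <- data.frame(
    subject = rownames(genotypes) %||% seq_len(nrow(genotypes)),
    raw = raw,
    standardized = (raw - mean(raw)) / s
  )
  attr(out, "n_missing_variants") <- sum(!present)
  out
}
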