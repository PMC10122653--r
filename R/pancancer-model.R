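#' Default covariate specification for the multicancer model
#'
#' Detects the modelling covariates present in a cohort table: per-cancer
#' PRS columns (`prs_*`), BMI, smoking status, pack-years, family-history
#' indicators (`fh_*`), and the first ten principal components
#' (`pc1`..`pc10`). The `variant` argument selects the covariate subsets
#' used for model comparison.
#'
#' @param cohort A cohort data.frame.
#' @param variant `"combined"` (all of the above), `"risk-factors-only"`
#'   (no PRS columns), or `"prs-only"` (PRS and principal components only).
#' @return Character vector of column names.
#' @export
model_covariates <- function(cohort, variant = c("combined",
                                                 "risk-factors-only",
                                                 "prs-only")) {
  variant <- match.arg(variant)
  prs <- grep("^prs_", names(cohort), value = TRUE)
  fh <- grep("^fh_", names(cohort), value = TRUE)
  pcs <- intersect(paste0("pc", 1:10), names(cohort))
  rf <- intersect(c("bmi", "smoking", "pack_years"), names(cohort))
  switch(variant,
         "combined" = c(prs, rf, fh, pcs),
         "risk-factors-only" = c(rf, fh, pcs),
         "prs-only" = c(prs, pcs))
}

#' Complete-case filtering
#'
#' Drops every subject with a missing value in any required covariate and
#' reports the removal count, mirroring a complete-case analysis.
#'
#' @param cohort Cohort data.frame.
#' @param required Covariate columns that must be non-missing; defaults to
#'   the combined-model covariates.
#' @return List with `cohort` (filtered) and `n_removed`.
#' @export
filter_complete_cases <- function(cohort,
                                  required = model_covariates(cohort)) {
  keep <- stats::complete.cases(cohort[, required, drop = FALSE])
  assert_that(any(keep), "no complete cases remain")
  list(cohort = cohort[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Seeded 2/3 - 1/3 train/test split
#'
#' Disjoint, exhaustive partition by a seeded shuffle; the training share
#' is within one subject of 2/3.
#'
#' @param cohort Cohort data.frame (>= 3 rows).
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 2/3).
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(cohort, seed = 1L, train_frac = 2 / 3) {
  n <- nrow(cohort)
  assert_that(n >= 3, "need at least 3 subjects to split")
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(n * train_frac)
  list(train = cohort[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = cohort[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}

# expand covariate columns (factor contrasts for smoking) into a numeric
# design matrix with stable column order
build_design <- function(cohort, covariates) {
  missing_cols <- setdiff(covariates, names(cohort))
  assert_that(length(missing_cols) == 0,
              paste("missing covariate column(s):",
                    paste(missing_cols, collapse = ", ")))
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(f, data = cohort[, covariates, drop = FALSE])
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Fit the sex-specific multicancer proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with age as the timescale: each
#' subject contributes a left-truncated interval `(entry_age, exit_age]`,
#' so the risk set at an event age contains exactly the subjects under
#' observation at that age. The event is the first in-scope cancer; every
#' other exit (other cancer, death, administrative end of follow-up) is a
#' censoring. Tied event ages use Efron's approximation.
#'
#' @param train Training cohort (complete cases).
#' @param covariates Covariate columns; defaults to the combined model.
#' @param include_pcs_in_pcrs Should principal components contribute to
#'   the pan-cancer risk score linear predictor? Default `FALSE`: they are
#'   fitted as adjustment covariates only.
#' @return A `hazard_model`: coefficients with standard errors, the
#'   training PCRS distribution (mean, sd, and scores for percentile
#'   lookup), and convergence diagnostics.
#' @export
fit_hazard_model <- function(train, covariates = model_covariates(train),
                             include_pcs_in_pcrs = FALSE) {
  assert_that(all(train$exit_age > train$entry_age),
              "left-truncation violated: exit age must exceed entry age")
  assert_that(sum(train$event) >= 1, "no events in the training cohort")
  x <- build_design(train, covariates)
  fit <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ x,
    data = data.frame(entry_age = train$entry_age,
                      exit_age = train$exit_age,
                      event = train$event),
    ties = "efron")
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)  # coxph prefixes matrix-covariate names
  if (any(!is.finite(beta)) || max(abs(beta)) > 15) {
    stop("model did not converge (possible complete separation); ",
         "largest |coefficient| = ", signif(max(abs(beta)), 3),
         call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(beta)
  pcrs_terms <- if (include_pcs_in_pcrs) {
    names(beta)
  } else {
    setdiff(names(beta), paste0("pc", 1:10))
  }
  train_pcrs <- drop(x[, pcrs_terms, drop = FALSE] %*% beta[pcrs_terms])
  assert_that(stats::sd(train_pcrs) > 0, "degenerate PCRS (zero variance)")
  structure(list(
    coef = beta,
    se = se,
    covariates = covariates,
    pcrs_terms = pcrs_terms,
    design_means = colMeans(x),
    pcrs_mean = mean(train_pcrs),
    pcrs_sd = stats::sd(train_pcrs),
    train_pcrs = sort(train_pcrs),
    n_train = nrow(train),
    n_events = sum(train$event),
    iter = fit$iter,
    loglik = fit$loglik
  ), class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("<hazard_model>", length(x$coef), "coefficients,",
      x$n_events, "events /", x$n_train, "subjects\n")
  cat("  PCRS over", length(x$pcrs_terms), "terms; mean",
      sprintf("%.4f", x$pcrs_mean), "sd", sprintf("%.4f", x$pcrs_sd), "\n")
  invisible(x)
}

#' Pan-cancer risk score for a cohort
#'
#' Computes the PCRS as the fitted-coefficient-weighted sum of each
#' subject's risk-factor covariates (principal components excluded unless
#' the model was built with `include_pcs_in_pcrs = TRUE`), plus each
#' score's percentile within the training distribution.
#'
#' @param model A [fit_hazard_model()] result.
#' @param cohort Cohort with all model covariates.
#' @return data.frame `subject_id`, `pcrs`, `percentile` (0-100, monotone
#'   in the score).
#' @export
compute_pcrs <- function(model, cohort) {
  x <- build_design(cohort, model$covariates)
  assert_that(all(model$pcrs_terms %in% colnames(x)),
              "cohort design lacks model terms")
  pcrs <- drop(x[, model$pcrs_terms, drop = FALSE] %*%
                 model$coef[model$pcrs_terms])
  pct <- 100 * findInterval(pcrs, model$train_pcrs) / length(model$train_pcrs)
  data.frame(subject_id = cohort$subject_id %||% seq_len(nrow(cohort)),
             pcrs = pcrs, percentile = pct)
}
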