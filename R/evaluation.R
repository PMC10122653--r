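#' Standardized hazard ratio of a risk score
#'
#' Rescales the score to unit standard deviation over the evaluation
#' cohort and fits a single-covariate proportional-hazards model on the
#' age timescale (left-truncated at entry age). Returns the hazard ratio
#' per 1 SD with its Wald 95% confidence interval.
#'
#' @param cohort Cohort with `entry_age`, `exit_age`, `event`.
#' @param scores Numeric risk score per subject (same order as `cohort`).
#' @return List: `hr`, `lower`, `upper`, `log_hr`, `se`, `n_events`.
#' @export
standardized_hr <- function(cohort, scores) {
  assert_that(sum(cohort$event) >= 1, "no events in the evaluation cohort")
  assert_that(length(scores) == nrow(cohort),
              "scores and cohort must align")
  s <- stats::sd(scores)
  assert_that(s > 0, "score has zero variance")
  z <- scores / s
  fit <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ z,
    data = data.frame(entry_age = cohort$entry_age,
                      exit_age = cohort$exit_age,
                      event = cohort$event, z = z),
    ties = "efron")
  b <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))[1]
  list(hr = exp(b), lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se),
       log_hr = b, se = unname(se), n_events = sum(cohort$event))
}

#' Harrell's concordance index with left truncation
#'
#' Fraction of comparable subject pairs whose score ordering agrees with
#' their event ordering. With age as the timescale, a pair is comparable
#' only if the earlier of the two exit ages is an event age at which both
#' subjects are under observation (entry before that age), per the usual
#' censored-data rules; tied scores count one half. Computed via
#' [survival::concordance()] on the counting-process form, which applies
#' exactly these risk-set rules.
#'
#' @param cohort Cohort with `entry_age`, `exit_age`, `event`.
#' @param scores Numeric risk score per subject.
#' @return Concordance in `[0, 1]`.
#' @export
harrells_c <- function(cohort, scores) {
  assert_that(length(scores) == nrow(cohort),
              "scores and cohort must align")
  fit <- survival::concordance(
    survival::Surv(entry_age, exit_age, event) ~ score,
    data = data.frame(entry_age = cohort$entry_age,
                      exit_age = cohort$exit_age,
                      event = cohort$event, score = scores),
    reverse = TRUE)
  n_pairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  assert_that(n_pairs > 0, "no comparable pairs")
  unname(fit$concordance)
}

#' Cumulative/dynamic AUC at a follow-up horizon
#'
#' Discrimination for events within `horizon_years` of study entry:
#' cases are subjects with an event within the horizon, controls are
#' subjects still at risk (event-free and uncensored) beyond it. Subjects
#' censored before the horizon contribute through inverse-probability-of-
#' censoring weights (IPCW): each case is weighted by the inverse
#' Kaplan-Meier censoring survival just before its event time, each
#' control by the inverse censoring survival at the horizon. With no
#' censoring before the horizon, this reduces exactly to the empirical
#' rank-sum AUC of cases versus controls; tied scores count one half.
#'
#' @param cohort Cohort with `entry_age`, `exit_age`, `event`.
#' @param scores Numeric risk score per subject.
#' @param horizon_years Horizon measured from entry (default 5).
#' @return AUC in `[0, 1]`.
#' @export
auc_at_horizon <- function(cohort, scores, horizon_years = 5) {
  assert_that(length(scores) == nrow(cohort),
              "scores and cohort must align")
  u <- cohort$exit_age - cohort$entry_age
  d <- cohort$event
  is_case <- d == 1 & u <= horizon_years
  is_ctrl <- u > horizon_years
  assert_that(any(is_case), "no events by the horizon")
  assert_that(any(is_ctrl), "no subjects at risk beyond the horizon")
  # censoring Kaplan-Meier on follow-up time (censoring as the "event")
  km <- survival::survfit(survival::Surv(u, 1 - d) ~ 1)
  G <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  g_case <- vapply(u[is_case], function(t) G(t - 1e-9), numeric(1))
  g_ctrl <- G(horizon_years)
  assert_that(all(g_case > 0) && g_ctrl > 0,
              "censoring weights degenerate at the horizon")
  w_case <- 1 / g_case
  s_case <- scores[is_case]
  s_ctrl <- scores[is_ctrl]
  # controls share one weight, so it cancels across the control margin
  num <- sum(vapply(seq_along(s_case), function(i) {
    w_case[i] * (sum(s_case[i] > s_ctrl) + 0.5 * sum(s_case[i] == s_ctrl))
  }, numeric(1)))
  num / (sum(w_case) * length(s_ctrl))
}

#' Fit and evaluate the three model variants
#'
#' Fits the combined, risk-factors-only, and PRS-only models on the
#' training split and evaluates each on the held-out test split:
#' standardized hazard ratio of the PCRS, Harrell's C, and the
#' cumulative/dynamic AUC at the horizon.
#'
#' @param cohort Complete-case cohort table.
#' @param seed Seed for the train/test split.
#' @param variants Model variants to fit (default all three).
#' @param horizon_years AUC horizon (default 5).
#' @param include_pcs_in_pcrs Passed to [fit_hazard_model()].
#' @return A data.frame with one row per variant: `model`, `sex`, `hr`,
#'   `hr_lower`, `hr_upper`, `c_index`, `auc`, `n_train`, `n_test`,
#'   `n_events_test`; fitted models in `attr(, "models")`.
#' @export
compare_models <- function(cohort, seed = 1L,
                           variants = c("combined", "risk-factors-only",
                                        "prs-only"),
                           horizon_years = 5,
                           include_pcs_in_pcrs = FALSE) {
  parts <- split_train_test(cohort, seed)
  models <- list()
  rows <- lapply(variants, function(v) {
    covs <- model_covariates(parts$train, v)
    fit <- fit_hazard_model(parts$train, covs,
                            include_pcs_in_pcrs = include_pcs_in_pcrs)
    models[[v]] <<- fit
    scores <- compute_pcrs(fit, parts$test)$pcrs
    hr <- standardized_hr(parts$test, scores)
    data.frame(model = v,
               sex = parts$test$sex[1] %||% NA_character_,
               hr = hr$hr, hr_lower = hr$lower, hr_upper = hr$upper,
               c_index = harrells_c(parts$test, scores),
               auc = auc_at_horizon(parts$test, scores, horizon_years),
               n_train = nrow(parts$train), n_test = nrow(parts$test),
               n_events_test = sum(parts$test$event),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Bootstrap confidence interval for a test-set metric
#'
#' Percentile bootstrap over subjects (seeded, 200 resamples by default)
#' for [harrells_c()] or [auc_at_horizon()].
#'
#' @param cohort Evaluation cohort.
#' @param scores Risk scores aligned with `cohort`.
#' @param metric A function `(cohort, scores) -> numeric`.
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @return List: `estimate`, `lower`, `upper` (2.5/97.5 percentiles).
#' @export
boot_metric_ci <- function(cohort, scores, metric = harrells_c,
                           n_boot = 200L, seed = 1L) {
  est <- metric(cohort, scores)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(nrow(cohort), replace = TRUE)
    tryCatch(metric(cohort[i, , drop = FALSE], scores[i]),
             error = function(e) NA_real_)
  }, numeric(1)))
  qs <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2])
}
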