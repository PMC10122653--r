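#' Reference PCRS distribution for absolute-risk calibration
#'
#' Draws a reference sample representative of the modelled population:
#' normal draws with the training-cohort PCRS mean and standard deviation
#' (10,000 by default). The draw is checked against its targets to within
#' four standard errors.
#'
#' @param model A `hazard_model`, or `NULL` if `mean`/`sd` given directly.
#' @param mean,sd Target PCRS moments.
#' @param n Number of draws (default 10000).
#' @param seed Integer seed.
#' @return A `reference_distribution`: list with `pcrs`, `mean`, `sd`,
#'   `seed`.
#' @export
reference_distribution <- function(model = NULL, mean = model$pcrs_mean,
                                   sd = model$pcrs_sd, n = 10000L,
                                   seed = 1L) {
  draws <- with_seed(seed, stats::rnorm(n, mean, sd))
  assert_that(abs(base::mean(draws) - mean) < 4 * sd / sqrt(n),
              "reference sample mean outside 4 SE of target")
  assert_that(abs(stats::sd(draws) - sd) < 4 * sd / sqrt(2 * n),
              "reference sample sd outside 4 SE of target")
  structure(list(pcrs = draws, mean = mean, sd = sd, seed = seed),
            class = "reference_distribution")
}

#' Shift an incidence table forward by one year of age
#'
#' The rate looked up for age `a` becomes the input rate at age `a + 1`;
#' the final age stratum reuses its own rate (boundary convention). This
#' accounts for a screening test performed at the start of a 12-month
#' follow-up window: risk over the year ahead is driven by next year's
#' registry rate.
#'
#' @param table Incidence data.frame `age`, `sex`, `rate` with contiguous
#'   1-year strata.
#' @return The shifted table, same shape.
#' @export
shift_incidence <- function(table) {
  out <- table
  for (s in unique(table$sex)) {
    i <- which(table$sex == s)
    i <- i[order(table$age[i])]
    assert_that(all(diff(table$age[i]) == 1L),
                "incidence ages must be contiguous integers")
    r <- table$rate[i]
    out$rate[i] <- c(r[-1L], r[length(r)])
  }
  out
}

#' Calibrate an age-indexed baseline hazard to marginal incidence rates
#'
#' For each 1-year age stratum `t`, solves
#' \eqn{\lambda_0(t) = \lambda_m(t) / E_w[\exp(PCRS)]}, where the
#' expectation runs over the reference draws. With
#' `deplete = TRUE` (the default) each draw is weighted by its
#' model-implied probability of remaining cancer-free up to `t`, updated
#' stratum by stratum from the youngest age upward — the
#' depletion-of-susceptibles correction, under which high-risk draws leave
#' the at-risk pool faster and the implied baseline hazard at older ages
#' rises relative to the naive ratio. With `deplete = FALSE` the weights
#' stay uniform (the simple mean-relative-risk ratio).
#'
#' @param incidence Incidence data.frame `age`, `rate` (single sex).
#' @param reference A [reference_distribution()].
#' @param deplete Apply the depletion-of-susceptibles correction.
#' @return A `baseline_hazard`: list with `age` and `lambda0`.
#' @export
calibrate_baseline <- function(incidence, reference, deplete = TRUE) {
  i <- order(incidence$age)
  ages <- incidence$age[i]
  lam_m <- incidence$rate[i]
  assert_that(all(lam_m >= 0), "incidence rates must be non-negative")
  r <- exp(reference$pcrs)
  w <- rep(1, length(r))
  lambda0 <- numeric(length(ages))
  for (k in seq_along(ages)) {
    mean_rr <- sum(w * r) / sum(w)
    lambda0[k] <- lam_m[k] / mean_rr
    if (!is.finite(lambda0[k]) || lambda0[k] * mean_rr > 1) {
      stop("calibration implies a stratum event probability > 1 at age ",
           ages[k], call. = FALSE)
    }
    if (deplete) w <- w * exp(-lambda0[k] * r)
  }
  structure(list(age = ages, lambda0 = lambda0, deplete = deplete),
            class = "baseline_hazard")
}

#' Absolute risk over a short window
#'
#' Cause-specific cumulative risk of a first in-scope cancer over
#' `[a, a + tau]`:
#' \eqn{x = 1 - \exp(-\sum_t \lambda_0(t)\, e^{PCRS}\, \Delta t)}, with
#' \eqn{\Delta t} the fraction of each 1-year stratum inside the window
#' (linear proration, so 11-month windows split strata). Competing
#' non-cancer mortality is not subtracted for these short windows; set
#' `mortality` to an age-indexed rate vector aligned with the baseline to
#' enable a life-table-style adjustment for long (e.g. 10-year)
#' trajectories.
#'
#' @param baseline A [calibrate_baseline()] result.
#' @param pcrs PCRS value(s); vectorized.
#' @param start_age Window start age (years, may be fractional).
#' @param window_months Window length in months (> 0).
#' @param mortality Optional per-stratum competing mortality rates
#'   (same age grid as `baseline`); default `NULL` (no adjustment).
#' @return Numeric vector of risks in `[0, 1]`, same length as `pcrs`.
#' @export
absolute_risk <- function(baseline, pcrs, start_age, window_months = 12,
                          mortality = NULL) {
  assert_that(window_months > 0, "window must cover at least part of a month")
  tau <- window_months / 12
  a0 <- start_age
  a1 <- start_age + tau
  assert_that(a0 >= min(baseline$age) && a1 <= max(baseline$age) + 1,
              "window outside the baseline hazard's age support")
  lo <- pmax(baseline$age, a0)
  hi <- pmin(baseline$age + 1, a1)
  dt <- pmax(hi - lo, 0)
  cum0 <- sum(baseline$lambda0 * dt)
  if (is.null(mortality)) {
    1 - exp(-cum0 * exp(pcrs))
  } else {
    # life-table decomposition on the prorated grid: cause-specific share
    # of the combined-risk complement, stratum by stratum
    vapply(pcrs, function(p) {
      surv <- 1
      risk <- 0
      for (k in which(dt > 0)) {
        hc <- baseline$lambda0[k] * exp(p) * dt[k]
        hm <- mortality[k] * dt[k]
        tot <- hc + hm
        pr_any <- 1 - exp(-tot)
        share <- if (tot > 0) hc / tot else 0
        risk <- risk + surv * pr_any * share
        surv <- surv * exp(-tot)
      }
      risk
    }, numeric(1))
  }
}

#' Mean absolute risk over an age-by-percentile grid
#'
#' For each percentile bin of the reference PCRS distribution, takes the
#' mean PCRS among the reference draws falling in the bin and evaluates
#' the window risk at each requested age.
#'
#' @param baseline A [calibrate_baseline()] result.
#' @param reference A [reference_distribution()] (the PCRS distribution).
#' @param ages Integer vector of start ages.
#' @param bins Percentile bin edges covering 0 to 100; default
#'   `c(0, 5, 10, 25, 50, 75, 90, 95, 100)`.
#' @param window_months Window length (months).
#' @return A `risk_surface` data.frame: `age`, `bin`, `bin_lo`, `bin_hi`,
#'   `mean_pcrs`, `risk`, with the window in `attr(, "window_months")`.
#' @export
risk_surface <- function(baseline, reference, ages,
                         bins = c(0, 5, 10, 25, 50, 75, 90, 95, 100),
                         window_months = 12) {
  assert_that(bins[1] == 0 && bins[length(bins)] == 100 &&
                all(diff(bins) > 0), "bins must cover [0, 100] increasingly")
  pct <- 100 * (rank(reference$pcrs, ties.method = "first") - 0.5) /
    length(reference$pcrs)
  grid <- expand.grid(age = ages, bin_idx = seq_len(length(bins) - 1L),
                      KEEP.OUT.ATTRS = FALSE)
  mean_pcrs <- vapply(seq_len(length(bins) - 1L), function(b) {
    inb <- pct >= bins[b] & pct < bins[b + 1L] |
      (b == length(bins) - 1L & pct == 100)
    assert_that(any(inb), paste0("empty percentile bin [", bins[b], ",",
                                 bins[b + 1L], ")"))
    mean(reference$pcrs[inb])
  }, numeric(1))
  out <- data.frame(
    age = grid$age,
    bin = paste0(bins[grid$bin_idx], "-", bins[grid$bin_idx + 1L]),
    bin_lo = bins[grid$bin_idx],
    bin_hi = bins[grid$bin_idx + 1L],
    mean_pcrs = mean_pcrs[grid$bin_idx],
    stringsAsFactors = FALSE
  )
  out$risk <- mapply(function(a, p) absolute_risk(baseline, p, a,
                                                  window_months),
                     out$age, out$mean_pcrs)
  attr(out, "window_months") <- window_months
  class(out) <- c("risk_surface", "data.frame")
  out
}
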