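#' MCED test characteristics
#'
#' Sensitivity/specificity pair for a multicancer early-detection test.
#' Presets: `"galleri"` (sensitivity 51.5% at 99.5% specificity) and
#' `"detect-a"` (27.1% at 98.9%).
#'
#' @param name Preset name or a label for a custom test.
#' @param se,sp Sensitivity and specificity in (0, 1); required unless
#'   `name` is a preset.
#' @return A `test_characteristics` list: `name`, `se`, `sp`.
#' @export
test_characteristics <- function(name, se = NULL, sp = NULL) {
  presets <- list(
    "galleri" = c(se = 0.515, sp = 0.995),
    "detect-a" = c(se = 0.271, sp = 0.989)
  )
  if (is.null(se) || is.null(sp)) {
    assert_that(tolower(name) %in% names(presets),
                paste0("unknown test preset: ", name))
    p <- presets[[tolower(name)]]
    se <- p[["se"]]
    sp <- p[["sp"]]
  }
  assert_that(se > 0 && se < 1 && sp > 0 && sp < 1,
              "sensitivity and specificity must lie in (0, 1)")
  structure(list(name = name, se = se, sp = sp),
            class = "test_characteristics")
}

#' @export
print.test_characteristics <- function(x, ...) {
  cat(sprintf("<test> %s: sensitivity %.1f%% at %.1f%% specificity\n",
              x$name, 100 * x$se, 100 * x$sp))
  invisible(x)
}

#' Positive and negative predictive value by Bayes' theorem
#'
#' For a pre-test probability of disease `x` (the short-window absolute
#' risk) and a test with sensitivity `Se` and specificity `Sp`:
#' \deqn{PPV(x) = \frac{Se\,x}{Se\,x + (1-Sp)(1-x)}, \qquad
#'       NPV(x) = \frac{Sp\,(1-x)}{(1-Se)\,x + Sp\,(1-x)}.}
#' Both are vectorized in `x`; the degenerate point `x = 0` with `Sp = 1`
#' is defined as `PPV = 0`.
#'
#' @param test A [test_characteristics()].
#' @param x Absolute risk(s) in `[0, 1]`.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
ppv <- function(test, x) {
  assert_that(all(x >= 0 & x <= 1), "absolute risk must lie in [0, 1]")
  num <- test$se * x
  den <- num + (1 - test$sp) * (1 - x)
  ifelse(den == 0, 0, num / den)
}

#' @rdname ppv
#' @export
npv <- function(test, x) {
  assert_that(all(x >= 0 & x <= 1), "absolute risk must lie in [0, 1]")
  num <- test$sp * (1 - x)
  den <- (1 - test$se) * x + num
  ifelse(den == 0, 1, num / den)
}

#' Project test performance over a risk surface
#'
#' Applies [ppv()] and [npv()] elementwise to the absolute risks of an
#' age-by-percentile risk surface.
#'
#' @param test A [test_characteristics()].
#' @param surface A [risk_surface()].
#' @return A `screening_projection` data.frame: the surface columns plus
#'   `ppv` and `npv`; the test is kept in `attr(, "test")`.
#' @export
project_screening <- function(test, surface) {
  out <- as.data.frame(surface)
  out$ppv <- ppv(test, out$risk)
  out$npv <- npv(test, out$risk)
  attr(out, "test") <- test
  attr(out, "window_months") <- attr(surface, "window_months")
  class(out) <- c("screening_projection", "data.frame")
  out
}

#' Weighted PPV over risk strata
#'
#' Two conventions for pooling PPV across strata with risks `x_s` and
#' weights `w_s`: `"pooled"` (default) evaluates the Bayes PPV at the
#' weight-averaged risk — the PPV of the mixed population — while
#' `"average"` weight-averages the per-stratum PPVs. The two agree when
#' all strata share one risk.
#'
#' @param test A [test_characteristics()].
#' @param risks Per-stratum absolute risks.
#' @param weights Non-negative stratum weights with a positive sum.
#' @param convention `"pooled"` or `"average"`.
#' @return A proportion.
#' @export
weighted_ppv <- function(test, risks, weights = rep(1, length(risks)),
                         convention = c("pooled", "average")) {
  convention <- match.arg(convention)
  assert_that(length(risks) == length(weights) && all(weights >= 0) &&
                sum(weights) > 0,
              "weights must be non-negative with a positive sum")
  w <- weights / sum(weights)
  if (convention == "pooled") {
    ppv(test, sum(w * risks))
  } else {
    sum(w * ppv(test, risks))
  }
}

#' Calibrate the risk time window against an empirical PPV
#'
#' Exhaustive grid search over candidate window lengths: for each window,
#' the weighted PPV over the configured age range (each age weighted by
#' the population age weights, the PCRS mixture integrated over the
#' reference draws) is compared with the empirical target; the window
#' minimizing the absolute difference is returned, ties broken toward 12
#' months. A warning is raised when the optimum sits on the grid boundary
#' (target outside the achievable PPV range).
#'
#' @param test A [test_characteristics()].
#' @param baseline A [calibrate_baseline()] result.
#' @param reference A [reference_distribution()].
#' @param age_weights data.frame `age`, `weight` (e.g.
#'   [generate_age_weights()]).
#' @param empirical_ppv Target PPV (e.g. 0.194 for DETECT-A).
#' @param age_range Two ages bounding the pooled group (default 65-75).
#' @param windows Candidate windows in months (default `6:18`).
#' @param convention Pooling convention passed to [weighted_ppv()].
#' @return List: `window_months`, `achieved_ppv`, and the search `table`
#'   (window, weighted PPV, absolute gap).
#' @export
calibrate_window <- function(test, baseline, reference, age_weights,
                             empirical_ppv, age_range = c(65, 75),
                             windows = 6:18,
                             convention = c("pooled", "average")) {
  convention <- match.arg(convention)
  assert_that(length(windows) > 0, "empty window grid")
  ages <- age_weights$age[age_weights$age >= age_range[1] &
                            age_weights$age <= age_range[2]]
  w_age <- age_weights$weight[match(ages, age_weights$age)]
  assert_that(length(ages) > 0 && sum(w_age) > 0,
              "no age weights inside the requested range")
  achieved <- vapply(windows, function(wm) {
    # risks per (age x reference draw); each draw carries equal PCRS weight
    risks <- unlist(lapply(ages, function(a)
      absolute_risk(baseline, reference$pcrs, a, wm)))
    wts <- rep(w_age, each = length(reference$pcrs))
    weighted_ppv(test, risks, wts, convention)
  }, numeric(1))
  gap <- abs(achieved - empirical_ppv)
  best <- which(gap == min(gap))
  if (length(best) > 1L) best <- best[which.min(abs(windows[best] - 12))]
  if (windows[best] %in% range(windows) &&
      (all(achieved < empirical_ppv) || all(achieved > empirical_ppv))) {
    warning("target PPV outside the achievable range; boundary window ",
            windows[best], " returned")
  }
  list(window_months = windows[best], achieved_ppv = achieved[best],
       table = data.frame(window_months = windows, weighted_ppv = achieved,
                          gap = gap))
}

#' Earliest screening-eligible age per risk stratum
#'
#' For a PPV threshold used as a screening-recommendation rule, returns
#' per percentile bin the smallest grid age at which the projected PPV
#' reaches the threshold, or `NA` ("never") when no age qualifies.
#'
#' @param projection A [project_screening()] result.
#' @param ppv_threshold Threshold in (0, 1).
#' @return data.frame `bin`, `bin_lo`, `bin_hi`, `eligible_age` (NA when
#'   never eligible).
#' @export
eligibility_grid <- function(projection, ppv_threshold) {
  assert_that(ppv_threshold > 0 && ppv_threshold < 1,
              "threshold must lie in (0, 1)")
  bins <- unique(projection[, c("bin", "bin_lo", "bin_hi")])
  bins <- bins[order(bins$bin_lo), ]
  bins$eligible_age <- vapply(bins$bin, function(b) {
    rows <- projection[projection$bin == b & projection$ppv >= ppv_threshold, ]
    if (nrow(rows) == 0L) NA_real_ else min(rows$age)
  }, numeric(1))
  rownames(bins) <- NULL
  bins
}
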