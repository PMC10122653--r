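#' Ground-truth configuration for the synthetic study
#'
#' A `truth_config` bundles every parameter of the synthetic generative
#' model: per-cancer SNP architecture, LD block structure, risk-factor
#' distributions, true log hazard ratios, an age-indexed baseline hazard
#' (per-year rates), competing death and other-cancer censoring processes,
#' enrollment and follow-up windows, and missingness rates. Presets encode
#' study conditions resembling a UK-Biobank-like prospective cohort; the
#' relative covariate log hazard ratios in a preset are rescaled at load
#' time so that the standard deviation of the true pan-cancer risk score
#' (PCRS) equals `log(target_hr_per_sd)` — i.e. the true hazard ratio per
#' 1 SD of PCRS equals the preset target.
#'
#' @param preset Name of a shipped preset (`"ukbb-female"`, `"ukbb-male"`,
#'   `"demo"`) or a path to a YAML file with the same structure.
#' @param overrides Named list of fields replacing preset values before
#'   resolution (e.g. `list(target_hr_per_sd = 1.2)`).
#' @return An object of class `truth_config`.
#' @examples
#' cfg <- truth_config("demo")
#' pcrs_truth_sd(cfg)  # equals log(cfg$target_hr_per_sd)
#' @export
truth_config <- function(preset = "ukbb-female", overrides = list()) {
  path <- if (file.exists(preset)) {
    preset
  } else {
    system.file("extdata", paste0("preset-", preset, ".yaml"),
                package = "mcedrisk")
  }
  assert_that(nzchar(path) && file.exists(path),
              paste0("unknown preset or missing file: ", preset))
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  cfg <- resolve_truth_config(raw)
  validate_truth_config(cfg)
  cfg
}

# turn a raw preset list into a fully resolved config: scale log HRs to the
# target standardized hazard ratio and expand baseline/death rate grids
resolve_truth_config <- function(raw) {
  cfg <- raw
  if (is.null(cfg$log_hr)) {
    rel <- cfg$relative_log_hr
    rf <- cfg$risk_factors
    prs <- rep(rel$prs_per_sd, length(cfg$cancers))
    names(prs) <- cfg$cancers
    fh <- rep(rel$family_history, length(rf$family_history))
    names(fh) <- names(rf$family_history)
    beta <- list(
      prs = prs,
      bmi = rel$bmi_per_sd / rf$bmi$sd,   # per kg/m^2
      smoking_former = rel$smoking_former,
      smoking_current = rel$smoking_current,
      pack_years = rel$pack_years_per_year,
      family_history = fh
    )
    sd0 <- pcrs_sd_from_beta(beta, rf)
    # target HR 1 means a null model: zero out all effects
    scale <- if (log(cfg$target_hr_per_sd) == 0) 0 else {
      assert_that(sd0 > 0,
                  "relative effects are all zero but the target HR is not 1")
      log(cfg$target_hr_per_sd) / sd0
    }
    beta$prs <- beta$prs * scale
    beta$bmi <- beta$bmi * scale
    beta$smoking_former <- beta$smoking_former * scale
    beta$smoking_current <- beta$smoking_current * scale
    beta$pack_years <- beta$pack_years * scale
    beta$family_history <- beta$family_history * scale
    cfg$log_hr <- beta
  } else {
    # already-resolved config (round trip): keep names on vectors
    cfg$log_hr$prs <- unlist(cfg$log_hr$prs)
    cfg$log_hr$family_history <- unlist(cfg$log_hr$family_history)
  }
  if (is.null(cfg$baseline_ages)) {
    b <- cfg$baseline
    cfg$baseline_ages <- seq.int(b$age_min, b$age_max - 1L)
    cfg$baseline_rates <-
      b$rate_at_min * exp(b$log_slope * (cfg$baseline_ages - b$age_min))
    cfg$death_rates <-
      cfg$death$rate_at_min *
      exp(cfg$death$log_slope * (cfg$baseline_ages - b$age_min))
  }
  class(cfg) <- "truth_config"
  cfg
}

# analytic SD of the true PCRS = beta' z under the configured covariate
# distribution. PRSs are independent unit normals; BMI normal; smoking is a
# three-level categorical with pack-years drawn for ever-smokers only
# (gamma, var = mean^2 / shape); family history independent Bernoullis.
pcrs_sd_from_beta <- function(beta, rf) {
  v_prs <- sum(beta$prs^2)
  v_bmi <- (beta$bmi * rf$bmi$sd)^2
  p <- rf$smoking
  mu_py <- rf$pack_years$mean
  var_py <- mu_py^2 / rf$pack_years$shape
  vals <- c(0,
            beta$smoking_former + beta$pack_years * mu_py,
            beta$smoking_current + beta$pack_years * mu_py)
  probs <- c(p$p_never, p$p_former, p$p_current)
  v_between <- sum(probs * vals^2) - sum(probs * vals)^2
  v_within <- (p$p_former + p$p_current) * beta$pack_years^2 * var_py
  pfh <- unlist(rf$family_history)
  v_fh <- sum(beta$family_history^2 * pfh * (1 - pfh))
  sqrt(v_prs + v_bmi + v_between + v_within + v_fh)
}

pcrs_mean_from_beta <- function(beta, rf) {
  p <- rf$smoking
  mu_py <- rf$pack_years$mean
  beta$bmi * rf$bmi$mean +
    beta$smoking_former * p$p_former + beta$smoking_current * p$p_current +
    beta$pack_years * (p$p_former + p$p_current) * mu_py +
    sum(beta$family_history * unlist(rf$family_history))
}

#' True PCRS standard deviation and mean implied by a truth config
#'
#' Closed-form moments of the true linear predictor
#' \eqn{\beta' z} under the configured covariate distribution. By
#' construction of the presets, `pcrs_truth_sd(cfg)` equals
#' `log(cfg$target_hr_per_sd)`.
#'
#' @param config A `truth_config`.
#' @return A numeric scalar.
#' @export
pcrs_truth_sd <- function(config) {
  pcrs_sd_from_beta(config$log_hr, config$risk_factors)
}

#' @rdname pcrs_truth_sd
#' @export
pcrs_truth_mean <- function(config) {
  pcrs_mean_from_beta(config$log_hr, config$risk_factors)
}

#' @noRd
validate_truth_config <- function(cfg) {
  assert_that(all(cfg$baseline_rates >= 0) && all(cfg$death_rates >= 0) &&
                cfg$other_cancer_rate >= 0,
              "all rates must be non-negative")
  assert_that(cfg$raf_range[1] > 0 && cfg$raf_range[2] < 1,
              "allele frequencies must lie in (0, 1)")
  assert_that(cfg$enrollment[1] >= cfg$baseline$age_min &&
                cfg$enrollment[2] < cfg$baseline$age_max,
              "enrollment range must lie within the modelled age range")
  assert_that(cfg$snps_per_cancer > 0,
              "configuration error: SNP count per cancer must be positive")
  shares <- unlist(cfg$cancer_share)
  assert_that(setequal(names(shares), cfg$cancers) && all(shares > 0),
              "cancer_share must give a positive share for each cancer")
  probs <- unlist(cfg$risk_factors$smoking)
  assert_that(abs(sum(probs) - 1) < 1e-8, "smoking probabilities must sum to 1")
  invisible(cfg)
}

#' Serialize / deserialize a truth config
#'
#' The resolved configuration (including the scaled log hazard ratios and
#' expanded rate grids) is written to YAML and reads back identically, so a
#' run can be reproduced from its persisted config alone.
#'
#' @param config A `truth_config`.
#' @param path Output (input) YAML path.
#' @return `read_truth_config` returns a `truth_config`;
#'   `write_truth_config` returns `path` invisibly.
#' @export
write_truth_config <- function(config, path) {
  x <- unclass(config)
  x$log_hr$prs <- as.list(x$log_hr$prs)
  x$log_hr$family_history <- as.list(x$log_hr$family_history)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth_config
#' @export
read_truth_config <- function(path) {
  cfg <- resolve_truth_config(yaml::read_yaml(path))
  validate_truth_config(cfg)
  cfg
}

#' @export
print.truth_config <- function(x, ...) {
  cat("<truth_config>", x$name, "\n")
  cat("  sex:", x$sex, " cancers:", length(x$cancers), "\n")
  cat("  true HR per 1 SD of PCRS:",
      sprintf("%.3f", exp(pcrs_truth_sd(x))), "\n")
  cat("  baseline hazard ages:", min(x$baseline_ages), "-",
      max(x$baseline_ages) + 1L, "\n")
  invisible(x)
}
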