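#' Run the end-to-end synthetic analysis
#'
#' Orchestrates every stage from one run configuration: simulate GWAS
#' summary statistics and genotypes, build per-cancer PRSs through QC and
#' LD clumping, simulate the cohort, fit the multicancer hazard model on
#' the training split, evaluate all model variants on the test split,
#' calibrate the baseline hazard to the (shifted) marginal incidence
#' rates, build risk surfaces, and project PPV/NPV and screening
#' eligibility for each configured test. Every stochastic stage draws its
#' seed from the master seed via [derive_seed()], so two runs with the
#' same configuration produce identical outputs.
#'
#' @param config Path to a YAML run configuration, or an equivalent list.
#'   Fields: `preset`, `n_subjects`, `seed`, `use_genotypes`,
#'   `window_months`, `reference_n`, `ages`, `bins`, `tests` (list of
#'   `name` or `name`/`se`/`sp`), `ppv_thresholds`, `horizon_years`,
#'   optional `clump` (`p_threshold`, `r2`, `window_kb`) and
#'   `calibrate_window` (`target_ppv`, `age_range`, `windows`), and
#'   `incidence_file` (external incidence CSV; the truth config's
#'   simulated marginal rates are used when absent).
#' @param out_dir Run directory to create (must not already contain a
#'   `summary.json`).
#' @return The run directory path, invisibly; all artifacts are written
#'   beneath it and summarized in `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- cfg$seed %||% 1L
  truth <- stage("truth-config", truth_config(cfg$preset %||% "demo"))
  summary <- list(
    config = cfg,
    config_hash = config_hash(cfg),
    seed = seed,
    preset = truth$name,
    sex = truth$sex
  )

  # resolve external inputs first so path errors surface before any heavy
  # simulation or fitting
  incidence <- stage("incidence", {
    if (!is.null(cfg$incidence_file)) {
      assert_that(file.exists(cfg$incidence_file),
                  paste0("incidence file not found: ", cfg$incidence_file))
      read_rate_table(cfg$incidence_file, "rate")
    } else {
      generate_incidence_table(truth, seed = derive_seed(seed, "incidence"))
    }
  })
  write_rate_table(incidence, file.path(out_dir, "incidence.csv"))
  age_w <- generate_age_weights(truth)
  write_rate_table(age_w, file.path(out_dir, "age-weights.csv"))

  prs_mat <- NULL
  if (isTRUE(cfg$use_genotypes)) {
    stage("prs-pipeline", {
      clump <- cfg$clump %||% list()
      prs_cols <- list()
      qc_counts <- list()
      for (cancer in truth$cancers) {
        ss <- generate_summary_stats(
          truth, cancer, seed = derive_seed(seed, paste0("stats-", cancer)))
        geno <- generate_genotypes(
          ss$stats, cfg$n_subjects, truth,
          seed = derive_seed(seed, paste0("geno-", cancer)))
        freqs <- data.frame(rsid = colnames(geno),
                            effect_allele = ss$stats$effect_allele[
                              match(colnames(geno), ss$stats$rsid)],
                            other_allele = ss$stats$other_allele[
                              match(colnames(geno), ss$stats$rsid)],
                            freq = attr(geno, "observed_freq"),
                            stringsAsFactors = FALSE)
        qc <- qc_filter_variants(ss$stats, freqs)
        idx <- ld_clump(qc$stats, geno,
                        p_threshold = clump$p_threshold %||% 5e-8,
                        r2_threshold = clump$r2 %||% 0.1,
                        window_kb = clump$window_kb %||% 1000)
        qc_counts[[cancer]] <- c(input = qc$report$n_input,
                                 retained = qc$report$n_retained,
                                 index = nrow(idx))
        utils::write.table(
          idx[, c("rsid", "chr", "pos", "beta", "pval")],
          file.path(out_dir, paste0("index-variants-", cancer, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        prs_cols[[cancer]] <- if (nrow(idx) > 0) {
          compute_prs(geno, idx)$standardized
        } else {
          # no genome-wide-significant index variants: uninformative score
          rep(0, cfg$n_subjects)
        }
      }
      prs_mat <- do.call(cbind, prs_cols)
      summary$qc <- qc_counts
    })
  }

  cohort <- stage("cohort", generate_cohort(
    truth, cfg$n_subjects, seed = derive_seed(seed, "cohort"),
    prs = prs_mat))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  cc <- stage("complete-case", filter_complete_cases(cohort))
  summary$n_subjects <- nrow(cohort)
  summary$n_removed_incomplete <- cc$n_removed
  parts <- split_train_test(cc$cohort, derive_seed(seed, "split"))
  model <- stage("model-fit", fit_hazard_model(parts$train))
  jsonlite::write_json(
    list(coef = as.list(model$coef), se = as.list(model$se),
         pcrs_mean = model$pcrs_mean, pcrs_sd = model$pcrs_sd,
         n_train = model$n_train, n_events = model$n_events),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  scored <- compute_pcrs(model, cc$cohort)
  utils::write.csv(scored, file.path(out_dir, "pcrs.csv"),
                   row.names = FALSE)

  metrics <- stage("evaluation", compare_models(
    cc$cohort, derive_seed(seed, "split"),
    horizon_years = cfg$horizon_years %||% 5))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  reference <- stage("reference", reference_distribution(
    model, n = cfg$reference_n %||% 10000L,
    seed = derive_seed(seed, "reference")))
  baseline <- stage("absolute-risk", calibrate_baseline(
    shift_incidence(incidence), reference))

  ages <- cfg$ages %||% seq(50, 75, by = 5)
  bins <- cfg$bins %||% c(0, 5, 10, 25, 50, 75, 90, 95, 100)
  tests <- lapply(cfg$tests %||% list(list(name = "galleri")), function(t)
    test_characteristics(t$name, t$se %||% NULL, t$sp %||% NULL))

  summary$tests <- list()
  for (test in tests) {
    slug <- gsub("[^a-z0-9]+", "-", tolower(test$name))
    wm <- cfg$window_months %||% 12
    cw <- NULL
    if (!is.null(cfg$calibrate_window)) {
      cwc <- cfg$calibrate_window
      cw <- stage("window-calibration", calibrate_window(
        test, baseline, reference, age_w,
        empirical_ppv = cwc$target_ppv,
        age_range = unlist(cwc$age_range %||% c(65, 75)),
        windows = seq(cwc$windows[[1]], cwc$windows[[2]])))
      wm <- cw$window_months
      utils::write.csv(cw$table,
                       file.path(out_dir,
                                 paste0("window-calibration-", slug, ".csv")),
                       row.names = FALSE)
    }
    surface <- stage("risk-surface", risk_surface(
      baseline, reference, ages, bins, window_months = wm))
    proj <- project_screening(test, surface)
    utils::write.csv(as.data.frame(proj),
                     file.path(out_dir, paste0("projection-", slug, ".csv")),
                     row.names = FALSE)
    elig <- lapply(cfg$ppv_thresholds %||% c(0.40, 0.60), function(thr) {
      g <- eligibility_grid(proj, thr)
      g$threshold <- thr
      g
    })
    elig <- do.call(rbind, elig)
    utils::write.csv(elig,
                     file.path(out_dir, paste0("eligibility-", slug, ".csv")),
                     row.names = FALSE)
    # pooled vs averaged weighted PPV for the 65-75 group, side by side
    grp <- age_w[age_w$age >= 65 & age_w$age <= 75, ]
    risks <- unlist(lapply(grp$age, function(a)
      absolute_risk(baseline, reference$pcrs, a, wm)))
    wts <- rep(grp$weight, each = length(reference$pcrs))
    summary$tests[[slug]] <- list(
      se = test$se, sp = test$sp, window_months = wm,
      calibrated = !is.null(cw),
      weighted_ppv_pooled = weighted_ppv(test, risks, wts, "pooled"),
      weighted_ppv_averaged = weighted_ppv(test, risks, wts, "average"))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# order-stable hash of a run configuration (provenance stamp)
config_hash <- function(cfg) {
  canon <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                            digits = NA)
  # small rolling hash; avoids a digest dependency
  h <- Reduce(function(h, ch) (h * 31 + ch) %% 2147483647,
              utf8ToInt(as.character(canon)), accumulate = FALSE, init = 7)
  sprintf("%08x", as.integer(h))
}

#' Summarize a completed run as a Markdown report
#'
#' Collects the stage outputs of a [run_pipeline()] directory into one
#' document: model metrics, per-test risk/PPV/NPV grids, eligibility
#' tables per PPV threshold, and the pooled-versus-averaged weighted PPV
#' comparison.
#'
#' @param run_dir A completed run directory.
#' @param path Output file (default `report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  need <- c("summary.json", "metrics.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  assert_that(length(missing) == 0,
              paste("incomplete run; missing:", paste(missing,
                                                      collapse = ", ")))
  summary <- jsonlite::read_json(file.path(run_dir, "summary.json"))
  metrics <- utils::read.csv(file.path(run_dir, "metrics.csv"))
  lines <- c(
    paste0("# Multicancer screening projection report (", summary$preset,
           ")"),
    "",
    paste0("Seed: ", summary$seed, "; config hash: ", summary$config_hash,
           "; subjects: ", summary$n_subjects, " (",
           summary$n_removed_incomplete, " removed as incomplete cases)"),
    "",
    "## Model performance (held-out test split)",
    "",
    md_table(metrics[, c("model", "hr", "hr_lower", "hr_upper", "c_index",
                         "auc")])
  )
  for (slug in names(summary$tests)) {
    t <- summary$tests[[slug]]
    proj <- utils::read.csv(file.path(run_dir,
                                      paste0("projection-", slug, ".csv")))
    elig <- utils::read.csv(file.path(run_dir,
                                      paste0("eligibility-", slug, ".csv")))
    lines <- c(
      lines, "",
      sprintf("## %s (Se %.1f%%, Sp %.1f%%, window %s months)", slug,
              100 * t$se, 100 * t$sp, t$window_months),
      "",
      sprintf(paste0("Weighted PPV, ages 65-75: %.4f (pooled) / %.4f ",
                     "(average-of-PPVs)"),
              t$weighted_ppv_pooled, t$weighted_ppv_averaged),
      "",
      "### Risk / PPV / NPV by age and PCRS percentile bin",
      "",
      md_table(proj[, c("age", "bin", "risk", "ppv", "npv")]),
      "",
      "### Earliest eligible age by PPV threshold",
      "",
      md_table(elig[, c("threshold", "bin", "eligible_age")])
    )
  }
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) signif(x, 4) else x
  df[] <- lapply(df, fmt)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
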