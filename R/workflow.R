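# Workflow orchestration: simulate -> clean -> CCE/PPS -> group models, with
# a frozen config, exclusion logging that reconciles with input counts, and
# delimited-text outputs. The analysis/ scripts are thin drivers over these
# functions.

#' Build and validate a run configuration
#'
#' @param seed Master seed for every source of randomness in the run.
#' @param out_dir Output directory.
#' @param tasks Which tasks to analyse (`"CCE"`, `"PPS"` or both).
#' @param rt_cutoff RT discard threshold, s (strict `>` discard).
#' @param min_trials Minimum surviving trials per CCE condition cell.
#' @param r2_cutoff Sigmoid-fit retention threshold (strict `>`), in (0, 1].
#' @param m_imputations Imputations for missing covariates (default 40).
#' @param sigmoid_form `"bounded"` or `"printed"`, see [pps_sigmoid()].
#' @param cohort A [cohort_spec()] for simulation runs, or NULL when
#'   analysing existing files.
#' @param trials_path,subjects_path,truth_path Input files for analysis
#'   runs; defaults point into `out_dir` (where [run_simulate()] writes).
#' @param plots Emit per-subject plots (off by default).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("ppsmap_run_"),
                       tasks = c("CCE", "PPS"),
                       rt_cutoff = 2.0, min_trials = 10, r2_cutoff = 0.5,
                       m_imputations = 40, sigmoid_form = "bounded",
                       cohort = NULL, trials_path = NULL,
                       subjects_path = NULL, truth_path = NULL,
                       plots = FALSE) {
  cfg <- as.list(environment())
  if (!is.numeric(cfg$rt_cutoff) || cfg$rt_cutoff <= 0)
    stop("config validation error: rt_cutoff must be positive")
  if (!is.numeric(cfg$min_trials) || cfg$min_trials <= 0)
    stop("config validation error: min_trials must be positive")
  if (!is.numeric(cfg$r2_cutoff) || cfg$r2_cutoff <= 0 || cfg$r2_cutoff > 1)
    stop("config validation error: r2_cutoff must lie in (0, 1]")
  if (cfg$m_imputations < 1)
    stop("config validation error: m_imputations must be >= 1")
  if (!sigmoid_form %in% c("bounded", "printed"))
    stop("config validation error: unknown sigmoid_form")
  if (!length(tasks) || !all(tasks %in% c("CCE", "PPS")))
    stop("config validation error: tasks must be a subset of CCE, PPS")
  class(cfg) <- "run_config"
  cfg
}

freeze_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keep <- cfg[!vapply(cfg, is.null, logical(1))]
  keep$cohort <- if (!is.null(cfg$cohort)) unclass(cfg$cohort)
  jsonlite::write_json(keep, file.path(dir, "config_frozen.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
}

#' Simulate a cohort and write its dataset files
#'
#' Simulates the configured [cohort_spec()] under the run seed and writes
#' `trials.csv`, `subjects.csv`, `truth.csv` and a frozen copy of the config
#' to `out_dir`. Identical config + seed produce byte-identical files.
#'
#' @param cfg A [run_config()] with a `cohort` spec.
#' @return Invisibly, the simulated `pps_dataset`.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$cohort)) stop("config error: no simulation spec present")
  ds <- simulate_cohort(cfg$cohort, cfg$seed)
  paths <- write_trials(ds, cfg$out_dir)
  freeze_config(cfg, cfg$out_dir)
  message(sprintf("simulated %d subjects, %d trials (seed %s) -> %s",
                  nrow(ds$subjects), nrow(ds$trials), format(cfg$seed),
                  cfg$out_dir))
  invisible(ds)
}

# Fit one CPM outcome, with multiple imputation + Rubin pooling when the
# predictor columns carry missing values.
fit_outcome_model <- function(outcome_name, tab, predictors, cfg, seed_offset) {
  tab <- tab[is.finite(tab[[outcome_name]]), , drop = FALSE]
  if (nrow(tab) < length(predictors) + 2)
    stop("too few subjects with outcome '", outcome_name, "'")
  y <- tab[[outcome_name]]
  has_missing <- any(!complete.cases(tab[predictors]))
  if (has_missing) {
    completed <- impute(tab, m = cfg$m_imputations,
                        seed = sub_seed(cfg$seed, seed_offset, 9),
                        targets = intersect(c("gender", "fsiq"), predictors))
    fits <- lapply(completed, function(dd) cpm_fit(y, dd[predictors]))
    fits <- Filter(function(f) f$converged, fits)
    if (!length(fits)) stop("no imputation fit converged for ", outcome_name)
    pool_rubin(fits)
  } else {
    cpm_fit(y, tab[predictors])
  }
}

cpm_table <- function(fit, outcome_name) {
  out <- fit$coef
  out$outcome <- outcome_name
  out$n <- fit$n
  out$pooled <- fit$pooled
  out[c("outcome", setdiff(names(out), "outcome"))]
}

#' Analyze a dataset end to end
#'
#' Runs the CCE and PPS pipelines, then the group models: one CPM per
#' outcome (`cce_rt` and `cce_acc` with gender, age, full-scale IQ, baseline
#' tactile performance and diagnostic group as predictors; PPS size `xc` and
#' gradient `b` with gender, age, full-scale IQ and group), Rubin-pooled
#' over multiple imputations when covariates are missing, plus Spearman
#' correlations of the PPS measures with the SRS-2 total T score overall and
#' within each group (Bonferroni over the two whole-sample tests). Writes
#' delimited results, exclusion logs and a plain-text report under
#' `out_dir`; appends a recovery table when simulated truth is available.
#'
#' @param cfg A [run_config()].
#' @param dataset Optional `pps_dataset`; when absent the configured input
#'   files are read.
#' @return List with `cce`, `pps`, `models` (named list of `cpm_fit`),
#'   `model_table`, `correlations`, `contrasts`, `recovery`, `report_path`.
#' @export
run_analyze <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(dataset)) {
    tp <- cfg$trials_path %||% file.path(cfg$out_dir, "trials.csv")
    sp <- cfg$subjects_path %||% file.path(cfg$out_dir, "subjects.csv")
    up <- cfg$truth_path %||% file.path(cfg$out_dir, "truth.csv")
    if (!file.exists(tp) || !file.exists(sp))
      stop("input files not found: ", tp, " / ", sp)
    dataset <- read_trials(tp, sp, truth_path = up)
  }
  subjects <- dataset$subjects
  subjects$group <- factor(subjects$group, levels = .groups)  # TD reference
  do_cce <- "CCE" %in% cfg$tasks && any(dataset$trials$task == "CCE")
  do_pps <- "PPS" %in% cfg$tasks && any(dataset$trials$task == "PPS")
  if (!do_cce && !do_pps) stop("no analysable trials for the configured tasks")

  cce <- if (do_cce) cce_results(dataset, rt_cutoff = cfg$rt_cutoff,
                                 min_trials = cfg$min_trials)
  pps <- if (do_pps) pps_results(dataset, rt_cutoff = cfg$rt_cutoff,
                                 r2_cutoff = cfg$r2_cutoff,
                                 form = cfg$sigmoid_form)

  cce_ok <- if (do_cce) cce$results[!cce$results$excluded, ]
  pps_ok <- if (do_pps) pps$kept
  if ((NROW(cce_ok) + NROW(pps_ok)) == 0)
    stop("all subjects excluded; nothing to model")

  contrasts <- list()
  if (do_cce) {
    contrasts$cce_rt <- contrast_vs_zero(cce_ok$cce_rt)
    contrasts$cce_acc <- contrast_vs_zero(cce_ok$cce_acc)
  }
  if (do_pps) {
    f <- filter_trials_pps(dataset$trials[dataset$trials$task == "PPS", ],
                           cfg$rt_cutoff)
    contrasts$facilitation <- baseline_contrast(f$trials)
  }

  covars <- c("gender", "age", "fsiq")
  models <- list()
  correlations <- NULL
  if (do_cce) {
    cce_tab <- merge(cce_ok, subjects, by = "subject_id")
    models$cce_rt <- fit_outcome_model(
      "cce_rt", cce_tab, c(covars, "baseline_rt", "group"), cfg, 1)
    models$cce_acc <- fit_outcome_model(
      "cce_acc", cce_tab, c(covars, "baseline_acc", "group"), cfg, 2)
  }
  if (do_pps) {
    pps_tab <- merge(pps_ok[setdiff(names(pps_ok), "group")], subjects,
                     by = "subject_id")
    models$pps_size <- fit_outcome_model(
      "xc", pps_tab, c(covars, "group"), cfg, 3)
    models$pps_gradient <- fit_outcome_model(
      "b", pps_tab, c(covars, "group"), cfg, 4)
    correlations <- pps_srs_correlations(pps_tab)
  }
  model_table <- do.call(rbind, Map(cpm_table, models, names(models)))

  recovery <- NULL
  if (do_pps && !is.null(dataset$meta$truth)) {
    tr <- dataset$meta$truth
    recovery <- merge(pps$fits[c("subject_id", "xc", "b", "r2", "kept")],
                      tr[c("subject_id", "xc_true", "b_true")],
                      by = "subject_id")
    recovery$xc_error <- recovery$xc - recovery$xc_true
  }

  report_path <- write_run_outputs(cfg, cce, pps, models, model_table,
                                   correlations, contrasts, recovery)
  list(cce = cce, pps = pps, models = models, model_table = model_table,
       correlations = correlations, contrasts = contrasts,
       recovery = recovery, report_path = report_path)
}

#' Correlations of PPS measures with social symptom severity
#'
#' Spearman correlations of PPS size (`xc`) and gradient (`b`) with the
#' SRS-2 total T score, in the whole sample and within each group; the two
#' whole-sample tests are Bonferroni-adjusted as a family.
#'
#' @param pps_tab Tibble with `xc`, `b`, `srs_total_t`, `group`.
#' @return Tibble with one row per measure x scope (8 rows for 3 groups).
#' @export
pps_srs_correlations <- function(pps_tab) {
  scopes <- c(list(all = pps_tab), split(pps_tab, pps_tab$group))
  rows <- list()
  for (sc in names(scopes)) {
    dd <- scopes[[sc]]
    for (msr in c("xc", "b")) {
      rows[[paste(sc, msr)]] <-
        if (nrow(dd) >= 3 && sum(is.finite(dd[[msr]]) &
                                 is.finite(dd$srs_total_t)) >= 3) {
          out <- spearman(dd[[msr]], dd$srs_total_t,
                          label = paste0(msr, "~srs_total_t"))
          out$scope <- sc
          out
        } else {
          tibble(pair = paste0(msr, "~srs_total_t"), r = NA_real_,
                 p = NA_real_, n = nrow(dd), scope = sc)
        }
    }
  }
  tab <- do.call(rbind, rows)
  tab$adjusted_p <- NA_real_
  whole <- tab$scope == "all"
  tab$adjusted_p[whole] <- bonferroni(tab$p[whole], m = sum(whole))
  tab
}

write_run_outputs <- function(cfg, cce, pps, models, model_table,
                              correlations, contrasts, recovery) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  freeze_config(cfg, cfg$out_dir)
  wcsv <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(cfg$out_dir, f), row.names = FALSE, na = "")
  wcsv(cce$results, "cce_results.csv")
  wcsv(cce$rejections, "cce_rejections.csv")
  wcsv(pps$curves, "pps_delta_curves.csv")
  wcsv(pps$fits, "pps_sigmoid_fits.csv")
  wcsv(pps$retention_log, "pps_retention.csv")
  wcsv(pps$rejections, "pps_rejections.csv")
  wcsv(model_table, "cpm_models.csv")
  wcsv(correlations, "srs_correlations.csv")
  wcsv(recovery, "recovery.csv")

  rp <- file.path(cfg$out_dir, "report.txt")
  con <- file(rp, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("ppsmap analysis report (seed %s)", format(cfg$seed))
  w("")
  if (!is.null(cce)) {
    w("== Crossmodal congruency ==")
    w("subjects analysed: %d, excluded (<%d trials/condition or empty cell): %d",
      sum(!cce$results$excluded), cfg$min_trials, cce$n_excluded)
    w("congruency effect vs 0: RT t = %.3f, p = %.3g; accuracy t = %.3f, p = %.3g",
      contrasts$cce_rt$statistic, contrasts$cce_rt$p,
      contrasts$cce_acc$statistic, contrasts$cce_acc$p)
    w("")
  }
  if (!is.null(pps)) {
    w("== Peripersonal space ==")
    for (i in seq_len(nrow(pps$retention_log)))
      w("group %s: sigmoid fit kept %d/%d (R2 > %.2f)",
        pps$retention_log$group[i], pps$retention_log$kept[i],
        pps$retention_log$attempted[i], cfg$r2_cutoff)
    w("nearest-distance facilitation vs tactile baseline: t = %.3f, p = %.3g (mean diff %.4f s)",
      contrasts$facilitation$statistic %||% NA, contrasts$facilitation$p,
      contrasts$facilitation$mean_difference)
    w("")
  }
  w("== Cumulative probability models (aOR per unit, TD reference) ==")
  for (nm in names(models)) {
    w("-- outcome: %s%s", nm,
      if (models[[nm]]$pooled) sprintf(" (pooled over %d imputations)",
                                       models[[nm]]$m) else "")
    cf <- models[[nm]]$coef
    for (i in seq_len(nrow(cf)))
      w("   %-16s aOR = %6.3f  CI95 [%.3f, %.3f]  p = %.4g",
        cf$term[i], cf$aor[i], cf$ci_low[i], cf$ci_high[i], cf$p[i])
  }
  w("")
  w("== Spearman correlations with SRS-2 total T ==")
  for (i in seq_len(NROW(correlations)))
    w("   %-6s %-16s r = %6.3f  p = %.3g%s", correlations$scope[i],
      correlations$pair[i], correlations$r[i], correlations$p[i],
      ifelse(is.na(correlations$adjusted_p[i]), "",
             sprintf("  (Bonferroni p = %.3g)", correlations$adjusted_p[i])))
  if (!is.null(recovery)) {
    w("")
    w("== Parameter recovery (simulated truth available) ==")
    w("kept fits: median |xc error| = %.2f cm, median fitted b = %.2f cm",
      median(abs(recovery$xc_error[recovery$kept])),
      median(recovery$b[recovery$kept]))
  }
  rp
}
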