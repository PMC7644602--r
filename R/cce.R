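# Crossmodal congruency pipeline: trial cleaning, per-subject congruency
# metrics for RT and accuracy, and the one-sample contrast against zero.

#' Filter CCE trials
#'
#' Drops non-responses and responses slower than the RT cutoff (2.0 s by
#' default; a response at exactly the cutoff is kept — the discard rule is a
#' strict inequality). Returns the kept trials and a rejection log with one
#' count per reason.
#'
#' @param trials Trial-log tibble containing only CCE trials.
#' @param rt_cutoff Discard threshold in seconds.
#' @return List with `trials` (kept rows) and `log` (tibble of
#'   `reason`, `n`).
#' @export
filter_trials_cce <- function(trials, rt_cutoff = 2.0) {
  stopifnot(all(trials$task == "CCE"), rt_cutoff > 0)
  no_resp <- !trials$responded | is.na(trials$rt_s)
  too_slow <- !no_resp & trials$rt_s > rt_cutoff
  keep <- !no_resp & !too_slow
  list(trials = trials[keep, ],
       log = tibble(reason = c("non_response", paste0("rt_over_", rt_cutoff, "s")),
                    n = c(sum(no_resp), sum(too_slow))))
}

#' Per-subject crossmodal congruency metrics
#'
#' Median RT per congruency condition over correct-response trials (pooled
#' across target digits), accuracy in percent per condition over responded
#' trials, and the congruency differences
#' `cce_rt = median_rt(incongruent) - median_rt(congruent)` (s) and
#' `cce_acc = accuracy(congruent) - accuracy(incongruent)` (percentage
#' points), plus tactile-only baseline RT and accuracy. An empty condition
#' flags the subject excluded with no metrics.
#'
#' @param trials Filtered CCE trials of a single subject.
#' @param center `"median"` (default, the operative definition) or `"mean"`.
#' @return One-row tibble (a `CCEResult`).
#' @export
compute_cce <- function(trials, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(all(trials$task == "CCE"))
  sid <- unique(trials$subject_id)
  stopifnot(length(sid) == 1)
  cfun <- if (center == "median") median else mean

  stat <- function(cond) {
    sub <- trials[trials$condition == cond, ]
    ok <- sub[!is.na(sub$correct) & sub$correct, ]
    list(n = nrow(sub),
         rt = if (nrow(ok)) cfun(ok$rt_s) else NA_real_,
         acc = if (nrow(sub)) 100 * mean(sub$correct, na.rm = TRUE) else NA_real_)
  }
  s <- lapply(setNames(.cce_conditions, .cce_conditions), stat)
  counts <- table(factor(paste(trials$condition, trials$digit),
                         levels = paste(rep(.cce_conditions, each = 2), .cce_digits)))
  empty <- any(vapply(s, function(x) x$n == 0 || is.na(x$rt), logical(1)))

  tibble(
    subject_id = sid,
    n_baseline = s$baseline$n, n_congruent = s$congruent$n,
    n_incongruent = s$incongruent$n,
    min_cell_count = min(counts),
    median_rt_baseline = s$baseline$rt,
    median_rt_congruent = s$congruent$rt,
    median_rt_incongruent = s$incongruent$rt,
    acc_baseline = s$baseline$acc,
    acc_congruent = s$congruent$acc,
    acc_incongruent = s$incongruent$acc,
    baseline_rt = s$baseline$rt,
    baseline_acc = s$baseline$acc,
    cce_rt = if (empty) NA_real_ else s$incongruent$rt - s$congruent$rt,
    cce_acc = if (empty) NA_real_ else s$congruent$acc - s$incongruent$acc,
    excluded = empty,
    exclusion_reason = if (empty) "empty_condition" else NA_character_)
}

#' Exclude subjects with too few surviving trials
#'
#' A subject is flagged excluded when any of the six condition cells
#' (3 congruency conditions x 2 target digits) retains fewer than
#' `min_trials` trials after filtering; exactly `min_trials` is kept.
#' Metrics of excluded subjects are blanked.
#'
#' @param results Tibble of per-subject `CCEResult` rows ([compute_cce()]).
#' @param min_trials Minimum trials per condition cell (default 10).
#' @return The results tibble with updated `excluded` flags.
#' @export
exclude_low_count_subjects <- function(results, min_trials = 10) {
  low <- results$min_cell_count < min_trials
  results$excluded <- results$excluded | low
  results$exclusion_reason <- ifelse(
    low & is.na(results$exclusion_reason),
    sprintf("fewer_than_%d_trials_per_condition", min_trials),
    results$exclusion_reason)
  results$cce_rt[results$excluded] <- NA_real_
  results$cce_acc[results$excluded] <- NA_real_
  results
}

#' Run the CCE pipeline over a cohort
#'
#' Filters trials, computes per-subject congruency metrics, and applies the
#' low-trial-count exclusion.
#'
#' @param dataset A `pps_dataset` (or trial tibble) containing CCE trials.
#' @param rt_cutoff,min_trials Cleaning thresholds.
#' @param center Passed to [compute_cce()].
#' @return List: `results` (per-subject tibble), `rejections` (per-subject
#'   trial rejection log), `n_excluded`.
#' @export
cce_results <- function(dataset, rt_cutoff = 2.0, min_trials = 10,
                        center = "median") {
  trials <- if (inherits(dataset, "pps_dataset")) dataset$trials else dataset
  trials <- trials[trials$task == "CCE", ]
  if (!nrow(trials)) stop("no CCE trials in input")
  out <- lapply(split(trials, trials$subject_id), function(tt) {
    f <- filter_trials_cce(tt, rt_cutoff)
    res <- compute_cce(f$trials, center = center)
    f$log$subject_id <- res$subject_id
    list(res = res, log = f$log)
  })
  results <- do.call(rbind, lapply(out, `[[`, "res"))
  results <- exclude_low_count_subjects(results, min_trials)
  list(results = results,
       rejections = do.call(rbind, lapply(out, `[[`, "log")),
       n_excluded = sum(results$excluded))
}

#' One-sample contrast against zero
#'
#' Two-sided one-sample test of the mean (t-test, default) or the median
#' (Wilcoxon signed-rank) against zero, used to establish that a congruency
#' or facilitation effect exists at the group level. When every value is
#' zero the variance is undefined and the contrast is reported as "no
#' effect" (statistic 0, p = 1).
#'
#' @param values Numeric vector, at least 2 finite values.
#' @param method `"t"` or `"wilcoxon"`.
#' @return List with `statistic`, `p`, `n`, `mean`, `method`.
#' @export
contrast_vs_zero <- function(values, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  if (sd(values) == 0) {
    if (all(values == 0))
      return(list(statistic = 0, p = 1, n = length(values), mean = 0,
                  method = method, note = "all values zero; no effect"))
    return(list(statistic = sign(mean(values)) * Inf, p = 0,
                n = length(values), mean = mean(values), method = method,
                note = "zero variance at nonzero mean"))
  }
  if (method == "t") {
    tt <- t.test(values, mu = 0)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         n = length(values), mean = mean(values), method = "t")
  } else {
    wt <- wilcox.test(values, mu = 0, exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         n = length(values), mean = mean(values), method = "wilcoxon")
  }
}
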