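# Peripersonal-space pipeline: trial cleaning, expectancy diagnostic,
# time-matched approach-minus-receding subtraction, and the paired
# facilitation contrast against the tactile-only baseline.

#' Filter PPS trials
#'
#' Applies the same cleaning as the CCE task: drops non-responses and
#' responses slower than the cutoff (strict inequality). Catch trials are
#' set aside (they are scored separately as false alarms, not RTs).
#'
#' @param trials Trial-log tibble containing only PPS trials.
#' @param rt_cutoff Discard threshold in seconds (default 2.0 s).
#' @return List with `trials` (kept experimental + baseline rows), `catch`
#'   (catch rows untouched) and `log`.
#' @export
filter_trials_pps <- function(trials, rt_cutoff = 2.0) {
  stopifnot(all(trials$task == "PPS"), rt_cutoff > 0)
  catch <- trials[trials$condition == "catch", ]
  tact <- trials[trials$condition != "catch", ]
  no_resp <- !tact$responded | is.na(tact$rt_s)
  too_slow <- !no_resp & tact$rt_s > rt_cutoff
  keep <- !no_resp & !too_slow
  list(trials = tact[keep, ], catch = catch,
       log = tibble(reason = c("non_response", paste0("rt_over_", rt_cutoff, "s")),
                    n = c(sum(no_resp), sum(too_slow))))
}

#' Expectancy-effect diagnostic
#'
#' Least-squares slope of RT on tactile onset time over the experimental
#' trials, pooled over directions. A negative slope means RTs speed up the
#' longer the touch is withheld — the temporal confound the time-matched
#' subtraction removes.
#'
#' @param trials PPS experimental trials (responded, both directions).
#' @return List with `slope` (s of RT change per s of onset time), `ci`
#'   (95% confidence bounds), `n`.
#' @export
expectancy_diagnostic <- function(trials) {
  tt <- trials[trials$condition == "experimental" & trials$responded &
                 !is.na(trials$rt_s), ]
  if (length(unique(tt$onset_time_s)) < 2)
    stop("need at least 2 distinct onset times")
  fit <- lm(rt_s ~ onset_time_s, data = tt)
  ci <- tryCatch(confint(fit)["onset_time_s", ], error = function(e) c(NA, NA))
  list(slope = unname(coef(fit)["onset_time_s"]), ci = unname(ci),
       n = nrow(tt))
}

#' Time-matched approach-minus-receding subtraction
#'
#' Inverts the spatial dimension for the receding condition so that the
#' subtraction equates elapsed time while differentiating distance:
#' `delta_i = mean RT(approach, D_i) - mean RT(recede, D_(12-i))` for
#' i = 1..11 (approach D1 is matched with recede D11, D2 with D10, ...).
#' Distances are reported in the approach frame of reference, D1 nearest
#' the hand. Any empty cell among the 22 flags the subject unfittable.
#'
#' @param trials Filtered PPS trials of a single subject
#'   ([filter_trials_pps()]).
#' @return A `delta_curve`: list with `subject_id`, `distances_cm`, `delta`
#'   (11 values, s), `n_approach`/`n_recede` per-cell counts, `baseline_rt`
#'   (mean tactile-only RT, s), `complete` flag.
#' @export
time_matched_subtraction <- function(trials) {
  stopifnot(all(trials$task == "PPS"))
  sid <- unique(trials$subject_id)
  stopifnot(length(sid) == 1)
  ex <- trials[trials$condition == "experimental" & !is.na(trials$rt_s), ]
  cell_mean <- function(dir) {
    m <- rep(NA_real_, 11); nn <- integer(11)
    sub <- ex[ex$direction == dir, ]
    if (nrow(sub)) {
      agg <- tapply(sub$rt_s, factor(sub$distance_index, levels = 1:11), mean)
      cnt <- tapply(sub$rt_s, factor(sub$distance_index, levels = 1:11), length)
      m <- as.numeric(agg); nn <- ifelse(is.na(cnt), 0L, as.integer(cnt))
    }
    list(mean = m, n = nn)
  }
  ap <- cell_mean("approach"); re <- cell_mean("recede")
  delta <- ap$mean - re$mean[12 - (1:11)]
  base <- trials[trials$condition == "baseline" & !is.na(trials$rt_s), ]
  structure(list(
    subject_id = sid,
    distances_cm = pps_distances(),
    delta = delta,
    n_approach = ap$n,
    n_recede = re$n[12 - (1:11)],
    baseline_rt = if (nrow(base)) mean(base$rt_s) else NA_real_,
    complete = all(is.finite(delta))),
    class = "delta_curve")
}

#' @export
print.delta_curve <- function(x, ...) {
  cat("<delta_curve>", x$subject_id, if (!x$complete) "(incomplete)", "\n")
  print(round(setNames(x$delta, paste0("D", 1:11)), 4))
  invisible(x)
}

#' Paired facilitation contrast at the nearest distance
#'
#' For each subject, compares the mean approach RT at D1 (the
#' expectancy-corrected multisensory RT nearest the body: its 2.5 s onset is
#' time-matched with the late tactile-only baseline) against the mean
#' tactile-only baseline RT at the same temporal onset, with a paired
#' two-sided t-test. A negative mean difference is multisensory
#' facilitation.
#'
#' @param trials Filtered PPS trials of one or more subjects.
#' @return List with `statistic`, `p`, `n`, `mean_difference` (s,
#'   multisensory minus baseline).
#' @export
baseline_contrast <- function(trials) {
  stopifnot(all(trials$task == "PPS"))
  per <- lapply(split(trials, trials$subject_id), function(tt) {
    ms <- tt[tt$condition == "experimental" & tt$direction == "approach" &
               tt$distance_index == 1L & !is.na(tt$rt_s), ]
    # the late baseline (onset 2.5 s) is the time-matched tactile-only control
    ba <- tt[tt$condition == "baseline" & tt$onset_time_s > 1 &
               !is.na(tt$rt_s), ]
    if (!nrow(ba)) stop("missing baseline trials for subject ",
                        unique(tt$subject_id))
    c(ms = mean(ms$rt_s), ba = mean(ba$rt_s))
  })
  m <- do.call(rbind, per)
  d <- m[, "ms"] - m[, "ba"]
  d <- d[is.finite(d)]
  if (length(d) < 2 || sd(d) == 0)
    return(list(statistic = NA_real_, p = 1, n = length(d),
                mean_difference = mean(d),
                note = "degenerate: fewer than 2 informative pairs"))
  tt <- t.test(d, mu = 0)
  list(statistic = unname(tt$statistic), p = tt$p.value, n = length(d),
       mean_difference = mean(d))
}

#' Catch-trial false alarms
#'
#' Fraction of catch (visual-only) trials with a response, per subject.
#'
#' @param trials PPS trials (unfiltered).
#' @return Tibble with `subject_id`, `n_catch`, `false_alarms`, `fa_rate`.
#' @export
catch_false_alarms <- function(trials) {
  ct <- trials[trials$task == "PPS" & trials$condition == "catch", ]
  out <- lapply(split(ct, ct$subject_id), function(tt)
    tibble(subject_id = unique(tt$subject_id), n_catch = nrow(tt),
           false_alarms = sum(tt$responded, na.rm = TRUE),
           fa_rate = mean(tt$responded, na.rm = TRUE)))
  do.call(rbind, out)
}
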