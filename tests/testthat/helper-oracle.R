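# Independent oracles and fixture builders used across test files.

# Exhaustive grid-search oracle for the sigmoid fit: minimum SSE over
# xc in [5, 105], b in [0.5, 50] at 0.25 cm resolution, written with its own
# arithmetic (no shared code with the fitting routine).
oracle_grid_sse <- function(y, x = pps_distances(),
                            xc_grid = seq(5, 105, by = 0.25),
                            b_grid = seq(0.5, 50, by = 0.25)) {
  ymin <- min(y); ymax <- max(y)
  best <- Inf
  for (b in b_grid) {
    z <- outer(xc_grid, x, function(xc, xx) (xx - xc) / b)
    pred <- ymin + (ymax - ymin) / (1 + exp(-z))
    best <- min(best, min(rowSums(sweep(pred, 2, y)^2)))
  }
  best
}

# One-row subject table for single-subject fixtures.
one_subject <- function(id = "S1", group = "TD") {
  tibble::tibble(subject_id = id, group = group, age = 30, gender = "M",
                 fsiq = 100, srs_total_t = 50,
                 panss_pos = NA_real_, panss_neg = NA_real_)
}

# Hand-rolled CCE trial table: one row per RT with given condition/digit,
# all responded and correct unless stated.
cce_trials <- function(rts, condition, digit = "thumb", correct = TRUE,
                       responded = TRUE, id = "S1") {
  n <- length(rts)
  tibble::tibble(
    subject_id = id, task = "CCE", trial_index = seq_len(n),
    condition = rep_len(condition, n), digit = rep_len(digit, n),
    direction = NA_character_, distance_index = NA_integer_,
    onset_time_s = 0, rt_s = rts,
    responded = rep_len(responded, n), correct = rep_len(correct, n))
}

# PPS experimental trial table with explicit per-trial direction/distance.
pps_trials <- function(rts, direction, distance_index, id = "S1",
                       condition = "experimental") {
  n <- length(rts)
  di <- rep_len(distance_index, n)
  dir <- rep_len(direction, n)
  tibble::tibble(
    subject_id = id, task = "PPS", trial_index = seq_len(n),
    condition = rep_len(condition, n), digit = NA_character_,
    direction = dir, distance_index = di,
    onset_time_s = pps_onset_time(di, dir),
    rt_s = rts, responded = TRUE, correct = NA)
}

# A reduced session plan containing `reps` copies of selected rows of a full
# PPS plan (used for targeted Monte-Carlo checks without the full session).
subset_plan <- function(plan, keep, reps = 1) {
  rows <- plan$trials[rep(which(keep), reps), ]
  rows$trial_index <- seq_len(nrow(rows))
  plan$trials <- rows
  plan
}

# Small cohort spec for workflow tests: trims group sizes and tightens
# nothing else.
small_cohort <- function(n_td = 12, n_asd = 12, n_sz = 12,
                         sim_tasks = c("CCE", "PPS")) {
  sp <- cohort_spec(sim_tasks = sim_tasks)
  sp$groups$TD$n <- n_td
  sp$groups$ASD$n <- n_asd
  sp$groups$SZ$n <- n_sz
  sp
}
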