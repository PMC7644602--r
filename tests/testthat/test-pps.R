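test_that("subtraction pairs approach D_i with recede D_(12-i)", {
  # approach means 0.30 at every distance; recede 0.35 only at D10: the
  # pairing must surface at delta_2 (approach D2 ~ recede D10), nowhere else
  ap <- pps_trials(rep(0.30, 22), "approach", rep(1:11, 2))
  re <- pps_trials(rep(c(0.32, 0.35), c(20, 2)), "recede",
                   c(rep(setdiff(1:11, 10), 2)[1:20], 10, 10))
  dc <- time_matched_subtraction(rbind(ap, re))
  expect_equal(dc$delta[2], 0.30 - 0.35, tolerance = 1e-12)
  expect_equal(dc$delta[-2], rep(0.30 - 0.32, 10), tolerance = 1e-12)
})

test_that("delta vector equals the hand-computed subtraction", {
  ap_means <- seq(0.30, 0.40, length.out = 11)   # approach D1..D11
  re_means <- seq(0.45, 0.35, length.out = 11)   # recede D1..D11
  ap <- pps_trials(ap_means, "approach", 1:11)
  re <- pps_trials(re_means, "recede", 1:11)
  dc <- time_matched_subtraction(rbind(ap, re))
  expect_equal(dc$delta, ap_means - re_means[11:1], tolerance = 1e-12)
  expect_true(dc$complete)
})

test_that("subtraction is equivariant to constant shifts of approach RTs", {
  pars <- generative_params()
  tt <- simulate_pps_subject(pars, build_pps_session(12), 40)
  f <- filter_trials_pps(tt)$trials
  d0 <- time_matched_subtraction(f)$delta
  shifted <- f
  idx <- shifted$condition == "experimental" & shifted$direction == "approach"
  shifted$rt_s[idx] <- shifted$rt_s[idx] + 0.111
  expect_equal(time_matched_subtraction(shifted)$delta, d0 + 0.111,
               tolerance = 1e-12)
})

test_that("an empty cell flags the subject unfittable", {
  ap <- pps_trials(rep(0.3, 10), "approach", c(1:9, 9))  # no approach D10, D11
  re <- pps_trials(rep(0.35, 11), "recede", 1:11)
  dc <- time_matched_subtraction(rbind(ap, re))
  expect_false(dc$complete)
  fit <- fit_sigmoid(dc)
  expect_false(fit$converged)
  expect_false(fit$kept)
})

test_that("a pure expectancy effect cancels exactly in the subtraction", {
  # kappa != 0, zero amplitude, zero noise: time-matched cells share onset
  # times, so every delta is exactly zero
  pars <- generative_params(sigma = 0, tau = 0, lapse_rate = 0,
                            amp_approach = 0, amp_recede = 0, kappa = 0.03)
  tt <- simulate_pps_subject(pars, build_pps_session(13), 41)
  dc <- time_matched_subtraction(filter_trials_pps(tt)$trials)
  expect_equal(dc$delta, rep(0, 11), tolerance = 1e-12)
})

test_that("expectancy diagnostic recovers the programmed drift", {
  pars0 <- generative_params(sigma = 0, tau = 0, lapse_rate = 0,
                             amp_approach = 0, amp_recede = 0, kappa = 0.02)
  tt <- simulate_pps_subject(pars0, build_pps_session(14), 42)
  ed <- suppressWarnings(expectancy_diagnostic(tt))  # noiseless fit is exact
  expect_equal(ed$slope, -0.02, tolerance = 1e-10)

  # with noise: sign recovered, and null kappa covered by the CI
  plan <- build_pps_session(15)
  sign_ok <- 0; cover <- 0; n_sim <- 60
  for (i in seq_len(n_sim)) {
    ttk <- simulate_pps_subject(
      generative_params(amp_approach = 0, amp_recede = 0, kappa = 0.02),
      plan, 500 + i)
    sign_ok <- sign_ok + (expectancy_diagnostic(ttk)$slope < 0)
    tt0 <- simulate_pps_subject(
      generative_params(amp_approach = 0, amp_recede = 0, kappa = 0),
      plan, 700 + i)
    ci <- expectancy_diagnostic(tt0)$ci
    cover <- cover + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(sign_ok / n_sim, 0.95)
  expect_gte(cover / n_sim, 0.90)
  expect_error(expectancy_diagnostic(pps_trials(0.3, "approach", 1)),
               "distinct onset")
})

test_that("sigmoid fit recovers noiseless curves generated from its form", {
  x <- pps_distances()
  y <- pps_sigmoid(x, xc = 45, b = 5, ymin = -0.05, ymax = 0)
  fit <- fit_sigmoid(y, ymin = -0.05, ymax = 0)
  expect_lt(abs(fit$xc - 45), 1e-6)
  expect_lt(abs(fit$b - 5), 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
  # saturations fixed from the curve: recovery still tight
  fit2 <- fit_sigmoid(y)
  expect_lt(abs(fit2$xc - 45), 0.5)
  expect_gt(fit2$r2, 0.999)
})

test_that("a constant curve yields r2 = 0 and is not kept", {
  fit <- fit_sigmoid(rep(0.02, 11))
  expect_equal(fit$r2, 0)
  expect_false(fit$kept)
})

test_that("bounded least squares matches the exhaustive grid oracle", {
  set.seed(202)
  for (i in 1:12) {
    xc <- runif(1, 10, 100); b <- runif(1, 1, 30)
    y <- pps_sigmoid(pps_distances(), xc, b, -0.05, 0) + rnorm(11, 0, 0.012)
    fit <- fit_sigmoid(y)
    oracle <- oracle_grid_sse(y)
    expect_lte(fit$sse, oracle * (1 + 1e-6))
  }
})

test_that("larger fitted b means a shallower slope at the central point", {
  h <- 1e-6
  for (b in c(2, 5, 20)) {
    num <- (pps_sigmoid(50 + h, 50, b, -0.05, 0) -
              pps_sigmoid(50 - h, 50, b, -0.05, 0)) / (2 * h)
    expect_equal(num, 0.05 / (4 * b), tolerance = 1e-4)
  }
})

test_that("fit retention uses a strict R-squared inequality", {
  set.seed(301)
  y <- pps_sigmoid(pps_distances(), 50, 8, -0.05, 0) + rnorm(11, 0, 0.02)
  fit <- fit_sigmoid(y)
  at <- fit_sigmoid(y, r2_cutoff = fit$r2)        # cutoff equals r2: dropped
  below <- fit_sigmoid(y, r2_cutoff = fit$r2 - 1e-9)
  expect_false(at$kept)
  expect_true(below$kept)
})

test_that("retention log counts kept fits per group", {
  fits <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:20),
    xc = 50, b = 5, ymin = -0.05, ymax = 0, sse = 0,
    r2 = c(rep(0.9, 18), 0.2, 0.1),
    converged = TRUE,
    kept = c(rep(TRUE, 18), FALSE, FALSE))
  out <- filter_fits(fits)
  expect_equal(out$log$attempted, 20)
  expect_equal(out$log$kept, 18)
  expect_equal(nrow(out$kept), 18)
})

test_that("nearest-distance facilitation contrast detects the effect", {
  plan <- build_pps_session(16)
  keep <- (plan$trials$condition == "experimental" &
             plan$trials$direction == "approach" &
             plan$trials$distance_index == 1) |
    (plan$trials$condition == "baseline" & plan$trials$onset_time_s > 1)
  mini <- subset_plan(plan, keep)
  sim_cohort_trials <- function(amp, seed0, n_subj = 12) {
    do.call(rbind, lapply(seq_len(n_subj), function(i)
      simulate_pps_subject(generative_params(amp_approach = amp),
                           mini, seed0 + i, sprintf("S%02d", i))))
  }
  hits <- 0; n_sim <- 20
  for (s in seq_len(n_sim)) {
    tt <- sim_cohort_trials(0.05, 3000 + 100 * s)
    res <- baseline_contrast(filter_trials_pps(tt)$trials)
    hits <- hits + (res$p < 0.05 && res$mean_difference < 0)
  }
  expect_gte(hits, 19)

  # type-I control at zero amplitude
  set.seed(9)
  rej <- 0; n_null <- 150
  for (s in seq_len(n_null)) {
    tt <- sim_cohort_trials(0, 40000 + 100 * s)
    rej <- rej + (baseline_contrast(filter_trials_pps(tt)$trials)$p < 0.05)
  }
  expect_gt(rej / n_null, 0.01)
  expect_lt(rej / n_null, 0.11)
})

test_that("catch false alarms are scored per subject", {
  pars <- generative_params(fa_rate = 0.5)
  tt <- simulate_pps_subject(pars, build_pps_session(17), 44)
  fa <- catch_false_alarms(tt)
  expect_equal(fa$n_catch, 78)
  expect_gt(fa$fa_rate, 0.25)
  expect_lt(fa$fa_rate, 0.75)
})
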