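test_that("simulation is deterministic given params, plan and seed", {
  pars <- generative_params()
  pp <- build_pps_session(2)
  cp <- build_cce_session(2)
  expect_identical(simulate_pps_subject(pars, pp, 9),
                   simulate_pps_subject(pars, pp, 9))
  expect_identical(simulate_cce_subject(pars, cp, 9),
                   simulate_cce_subject(pars, cp, 9))
  sp <- small_cohort(2, 1, 1)
  expect_identical(simulate_cohort(sp, 11)$trials,
                   simulate_cohort(sp, 11)$trials)
})

test_that("task mismatch between params/plan and simulator errors", {
  pars <- generative_params()
  expect_error(simulate_pps_subject(pars, build_cce_session(1), 1),
               "task mismatch")
  expect_error(simulate_cce_subject(pars, build_pps_session(1), 1),
               "task mismatch")
})

test_that("zero noise makes every RT an exact function of the parameters", {
  pars <- generative_params(sigma = 0, tau = 0, lapse_rate = 0, fa_rate = 0,
                            kappa = 0.02, amp_approach = 0.05,
                            amp_recede = 0.01, xc_true = 45, b_true = 5)
  tt <- simulate_pps_subject(pars, build_pps_session(3), 1)
  ex <- tt[tt$condition == "experimental", ]
  expected <- pars$mu - pars$kappa * ex$onset_time_s -
    ifelse(ex$direction == "approach", pars$amp_approach, pars$amp_recede) *
    facilitation_profile(pps_distances()[ex$distance_index], 45, 5)
  expect_equal(ex$rt_s, expected, tolerance = 1e-12)
  base <- tt[tt$condition == "baseline", ]
  expect_equal(base$rt_s, pars$mu - pars$kappa * base$onset_time_s,
               tolerance = 1e-12)
  expect_true(all(!tt$responded[tt$condition == "catch"]))
})

test_that("zero-signal generator yields flat per-distance differences", {
  pars <- generative_params(amp_approach = 0, amp_recede = 0, kappa = 0)
  tt <- simulate_pps_subject(pars, build_pps_session(5), 21)
  dc <- time_matched_subtraction(filter_trials_pps(tt)$trials)
  # |delta| < 3 SEM where SEM of a 16+16-trial difference of means
  sem <- sqrt(2 * (pars$sigma^2 + pars$tau^2) / 16)
  expect_true(all(abs(dc$delta) < 3 * sem))
})

test_that("Monte-Carlo mean at D1 matches the closed-form mean", {
  pars <- generative_params(tau = 0)
  plan <- build_pps_session(4)
  keep <- plan$trials$condition == "experimental" &
    plan$trials$direction == "approach" & plan$trials$distance_index == 1
  big <- subset_plan(plan, keep, reps = 10000 / sum(keep))
  tt <- simulate_pps_subject(pars, big, 8)
  expected <- pars$mu - pars$kappa * pps_onset_time(1, "approach") -
    pars$amp_approach * facilitation_profile(5, pars$xc_true, pars$b_true)
  got <- mean(tt$rt_s, na.rm = TRUE)
  sem <- pars$sigma / sqrt(sum(!is.na(tt$rt_s)))
  expect_lt(abs(got - expected), 3 * sem)
})

test_that("all generated RTs are positive and catch trials carry no onset", {
  pars <- generative_params(sigma = 0.3, tau = 0.3)  # heavy noise vs floor
  tt <- simulate_pps_subject(pars, build_pps_session(6), 10)
  expect_true(all(tt$rt_s[!is.na(tt$rt_s)] > 0))
  expect_true(all(is.na(tt$onset_time_s[tt$condition == "catch"])))
})

test_that("noiseless CCE effects equal the programmed shifts exactly", {
  pars <- generative_params(sigma = 0, tau = 0, lapse_rate = 0,
                            cce_congruent_benefit = 0.025,
                            cce_incongruent_cost = 0.025,
                            acc_base = 1, acc_congruent = 1,
                            acc_incongruent = 1)
  tt <- simulate_cce_subject(pars, build_cce_session(4), 2)
  res <- compute_cce(filter_trials_cce(tt)$trials)
  expect_equal(res$cce_rt, 0.05, tolerance = 1e-12)
  expect_equal(res$cce_rt, pars$cce_congruent_benefit + pars$cce_incongruent_cost,
               tolerance = 1e-12)
})

test_that("accuracy difference converges to the Bernoulli means", {
  pars <- generative_params(acc_congruent = 1, acc_incongruent = 0.8,
                            lapse_rate = 0)
  plan <- build_cce_session(9)
  big <- subset_plan(plan, rep(TRUE, nrow(plan$trials)), reps = 40)  # 3600 trials
  tt <- simulate_cce_subject(pars, big, 6)
  res <- compute_cce(filter_trials_cce(tt)$trials)
  expect_lt(abs(res$cce_acc - 20), 3)  # 3 pp ~ 3 SE at n = 600/cell
})

test_that("cohort simulation respects sizes, totals and missingness", {
  sp <- small_cohort(0, 1, 0)
  ds <- simulate_cohort(sp, 13)
  expect_equal(nrow(ds$subjects), 1)
  expect_equal(nrow(ds$trials), 552)
  expect_true(all(c("xc_true", "b_true") %in% names(ds$meta$truth)))

  sp0 <- small_cohort(0, 0, 0)
  expect_error(simulate_cohort(sp0, 1), "no subjects")

  spbad <- small_cohort(2, 2, 2)
  spbad$groups$TD$xc_sd <- -1
  expect_error(cohort_spec(groups = spbad$groups), "negative SD")

  # missingness lands only in the declared covariates
  sp2 <- small_cohort(20, 0, 0)
  sp2$groups$TD$miss_fsiq <- 0.5
  ds2 <- simulate_cohort(sp2, 17)
  expect_gt(sum(is.na(ds2$subjects$fsiq)), 0)
  expect_true(all(!is.na(ds2$subjects$age)))
  expect_true(all(ds2$subjects$fsiq >= 70, na.rm = TRUE))
})

test_that("true group difference in PPS size is recovered downstream", {
  # TD xc 60 vs ASD xc 30, SD 5, n = 20/20: the sign of the fitted group
  # difference should be recovered in nearly every simulated cohort.
  plan <- build_pps_session(31)
  correct <- 0
  n_sim <- 100
  for (s in seq_len(n_sim)) {
    fit_mean <- function(xc_mean, off) {
      set.seed(9000 + s * 7 + off)
      xcs <- pmin(105, pmax(5, rnorm(20, xc_mean, 5)))
      vapply(seq_along(xcs), function(i) {
        pars <- generative_params(xc_true = xcs[i])
        tt <- simulate_pps_subject(pars, plan, 9000 + s * 211 + off * 31 + i)
        fit_sigmoid(time_matched_subtraction(filter_trials_pps(tt)$trials))$xc
      }, numeric(1))
    }
    if (mean(fit_mean(30, 1), na.rm = TRUE) <
        mean(fit_mean(60, 2), na.rm = TRUE)) correct <- correct + 1
  }
  expect_gte(correct, 95)
})
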