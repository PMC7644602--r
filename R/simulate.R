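# Trial-level generator. The study does not report raw RT magnitudes or
# facilitation amplitudes, so the defaults here are artifact configuration
# chosen as typical speeded tactile-detection values, not paper claims.

#' Generative parameters for one simulated subject
#'
#' The PPS model is
#' `RT = mu - kappa * onset - amp_dir * L(d) + exGaussian(0, sigma, tau)`
#' with `L(d) = 1 / (1 + exp((d - xc_true) / b_true))`, so `L -> 1` near the
#' body: approaching (and more weakly receding) visual stimuli speed tactile
#' RTs inside the peripersonal radius `xc_true`, with boundary sharpness set
#' by `b_true`. `kappa` is the expectancy drift: RT falls linearly with the
#' elapsed time from trial onset to touch. The CCE model shifts a baseline
#' RT by `-cce_congruent_benefit` or `+cce_incongruent_cost` and draws
#' response correctness from per-condition accuracies.
#'
#' @param mu Baseline tactile RT, s (Gaussian component mean).
#' @param sigma,tau Ex-Gaussian noise: Gaussian SD and exponential tail mean,
#'   s. The exponential tail adds `tau` to every mean; it cancels in all
#'   difference scores.
#' @param amp_approach,amp_recede Maximal multisensory facilitation, s.
#' @param xc_true PPS central point, cm (in `[5, 105]`).
#' @param b_true PPS gradient parameter, cm (> 0; smaller = sharper boundary).
#' @param kappa Expectancy slope, s of RT reduction per s of onset time.
#' @param lapse_rate Probability a response is omitted.
#' @param fa_rate Catch-trial false-alarm probability.
#' @param cce_congruent_benefit,cce_incongruent_cost CCE RT shifts, s.
#' @param acc_base,acc_congruent,acc_incongruent CCE accuracy probabilities.
#' @return A validated `generative_params` list.
#' @export
generative_params <- function(mu = 0.35, sigma = 0.02, tau = 0.035,
                              amp_approach = 0.050, amp_recede = 0.010,
                              xc_true = 45, b_true = 5, kappa = 0.02,
                              lapse_rate = 0.02, fa_rate = 0.005,
                              cce_congruent_benefit = 0.030,
                              cce_incongruent_cost = 0.050,
                              acc_base = 0.95, acc_congruent = 0.97,
                              acc_incongruent = 0.85) {
  p <- as.list(environment())
  stopifnot(p$mu > 0, p$sigma >= 0, p$tau >= 0, p$b_true > 0,
            p$xc_true >= 5, p$xc_true <= 105)
  probs <- c(p$lapse_rate, p$fa_rate, p$acc_base, p$acc_congruent,
             p$acc_incongruent)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(p, class = "generative_params")
}

#' Multisensory facilitation profile
#'
#' `L(d) = 1 / (1 + exp((d - xc) / b))`: 1 well inside the peripersonal
#' radius, 0 well outside, 1/2 at `d = xc`.
#'
#' @param d_cm Distance in cm.
#' @param xc,b Central point and gradient parameter, cm.
#' @return Facilitation fraction in (0, 1).
#' @export
facilitation_profile <- function(d_cm, xc, b) plogis(-(d_cm - xc) / b)

# Ex-Gaussian noise centred so its Gaussian component has mean zero; the
# exponential component contributes a +tau mean shift, as usual for RT models.
rexgauss <- function(n, sigma, tau) {
  g <- if (sigma > 0) rnorm(n, 0, sigma) else numeric(n)
  e <- if (tau > 0) rexp(n, rate = 1 / tau) else numeric(n)
  g + e
}

.rt_floor <- 0.1  # physical floor on simulated RTs, s

#' Simulate one subject's PPS session
#'
#' Experimental trials follow the generative model of
#' [generative_params()]; baseline (tactile-only) trials use zero
#' facilitation amplitude; catch trials elicit a response with probability
#' `fa_rate` and never carry a tactile onset. Responses lapse (are omitted)
#' with probability `lapse_rate`. RTs are floored at 0.1 s.
#'
#' @param params A `generative_params` object.
#' @param plan A PPS `session_plan` from [build_pps_session()].
#' @param seed Integer seed; identical params + plan + seed give an
#'   identical trial table.
#' @param subject_id Label for the output rows.
#' @return Tibble in the trial-log schema.
#' @export
simulate_pps_subject <- function(params, plan, seed, subject_id = "S1") {
  stopifnot(inherits(params, "generative_params"),
            inherits(plan, "session_plan"))
  if (plan$task != "PPS") stop("task mismatch: plan is for ", plan$task)
  tr <- plan$trials
  n <- nrow(tr)
  with_seed(seed, {
    amp <- numeric(n)
    is_exp <- tr$condition == "experimental"
    amp[is_exp] <- ifelse(tr$direction[is_exp] == "approach",
                          params$amp_approach, params$amp_recede) *
      facilitation_profile(pps_distances()[tr$distance_index[is_exp]],
                           params$xc_true, params$b_true)
    det_rt <- params$mu - params$kappa * ifelse(is.na(tr$onset_time_s), 0,
                                                tr$onset_time_s) - amp
    rt <- pmax(.rt_floor, det_rt + rexgauss(n, params$sigma, params$tau))

    is_catch <- tr$condition == "catch"
    responded <- rep(NA, n)
    responded[!is_catch] <- runif(sum(!is_catch)) >= params$lapse_rate
    responded[is_catch] <- runif(sum(is_catch)) < params$fa_rate
    rt[!responded] <- NA_real_

    tibble(
      subject_id = subject_id,
      task = "PPS",
      trial_index = tr$trial_index,
      condition = tr$condition,
      digit = NA_character_,
      direction = tr$direction,
      distance_index = tr$distance_index,
      onset_time_s = tr$onset_time_s,
      rt_s = rt,
      responded = responded,
      correct = NA)
  })
}

#' Simulate one subject's CCE session
#'
#' `RT = mu + shift(condition) + exGaussian noise`, floored at 0.1 s, with
#' `shift(baseline) = 0`, `shift(congruent) = -cce_congruent_benefit`,
#' `shift(incongruent) = +cce_incongruent_cost`; correctness is Bernoulli
#' with the condition's accuracy. Lapses omit the response.
#'
#' @inheritParams simulate_pps_subject
#' @param plan A CCE `session_plan` from [build_cce_session()].
#' @return Tibble in the trial-log schema.
#' @export
simulate_cce_subject <- function(params, plan, seed, subject_id = "S1") {
  stopifnot(inherits(params, "generative_params"),
            inherits(plan, "session_plan"))
  if (plan$task != "CCE") stop("task mismatch: plan is for ", plan$task)
  tr <- plan$trials
  n <- nrow(tr)
  with_seed(seed, {
    shift <- unname(c(baseline = 0,
                      congruent = -params$cce_congruent_benefit,
                      incongruent = params$cce_incongruent_cost)[tr$condition])
    acc <- unname(c(baseline = params$acc_base,
                    congruent = params$acc_congruent,
                    incongruent = params$acc_incongruent)[tr$condition])
    rt <- pmax(.rt_floor, params$mu + shift + rexgauss(n, params$sigma, params$tau))
    responded <- runif(n) >= params$lapse_rate
    correct <- runif(n) < acc
    rt[!responded] <- NA_real_
    correct[!responded] <- NA

    tibble(
      subject_id = subject_id,
      task = "CCE",
      trial_index = tr$trial_index,
      condition = tr$condition,
      digit = tr$digit,
      direction = NA_character_,
      distance_index = NA_integer_,
      onset_time_s = tr$onset_time_s,
      rt_s = rt,
      responded = responded,
      correct = correct)
  })
}

.group_default <- function(n, xc_mean, xc_sd, b_mean, b_sd, age_mean, age_sd,
                           fsiq_mean, fsiq_sd, srs_mean, srs_sd, p_male,
                           miss_gender = 0, miss_fsiq = 0,
                           panss_pos_mean = NA, panss_neg_mean = NA,
                           panss_sd = 5,
                           amp_approach_mean = 0.050, amp_approach_sd = 0.020,
                           amp_recede_mean = 0.010, amp_recede_sd = 0.004,
                           mu_mean = 0.35, mu_sd = 0.04,
                           kappa_mean = 0.02, kappa_sd = 0.005) {
  as.list(environment())
}

#' Cohort specification for [simulate_cohort()]
#'
#' Default group sizes and covariate distributions (age, full-scale IQ,
#' SRS-2 total T, gender mix, PANSS for SZ) emulate the study cohort
#' structure: TD n = 36, ASD n = 26, SZ n = 22; one SZ participant missing
#' gender (rate 1/22) and full-scale IQ missing for 3 ASD and 2 SZ
#' participants. PPS defaults place the TD and SZ central point near 60 cm
#' and the ASD central point near 40 cm with a sharper gradient — the
#' qualitative group pattern the pipeline is meant to detect; magnitudes are
#' artifact configuration, not reported values.
#'
#' @param groups Named list (`TD`, `ASD`, `SZ`) of per-group parameter lists;
#'   see the source for the fields. Override individual entries via `...`
#'   style modification of the returned object.
#' @param srs_link Slope of an optional linear link from `xc_true` (cm,
#'   centred within group) to the SRS-2 total T score; 0 disables it.
#' @param sim_tasks Which tasks to simulate per subject.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = NULL, srs_link = 0,
                        sim_tasks = c("CCE", "PPS")) {
  if (is.null(groups)) {
    groups <- list(
      TD  = .group_default(36, xc_mean = 60, xc_sd = 8, b_mean = 10, b_sd = 3,
                           age_mean = 33.56, age_sd = 11.19,
                           fsiq_mean = 112.97, fsiq_sd = 13.31,
                           srs_mean = 47.31, srs_sd = 7.67, p_male = 23 / 36),
      ASD = .group_default(26, xc_mean = 40, xc_sd = 8, b_mean = 5, b_sd = 2,
                           age_mean = 25.65, age_sd = 6.05,
                           fsiq_mean = 105.09, fsiq_sd = 17.54,
                           srs_mean = 67.91, srs_sd = 12.63, p_male = 14 / 26,
                           miss_fsiq = 3 / 26),
      SZ  = .group_default(22, xc_mean = 60, xc_sd = 8, b_mean = 10, b_sd = 3,
                           age_mean = 45.09, age_sd = 9.94,
                           fsiq_mean = 93.15, fsiq_sd = 17.07,
                           srs_mean = 61.00, srs_sd = 11.74, p_male = 13 / 21,
                           miss_gender = 1 / 22, miss_fsiq = 2 / 22,
                           panss_pos_mean = 15.21, panss_neg_mean = 15.54))
  }
  stopifnot(all(names(groups) %in% .groups))
  for (g in names(groups)) {
    gr <- groups[[g]]
    stopifnot(gr$n >= 0)
    sds <- unlist(gr[grepl("_sd$", names(gr))])
    if (any(sds < 0)) stop("degenerate distribution: negative SD in group ", g)
    if (gr$miss_gender < 0 || gr$miss_gender > 1 ||
        gr$miss_fsiq < 0 || gr$miss_fsiq > 1)
      stop("missingness rates must lie in [0, 1]")
  }
  structure(list(groups = groups, srs_link = srs_link,
                 sim_tasks = match.arg(sim_tasks, several.ok = TRUE)),
            class = "cohort_spec")
}

# Derive a distinct 31-bit sub-seed for subject i, stream k.
sub_seed <- function(seed, i, k = 0) {
  (as.double(seed) * 2654435761 + i * 97561 + k * 40093) %% 2147483647
}

#' Simulate a full cohort
#'
#' Draws per-subject generative parameters from the group distributions of a
#' [cohort_spec()], simulates the planned session(s) for every subject,
#' injects covariate missingness completely at random, and returns a
#' [pps_dataset()] whose metadata retain the true parameters
#' (`meta$truth`) for recovery tests.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer master seed; the whole dataset is a pure function of
#'   `spec` and `seed`.
#' @return A `pps_dataset`.
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(vapply(spec$groups, `[[`, numeric(1), "n"))
  if (n_total < 1) stop("cohort spec contains no subjects")

  plans <- list(CCE = if ("CCE" %in% spec$sim_tasks) build_cce_session(sub_seed(seed, 0, 1)),
                PPS = if ("PPS" %in% spec$sim_tasks) build_pps_session(sub_seed(seed, 0, 2)))

  subjects <- list(); truth <- list(); trials <- list()
  i <- 0
  for (g in names(spec$groups)) {
    gr <- spec$groups[[g]]
    for (j in seq_len(gr$n)) {
      i <- i + 1
      sid <- sprintf("%s%02d", g, j)
      draws <- with_seed(sub_seed(seed, i, 0), {
        xc <- min(105, max(5, rnorm(1, gr$xc_mean, gr$xc_sd)))
        b <- max(0.5, rnorm(1, gr$b_mean, gr$b_sd))
        list(
          xc = xc, b = b,
          amp_a = max(0, rnorm(1, gr$amp_approach_mean, gr$amp_approach_sd)),
          amp_r = max(0, rnorm(1, gr$amp_recede_mean, gr$amp_recede_sd)),
          mu = max(0.15, rnorm(1, gr$mu_mean, gr$mu_sd)),
          kappa = rnorm(1, gr$kappa_mean, gr$kappa_sd),
          age = max(18, rnorm(1, gr$age_mean, gr$age_sd)),
          fsiq = max(70, rnorm(1, gr$fsiq_mean, gr$fsiq_sd)),
          srs = rnorm(1, gr$srs_mean, gr$srs_sd) +
            spec$srs_link * (xc - gr$xc_mean),
          male = runif(1) < gr$p_male,
          panss_pos = if (is.na(gr$panss_pos_mean)) NA_real_ else
            rnorm(1, gr$panss_pos_mean, gr$panss_sd),
          panss_neg = if (is.na(gr$panss_neg_mean)) NA_real_ else
            rnorm(1, gr$panss_neg_mean, gr$panss_sd),
          drop_gender = runif(1) < gr$miss_gender,
          drop_fsiq = runif(1) < gr$miss_fsiq)
      })
      pars <- generative_params(mu = draws$mu, xc_true = draws$xc,
                                b_true = draws$b, amp_approach = draws$amp_a,
                                amp_recede = draws$amp_r, kappa = draws$kappa)
      subjects[[i]] <- tibble(
        subject_id = sid, group = g, age = draws$age,
        gender = if (draws$drop_gender) NA_character_ else
          if (draws$male) "M" else "F",
        fsiq = if (draws$drop_fsiq) NA_real_ else draws$fsiq,
        srs_total_t = draws$srs,
        panss_pos = draws$panss_pos, panss_neg = draws$panss_neg)
      truth[[i]] <- tibble(
        subject_id = sid, group = g, xc_true = draws$xc, b_true = draws$b,
        amp_approach = draws$amp_a, amp_recede = draws$amp_r,
        mu = draws$mu, kappa = draws$kappa)
      st <- list()
      if (!is.null(plans$CCE))
        st$cce <- simulate_cce_subject(pars, plans$CCE, sub_seed(seed, i, 3), sid)
      if (!is.null(plans$PPS))
        st$pps <- simulate_pps_subject(pars, plans$PPS, sub_seed(seed, i, 4), sid)
      trials[[i]] <- do.call(rbind, st)
    }
  }
  pps_dataset(
    subjects = do.call(rbind, subjects),
    trials = do.call(rbind, trials),
    meta = list(generator = list(seed = seed, spec = spec),
                truth = do.call(rbind, truth)))
}
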