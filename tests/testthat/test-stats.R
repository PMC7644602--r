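test_that("CPM with a binary outcome reduces to logistic regression", {
  set.seed(61)
  n <- 40
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 + 0.6 * X$x1 - 0.3 * X$x2))
  f <- cpm_fit(y, X)
  g <- glm(y ~ x1 + x2, family = binomial, data = cbind(y = y, X))
  expect_lt(max(abs(f$coef$beta - coef(g)[-1])), 1e-4)
  expect_lt(max(abs(f$coef$se - sqrt(diag(vcov(g)))[-1])), 1e-4)
})

test_that("CPM agrees with an independent proportional-odds fit", {
  skip_if_not_installed("MASS")
  set.seed(62)
  n <- 80
  X <- data.frame(x = rnorm(n), g = factor(sample(c("A", "B"), n, TRUE)))
  y <- sample(1:5, n, TRUE, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
  f <- cpm_fit(y, X)
  po <- MASS::polr(factor(y) ~ x + g, data = cbind(y = y, X), Hess = TRUE)
  expect_lt(max(abs(f$coef$beta - coef(po))), 1e-5)
  expect_lt(max(abs(f$coef$se - sqrt(diag(vcov(po)))[seq_along(coef(po))])),
            1e-4)
  expect_lt(max(abs(f$intercepts - po$zeta)), 1e-4)
})

test_that("CPM is invariant to strictly monotone outcome transforms", {
  set.seed(63)
  n <- 50
  X <- data.frame(x = rnorm(n))
  y <- rnorm(n)
  fa <- cpm_fit(y, X)
  fb <- cpm_fit(exp(y), X)
  fc <- cpm_fit(rank(y), X)
  expect_lt(max(abs(fa$coef$beta - fb$coef$beta)), 1e-10)
  expect_lt(max(abs(fa$coef$beta - fc$coef$beta)), 1e-10)
})

test_that("identical outcome distributions across groups give aOR near 1", {
  y <- rep(1:10, 2)
  g <- rep(c("A", "B"), each = 10)
  f <- cpm_fit(y, data.frame(group = g))
  expect_lt(abs(f$coef$aor - 1), 1e-6)
  expect_gt(f$coef$p, 0.99)
})

test_that("CPM validates its inputs and parameterization", {
  expect_error(cpm_fit(rep(1, 10), data.frame(x = rnorm(10))), "constant")
  expect_error(cpm_fit(rnorm(4), data.frame(a = rnorm(4), b = rnorm(4),
                                            c = rnorm(4))), "n >=")
  expect_error(cpm_fit(rnorm(10), data.frame(x = c(NA, rnorm(9)))), "missing")
  f <- cpm_fit(rnorm(30), data.frame(x = rnorm(30)))
  expect_true(all(diff(f$intercepts) > 0))  # increasing cut points
  expect_true(all(f$coef$ci_low <= f$coef$aor & f$coef$aor <= f$coef$ci_high))
})

test_that("imputation returns m completed copies, identity when complete", {
  subs <- do.call(rbind, lapply(1:20, function(i) one_subject(sprintf("S%d", i))))
  subs$age <- 20 + 1:20
  out <- impute(subs, m = 40, seed = 5)
  expect_length(out, 40)
  expect_identical(out[[1]], subs)  # nothing missing -> untouched

  subs2 <- subs
  subs2$fsiq <- 90 + subs2$age + rnorm(20, 0, 3)
  subs2$fsiq[c(3, 7)] <- NA
  subs2$gender[5] <- NA
  out2 <- impute(subs2, m = 7, seed = 5)
  expect_length(out2, 7)
  for (d in out2) {
    expect_true(all(!is.na(d$fsiq)))
    expect_true(all(d$gender %in% c("M", "F")))          # donor values only
    expect_true(all(d$fsiq %in% subs2$fsiq[!is.na(subs2$fsiq)] |
                      !is.na(subs2$fsiq)))
  }
  expect_identical(impute(subs2, m = 3, seed = 9), impute(subs2, m = 3, seed = 9))
  subs3 <- subs2; subs3$fsiq <- NA_real_
  expect_error(impute(subs3, m = 2, seed = 1), "entirely missing")
})

test_that("PMM imputation keeps pooled estimates near the complete-data fit", {
  # MCAR 20% missingness in fsiq: the pooled CPM coefficient should stay
  # inside the complete-data 95% CI in nearly all replicates
  ok <- 0; n_rep <- 30
  for (r in seq_len(n_rep)) {
    set.seed(800 + r)
    n <- 60
    tab <- tibble::tibble(
      subject_id = sprintf("S%d", 1:n),
      group = sample(c("TD", "ASD"), n, TRUE),
      age = rnorm(n, 35, 10),
      gender = sample(c("M", "F"), n, TRUE),
      srs_total_t = rnorm(n, 55, 10),
      fsiq = rnorm(n, 100, 15),
      panss_pos = NA_real_, panss_neg = NA_real_)
    y <- 0.03 * tab$fsiq + rnorm(n)
    full <- cpm_fit(y, tab[c("fsiq", "group")])
    ci <- c(full$coef$beta[1] - 1.96 * full$coef$se[1],
            full$coef$beta[1] + 1.96 * full$coef$se[1])
    tab$fsiq[sample(n, 12)] <- NA
    compl <- impute(tab, m = 10, seed = r)
    fits <- lapply(compl, function(d) cpm_fit(y, d[c("fsiq", "group")]))
    pooled <- pool_rubin(fits)
    ok <- ok + (ci[1] <= pooled$coef$beta[1] && pooled$coef$beta[1] <= ci[2])
  }
  expect_gte(ok, 0.9 * n_rep)
})

test_that("Rubin pooling follows the textbook formulas", {
  mk_fit <- function(beta, v) {
    structure(list(
      coef = tibble::tibble(term = "x", beta = beta, se = sqrt(v),
                            aor = exp(beta), ci_low = NA, ci_high = NA, p = NA),
      intercepts = 0, loglik = 0, n = 10, n_categories = 5,
      converged = TRUE, pooled = FALSE, m = NA_integer_), class = "cpm_fit")
  }
  # identical fits: between-variance 0, SEs returned exactly
  pid <- pool_rubin(list(mk_fit(1.2, 0.09), mk_fit(1.2, 0.09)))
  expect_equal(pid$coef$beta, 1.2)
  expect_equal(pid$coef$se, 0.3)
  expect_equal(pid$coef$ci_low, exp(1.2 - qnorm(0.975) * 0.3))

  # betas 1 and 3 with equal within-variance v: pooled 2, total v + 1.5*2
  v <- 0.25
  p2 <- pool_rubin(list(mk_fit(1, v), mk_fit(3, v)))
  expect_equal(p2$coef$beta, 2)
  expect_equal(p2$coef$se^2, v + (1 + 1 / 2) * var(c(1, 3)))
  expect_equal(p2$coef$se^2, v + 1.5 * 2)

  expect_warning(p1 <- pool_rubin(list(mk_fit(1, v))), "single imputation")
  expect_equal(p1$coef$beta, 1)
  bad <- mk_fit(1, v); bad$coef$term <- "z"
  expect_error(pool_rubin(list(mk_fit(1, v), bad)), "mismatched")
})

test_that("Spearman correlation handles monotone, tied and degenerate data", {
  x <- 1:10
  expect_equal(spearman(x, x^3)$r, 1)
  expect_equal(spearman(x, -sqrt(x))$r, -1)

  xt <- c(1, 2, 2, 3, 4, 5, 5, 5, 6, 7)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6, 7, 7)
  got <- spearman(xt, yt)
  oracle <- cor.test(xt, yt, method = "spearman", exact = FALSE)
  expect_equal(got$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-10)

  expect_true(is.na(spearman(rep(1, 5), 1:5)$r))
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  expect_equal(bonferroni(0.009, m = 2), 0.018)
  expect_equal(bonferroni(0.6, m = 2), 1)
  expect_equal(bonferroni(0.04, m = 1), 0.04)
  expect_equal(bonferroni(c(0.01, 0.2), m = 3), p.adjust(c(0.01, 0.2, 1),
                                                         "bonferroni")[1:2])
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m >=")
})
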