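# Cumulative probability model (CPM): proportional-odds logistic ordinal
# regression for a continuous outcome. Every distinct outcome value is an
# ordered category (ties collapsed), so the model is invariant to strictly
# monotone transforms of the outcome and reduces to binary logistic
# regression for a two-valued outcome. Fitting is full Newton-Raphson with
# step-halving on the exact gradient and Hessian; inference is Wald.

# Log-likelihood, gradient and Hessian of the proportional-odds model with
# P(Y <= k | x) = plogis(zeta_k - x'beta), zeta strictly increasing.
.cpm_llik <- function(theta, k, X, K) {
  nz <- K - 1L; p <- ncol(X); n <- length(k)
  zeta <- theta[seq_len(nz)]; beta <- theta[nz + seq_len(p)]
  if (is.unsorted(zeta, strictly = TRUE)) return(list(ll = -Inf))
  eta <- if (p) drop(X %*% beta) else numeric(n)
  a <- ifelse(k < K, zeta[pmin(k, nz)] - eta, Inf)       # upper cut
  b <- ifelse(k > 1, zeta[pmax(k - 1L, 1L)] - eta, -Inf) # lower cut
  Fa <- plogis(a); Fb <- plogis(b)
  P <- Fa - Fb
  if (any(P <= 0) || any(!is.finite(P))) return(list(ll = -Inf))
  fa <- dlogis(a); fb <- dlogis(b)
  fa[!is.finite(a)] <- 0; fb[!is.finite(b)] <- 0
  # second derivatives of log P wrt the cut arguments
  fpa <- fa * (1 - 2 * Fa); fpb <- fb * (1 - 2 * Fb)
  l_aa <- fpa / P - (fa / P)^2
  l_bb <- -fpb / P - (fb / P)^2
  l_ab <- fa * fb / P^2

  grad <- numeric(nz + p)
  H <- matrix(0, nz + p, nz + p)
  w_eta <- (fb - fa) / P  # d log P / d eta
  if (p) {
    grad[nz + seq_len(p)] <- drop(crossprod(X, w_eta))
    l_ee <- l_aa + 2 * l_ab + l_bb
    H[nz + seq_len(p), nz + seq_len(p)] <- crossprod(X * l_ee, X)
  }
  for (i in seq_len(n)) {
    ki <- k[i]
    if (ki < K) {
      j <- ki
      grad[j] <- grad[j] + fa[i] / P[i]
      H[j, j] <- H[j, j] + l_aa[i]
      if (p) {
        v <- -(l_aa[i] + l_ab[i]) * X[i, ]
        H[j, nz + seq_len(p)] <- H[j, nz + seq_len(p)] + v
        H[nz + seq_len(p), j] <- H[nz + seq_len(p), j] + v
      }
    }
    if (ki > 1) {
      j <- ki - 1L
      grad[j] <- grad[j] - fb[i] / P[i]
      H[j, j] <- H[j, j] + l_bb[i]
      if (p) {
        v <- -(l_bb[i] + l_ab[i]) * X[i, ]
        H[j, nz + seq_len(p)] <- H[j, nz + seq_len(p)] + v
        H[nz + seq_len(p), j] <- H[nz + seq_len(p), j] + v
      }
    }
    if (ki < K && ki > 1)
      H[ki, ki - 1L] <- H[ki, ki - 1L] + l_ab[i]
  }
  if (K > 2) { # symmetrise the zeta off-diagonal band
    for (j in seq_len(nz - 1)) H[j, j + 1] <- H[j + 1, j]
  }
  list(ll = sum(log(P)), grad = grad, H = H)
}

#' Fit a cumulative probability model
#'
#' Proportional-odds logistic regression treating each distinct value of a
#' continuous outcome as an ordered category. Coefficients are on the
#' log-odds scale for a *higher* outcome value per unit predictor;
#' `exp(beta)` is the adjusted odds ratio (aOR), with 95% Wald confidence
#' intervals and p-values. Intercepts (cut points) are strictly increasing
#' in the parameterization `P(Y <= k | x) = plogis(zeta_k - x'beta)`.
#'
#' @param y Numeric outcome with at least 2 distinct values.
#' @param X Predictor table (data.frame); factors are expanded to treatment
#'   contrasts, characters converted to factors. May be NULL/empty for an
#'   intercepts-only fit.
#' @param max_iter,tol Newton iteration cap and gradient tolerance.
#' @return A `cpm_fit`: list with `coef` tibble (`term, beta, se, aor,
#'   ci_low, ci_high, p`), `intercepts`, `loglik`, `n`, `n_categories`,
#'   `converged`, `pooled`.
#' @export
cpm_fit <- function(y, X = NULL, max_iter = 100, tol = 1e-8) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("outcome contains non-finite values")
  lev <- sort(unique(y))
  K <- length(lev)
  if (K < 2) stop("constant outcome: CPM undefined")
  k <- match(y, lev)
  n <- length(y)

  if (!is.null(X) && NCOL(X) > 0) {
    X <- as.data.frame(X)
    if (nrow(X) != n) stop("X and y lengths differ")
    if (any(!complete.cases(X)))
      stop("predictors contain missing values; impute first")
    for (cl in names(X)) if (is.character(X[[cl]])) X[[cl]] <- factor(X[[cl]])
    mm <- model.matrix(~ ., data = X)[, -1, drop = FALSE]
  } else {
    mm <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  p <- ncol(mm)
  if (n < p + 2) stop("need n >= number of predictors + 2")

  cnts <- tabulate(k, K)
  zeta <- qlogis(pmin(1 - 1e-6, pmax(1e-6, cumsum(cnts)[-K] / n)))
  theta <- c(zeta, rep(0, p))
  cur <- .cpm_llik(theta, k, mm, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$H, cur$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    step <- -step  # Newton ascent: theta - H^{-1} g, H negative definite
    lam <- 1; nxt <- NULL
    for (h in 1:30) {
      cand <- .cpm_llik(theta + lam * step, k, mm, K)
      if (is.finite(cand$ll) && cand$ll >= cur$ll - 1e-12) { nxt <- cand; break }
      lam <- lam / 2
    }
    if (is.null(nxt)) break
    theta <- theta + lam * step
    moved <- abs(nxt$ll - cur$ll)
    cur <- nxt
    if (max(abs(cur$grad)) < tol || moved < 1e-12) { converged <- TRUE; break }
  }

  vc <- tryCatch(solve(-cur$H), error = function(e) NULL)
  terms <- colnames(mm)
  if (p) {
    beta <- theta[(K - 1) + seq_len(p)]
    se <- if (!is.null(vc)) sqrt(pmax(0, diag(vc)[(K - 1) + seq_len(p)]))
          else rep(NA_real_, p)
    z <- beta / se
    coef_tab <- tibble(
      term = terms, beta = beta, se = se, aor = exp(beta),
      ci_low = exp(beta - qnorm(0.975) * se),
      ci_high = exp(beta + qnorm(0.975) * se),
      p = 2 * pnorm(-abs(z)))
  } else {
    coef_tab <- tibble(term = character(), beta = numeric(), se = numeric(),
                       aor = numeric(), ci_low = numeric(),
                       ci_high = numeric(), p = numeric())
  }
  structure(list(coef = coef_tab, intercepts = theta[seq_len(K - 1)],
                 loglik = cur$ll, n = n, n_categories = K,
                 converged = converged && !is.null(vc),
                 pooled = FALSE, m = NA_integer_),
            class = "cpm_fit")
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat("<cpm_fit> n =", x$n, ", categories =", x$n_categories,
      if (x$pooled) sprintf(", Rubin-pooled over %d imputations", x$m),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  df <- as.data.frame(x$coef)
  df[-1] <- lapply(df[-1], signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pool CPM fits over imputations with Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation coefficients; total variance
#' = mean within-imputation variance + (1 + 1/m) x between-imputation
#' variance. Wald intervals and p-values use the Barnard-Rubin degrees of
#' freedom (normal reference when the between-imputation variance is zero,
#' in which case each fit's standard errors are returned exactly).
#'
#' @param fits List of `cpm_fit` objects sharing the same predictors.
#' @return A pooled `cpm_fit`.
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "cpm_fit")))
  m <- length(fits)
  terms <- fits[[1]]$coef$term
  for (f in fits) {
    if (!identical(f$coef$term, terms)) stop("mismatched predictor sets")
    if (!f$converged) stop("cannot pool non-converged fits")
  }
  if (m == 1) {
    warning("pooling a single imputation: returning the fit unchanged")
    out <- fits[[1]]; out$pooled <- TRUE; out$m <- 1L
    return(out)
  }
  B <- vapply(fits, function(f) f$coef$beta, numeric(length(terms)))
  V <- vapply(fits, function(f) f$coef$se^2, numeric(length(terms)))
  B <- matrix(B, ncol = m); V <- matrix(V, ncol = m)
  qbar <- rowMeans(B)
  ubar <- rowMeans(V)
  bvar <- apply(B, 1, var)
  tvar <- ubar + (1 + 1 / m) * bvar
  se <- sqrt(tvar)
  r <- (1 + 1 / m) * bvar / ubar
  df <- ifelse(bvar > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  crit <- ifelse(is.finite(df), qt(0.975, df), qnorm(0.975))
  stat <- qbar / se
  pval <- ifelse(is.finite(df), 2 * pt(-abs(stat), df), 2 * pnorm(-abs(stat)))
  structure(list(
    coef = tibble(term = terms, beta = qbar, se = se, aor = exp(qbar),
                  ci_low = exp(qbar - crit * se),
                  ci_high = exp(qbar + crit * se), p = pval),
    intercepts = rowMeans(matrix(unlist(lapply(fits, `[[`, "intercepts")),
                                 ncol = m)),
    loglik = mean(vapply(fits, `[[`, numeric(1), "loglik")),
    n = fits[[1]]$n, n_categories = fits[[1]]$n_categories,
    converged = TRUE, pooled = TRUE, m = m),
    class = "cpm_fit")
}
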