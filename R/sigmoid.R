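# Sigmoid fit of the expectancy-corrected distance curve: the peripersonal
# radius is the central point xc, the gradient parameter b is inversely
# proportional to the slope at xc (|slope at xc| = (ymax - ymin) / (4 b) in
# the bounded form).

#' Sigmoid model of the distance curve
#'
#' Default `"bounded"` form
#' `y(x) = ymin + (ymax - ymin) * exp((x - xc)/b) / (1 + exp((x - xc)/b))`,
#' which saturates exactly at `ymin` (near the body) and `ymax` (far) — the
#' stated meaning of fixed saturation points. The `"printed"` form
#' `y(x) = ymin + ymax * exp((x - xc)/b) / (1 + exp((x - xc)/b))` (saturating
#' at `ymin` and `ymin + ymax`) is available behind the flag.
#'
#' @param x Distance, cm.
#' @param xc,b Central point and gradient parameter, cm.
#' @param ymin,ymax Saturation levels, s (on the subtracted RT scale `ymin`
#'   is the strongest facilitation, `ymax` the weakest).
#' @param form `"bounded"` (default) or `"printed"`.
#' @return Predicted delta values.
#' @export
pps_sigmoid <- function(x, xc, b, ymin, ymax, form = c("bounded", "printed")) {
  form <- match.arg(form)
  s <- plogis((x - xc) / b)
  if (form == "bounded") ymin + (ymax - ymin) * s else ymin + ymax * s
}

.sigmoid_bounds <- list(xc = c(5, 105), b = c(0.1, 100))

# Vectorised SSE of the sigmoid over a set of (xc, b) candidates.
sigmoid_sse <- function(xc, b, x, y, ymin, ymax, form = "bounded") {
  s <- plogis(outer(-xc, x, "+") / b)  # rows: candidates, cols: distances
  pred <- if (form == "bounded") ymin + (ymax - ymin) * s else ymin + ymax * s
  rowSums(sweep(pred, 2, y)^2)
}

#' Fit the PPS sigmoid to a delta curve
#'
#' `ymin` and `ymax` are fixed to the minimum and maximum of the 11
#' per-distance mean deltas (the saturation points are not free parameters);
#' `xc` and `b` are estimated by bounded nonlinear least squares
#' (`xc` in [5, 105] cm, `b` in (0.1, 100] cm) with a 25-point multi-start
#' grid screened in one vectorised pass and L-BFGS-B refinement from the
#' best candidates, ties broken by lowest SSE then smallest `b`. Fit quality
#' is `r2 = 1 - SS_res / SS_tot` over the 11 points; the fit is retained
#' (`kept`) when `r2 > 0.5` (strict). A constant curve has degenerate
#' `SS_tot` and is reported as `r2 = 0`, not kept.
#'
#' @param curve A `delta_curve` ([time_matched_subtraction()]) or a numeric
#'   vector of 11 deltas.
#' @param r2_cutoff Retention threshold on `r2` (strict inequality).
#' @param form Sigmoid form, see [pps_sigmoid()].
#' @param n_refine How many screened starts get local refinement.
#' @param ymin,ymax Optional externally fixed saturation levels; by default
#'   they are taken from the curve's extremes.
#' @return A one-row `SigmoidFit` tibble: `subject_id, xc, b, ymin, ymax,
#'   sse, r2, converged, kept`.
#' @export
fit_sigmoid <- function(curve, r2_cutoff = 0.5, form = c("bounded", "printed"),
                        n_refine = 8, ymin = NULL, ymax = NULL) {
  form <- match.arg(form)
  if (inherits(curve, "delta_curve")) {
    y <- curve$delta; sid <- curve$subject_id
  } else {
    y <- as.numeric(curve); sid <- NA_character_
  }
  x <- pps_distances()
  stopifnot(length(y) == 11)
  if (any(!is.finite(y)))
    return(tibble(subject_id = sid, xc = NA_real_, b = NA_real_,
                  ymin = NA_real_, ymax = NA_real_, sse = NA_real_,
                  r2 = NA_real_, converged = FALSE, kept = FALSE))
  ymin <- ymin %||% min(y); ymax <- ymax %||% max(y)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    return(tibble(subject_id = sid, xc = NA_real_, b = NA_real_,
                  ymin = ymin, ymax = ymax, sse = 0, r2 = 0,
                  converged = FALSE, kept = FALSE))

  starts <- expand.grid(xc = seq(5, 105, length.out = 5),
                        b = exp(seq(log(0.5), log(50), length.out = 5)))
  starts$sse <- sigmoid_sse(starts$xc, starts$b, x, y, ymin, ymax, form)
  starts <- starts[order(starts$sse, starts$b), ]

  obj <- function(p) sum((y - pps_sigmoid(x, p[1], p[2], ymin, ymax, form))^2)
  best <- NULL; any_conv <- FALSE
  for (k in seq_len(min(n_refine, nrow(starts)))) {
    o <- tryCatch(
      optim(c(starts$xc[k], starts$b[k]), obj, method = "L-BFGS-B",
            lower = c(.sigmoid_bounds$xc[1], .sigmoid_bounds$b[1]),
            upper = c(.sigmoid_bounds$xc[2], .sigmoid_bounds$b[2]),
            control = list(factr = 10, pgtol = 1e-12, maxit = 200)),
      error = function(e) NULL)
    if (is.null(o)) next
    any_conv <- any_conv || o$convergence == 0
    cand <- list(xc = o$par[1], b = o$par[2], sse = o$value)
    if (is.null(best) || cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 && cand$b < best$b))
      best <- cand
  }
  if (is.null(best)) {  # all refinements failed: fall back to grid screen
    best <- list(xc = starts$xc[1], b = starts$b[1], sse = starts$sse[1])
    any_conv <- FALSE
  }
  r2 <- 1 - best$sse / ss_tot
  tibble(subject_id = sid, xc = best$xc, b = best$b, ymin = ymin,
         ymax = ymax, sse = best$sse, r2 = r2, converged = any_conv,
         kept = any_conv && r2 > r2_cutoff)
}

#' Retain good sigmoid fits
#'
#' Keeps fits with `kept = TRUE` (converged and `r2` strictly above the
#' cutoff already applied by [fit_sigmoid()]) and reports the accounting in
#' the kept/attempted style, per group when a `group` column is present.
#'
#' @param fits Tibble of `SigmoidFit` rows.
#' @return List with `kept` (retained rows) and `log` (tibble of `group`,
#'   `attempted`, `kept`).
#' @export
filter_fits <- function(fits) {
  grp <- if ("group" %in% names(fits)) fits$group else "all"
  log <- do.call(rbind, lapply(split(fits, grp), function(ff)
    tibble(group = unique(if ("group" %in% names(ff)) ff$group else "all"),
           attempted = nrow(ff), kept = sum(ff$kept))))
  list(kept = fits[fits$kept, ], log = log)
}

#' Run the PPS pipeline over a cohort
#'
#' Filters trials, builds the expectancy-corrected delta curve and sigmoid
#' fit per subject, and applies the fit-quality retention rule.
#'
#' @param dataset A `pps_dataset` (or trial tibble) containing PPS trials.
#' @param rt_cutoff RT discard threshold, s.
#' @param r2_cutoff Fit retention threshold (strict).
#' @param form Sigmoid form, see [pps_sigmoid()].
#' @return List: `curves` (per-subject delta tibble, columns `d1..d11`),
#'   `fits` (per-subject `SigmoidFit` rows + group), `kept`, `retention_log`,
#'   `rejections`, `catch`.
#' @export
pps_results <- function(dataset, rt_cutoff = 2.0, r2_cutoff = 0.5,
                        form = "bounded") {
  trials <- if (inherits(dataset, "pps_dataset")) dataset$trials else dataset
  subjects <- if (inherits(dataset, "pps_dataset")) dataset$subjects else NULL
  trials <- trials[trials$task == "PPS", ]
  if (!nrow(trials)) stop("no PPS trials in input")

  out <- lapply(split(trials, trials$subject_id), function(tt) {
    f <- filter_trials_pps(tt, rt_cutoff)
    curve <- time_matched_subtraction(f$trials)
    fit <- fit_sigmoid(curve, r2_cutoff = r2_cutoff, form = form)
    f$log$subject_id <- curve$subject_id
    crow <- tibble(subject_id = curve$subject_id,
                   baseline_rt = curve$baseline_rt,
                   complete = curve$complete)
    crow[paste0("d", 1:11)] <- as.list(curve$delta)
    list(curve = crow, fit = fit, log = f$log)
  })
  curves <- do.call(rbind, lapply(out, `[[`, "curve"))
  fits <- do.call(rbind, lapply(out, `[[`, "fit"))
  if (!is.null(subjects))
    fits$group <- subjects$group[match(fits$subject_id, subjects$subject_id)]
  filt <- filter_fits(fits)
  list(curves = curves, fits = fits, kept = filt$kept,
       retention_log = filt$log,
       rejections = do.call(rbind, lapply(out, `[[`, "log")),
       catch = catch_false_alarms(trials))
}

#' Plot a delta curve with its sigmoid fit
#'
#' Base-graphics plot of the 11 expectancy-corrected deltas, the fitted
#' sigmoid, and a vertical line at the fitted central point.
#'
#' @param curve A `delta_curve`.
#' @param fit Matching `SigmoidFit` row (optional; fitted on the fly when
#'   absent).
#' @param ... Passed to `plot()`.
#' @return Invisibly, the fit used.
#' @export
plot_pps_fit <- function(curve, fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_sigmoid(curve)
  x <- curve$distances_cm
  plot(x, curve$delta, pch = 16, xlab = "distance (cm, approach frame)",
       ylab = "approach - recede RT (s)", ...)
  abline(h = 0, col = "grey70", lty = 3)
  if (is.finite(fit$xc)) {
    xs <- seq(5, 105, length.out = 200)
    lines(xs, pps_sigmoid(xs, fit$xc, fit$b, fit$ymin, fit$ymax))
    abline(v = fit$xc, lty = 2)
  }
  invisible(fit)
}
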