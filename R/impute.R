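# Multiple imputation by bootstrap predictive mean matching (PMM). Each
# imputation refits the predictive model on a bootstrap resample of the
# complete cases, predicts the missing entries, and replaces each with the
# observed value of a randomly chosen nearest-prediction donor — so imputed
# values are always observed, in-range values (and valid category labels).

.pmm_one <- function(df, target, predictors, donors_k = 5) {
  obs <- !is.na(df[[target]])
  if (!any(obs)) stop("column '", target, "' is entirely missing")
  if (all(obs)) return(df[[target]])
  ycol <- df[[target]]
  is_factor <- is.character(ycol) || is.factor(ycol)
  lev <- if (is_factor) sort(unique(as.character(ycol[obs])))
  ynum <- if (is_factor) as.numeric(factor(as.character(ycol), levels = lev)) - 1
          else as.numeric(ycol)

  Xp <- df[predictors]
  for (cl in names(Xp)) if (is.character(Xp[[cl]])) Xp[[cl]] <- factor(Xp[[cl]])
  # constant predictors carry no information and break the design matrix
  keep <- vapply(Xp, function(v) length(unique(v)) > 1, logical(1))
  Xp <- Xp[keep]
  mm <- if (ncol(Xp)) model.matrix(~ ., data = Xp)
        else matrix(1, nrow(df), 1)

  idx_obs <- which(obs)
  boot <- sample(idx_obs, length(idx_obs), replace = TRUE)
  fit <- stats::lm.fit(mm[boot, , drop = FALSE], ynum[boot])
  cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pred <- drop(mm %*% cf)

  out <- ycol
  for (i in which(!obs)) {
    d <- abs(pred[idx_obs] - pred[i])
    near <- idx_obs[order(d)][seq_len(min(donors_k, length(idx_obs)))]
    donor <- near[sample.int(length(near), 1)]
    out[i] <- ycol[donor]
  }
  out
}

#' Multiple imputation of subject covariates
#'
#' Bootstrap predictive-mean-matching imputation of missing covariates
#' (by default `gender` and `fsiq`, the variables missing in the study
#' cohort), conditioned on the always-observed covariates. Returns `m`
#' completed copies of the subject table, reproducible by seed. With no
#' missing values all copies equal the input.
#'
#' @param subjects Subject tibble (see [read_trials()]); extra columns such
#'   as fitted outcomes are carried through untouched.
#' @param m Number of imputations (default 40).
#' @param seed Integer seed.
#' @param targets Columns to impute (only those with missing values are
#'   touched; a fully missing target is an error).
#' @param predictors Complete columns used as predictors.
#' @param donors_k Donor pool size for matching.
#' @return List of `m` completed tibbles.
#' @export
impute <- function(subjects, m = 40, seed = 1,
                   targets = c("gender", "fsiq"),
                   predictors = c("group", "age", "srs_total_t"),
                   donors_k = 5) {
  stopifnot(m >= 1)
  subjects <- as_tibble(subjects)
  targets <- intersect(targets, names(subjects))
  miss_pred <- predictors[vapply(subjects[predictors],
                                 function(x) any(is.na(x)), logical(1))]
  if (length(miss_pred))
    stop("predictor column(s) with missing values: ",
         paste(miss_pred, collapse = ", "))
  for (tg in targets)
    if (all(is.na(subjects[[tg]])))
      stop("column '", tg, "' is entirely missing")
  need <- targets[vapply(subjects[targets], function(x) any(is.na(x)), logical(1))]
  if (!length(need)) return(replicate(m, subjects, simplify = FALSE))

  with_seed(seed, lapply(seq_len(m), function(im) {
    done <- subjects
    for (tg in need)
      done[[tg]] <- .pmm_one(subjects, tg, predictors, donors_k)
    done
  }))
}
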