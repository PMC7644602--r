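# Spearman correlations and Bonferroni multiplicity control for the
# symptom-scale analyses.

#' Spearman rank correlation
#'
#' Tie-corrected Spearman rho (Pearson correlation of mid-ranks) with a
#' two-sided p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs with missing values are dropped; a constant vector leaves rho
#' undefined (reported as NA with p = NA).
#'
#' @param x,y Numeric vectors.
#' @param label Optional label for the variable pair.
#' @return One-row tibble: `pair, r, p, n`.
#' @export
spearman <- function(x, y, label = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite values")
  if (label %||% "" == "") label <- "x~y"
  if (sd(x) == 0 || sd(y) == 0)
    return(tibble(pair = label, r = NA_real_, p = NA_real_, n = n))
  r <- cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  tibble(pair = label, r = r, p = p, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)` for a family of `m` tests.
#'
#' @param pvals Numeric p-values.
#' @param m Family size; must be at least `length(pvals)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= length(pvals))
  pmin(1, pvals * m)
}
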