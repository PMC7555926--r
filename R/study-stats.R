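# Metabolic index computations and the statistical procedures of the
# cohort analysis: HOMA-IR, TyG, Lee index, glucose-tolerance AUC,
# correlation tests with the exact t-transform, and normality-gated group
# comparison.

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = fasting insulin (mU/L) x fasting glucose (mmol/L) / 22.5`.
#'
#' @param insulin fasting insulin, mU/L.
#' @param fbg fasting blood glucose, mmol/L.
#' @return HOMA-IR, dimensionless; vectorised.
#' @examples
#' homa_ir(22.5, 1)   # 1
#' homa_ir(15, 5.5)
#' @export
homa_ir <- function(insulin, fbg) {
  if (any(insulin < 0) || any(fbg < 0))
    stop("insulin and glucose must be non-negative")
  insulin * fbg / 22.5
}

#' Triglyceride-glucose (TyG) index
#'
#' `TyG = ln(fasting triglycerides (mg/dL) x fasting glucose (mg/dL) / 2)`.
#'
#' @param tg fasting triglycerides, mg/dL.
#' @param glucose fasting glucose, mg/dL.
#' @return TyG index, dimensionless; vectorised.
#' @export
tyg_index <- function(tg, glucose) {
  if (any(tg <= 0) || any(glucose <= 0))
    stop("triglycerides and glucose must be positive")
  log(tg * glucose / 2)
}

#' Lee index of rodent adiposity
#'
#' Body weight to the 1/3 power divided by naso-anal length.  The exponent
#' is 1/3 by default (the dimensional convention); the rounded 0.33
#' sometimes quoted can be requested instead (about a 2% difference at
#' adult rat weights).
#'
#' @param weight body weight, g.
#' @param length naso-anal length, cm.
#' @param exponent 1/3 (default) or 0.33.
#' @return Lee index, dimensionless; vectorised.
#' @export
lee_index <- function(weight, length, exponent = 1 / 3) {
  if (any(weight <= 0) || any(length <= 0))
    stop("weight and length must be positive")
  weight^exponent / length
}

#' Area under a glucose-tolerance curve
#'
#' Trapezoidal area under the glucose excursion, expressed in
#' mmol/L x min.
#'
#' @param minutes sampling times, min, strictly increasing.
#' @param glucose blood glucose, mmol/L, same length.
#' @return AUC, mmol/L x min.
#' @export
gtt_auc <- function(minutes, glucose) {
  stopifnot(length(minutes) == length(glucose), length(minutes) >= 2)
  if (is.unsorted(minutes, strictly = TRUE))
    stop("GTT minutes must be strictly increasing")
  sum(diff(minutes) * (head(glucose, -1) + tail(glucose, -1)) / 2)
}

#' Two-sided p-value of a correlation coefficient
#'
#' The exact t-transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to
#' a t distribution with `n - 2` degrees of freedom.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations.
#' @return two-sided p-value.
#' @examples
#' cor_p_from_r(0.497, 28)
#' @export
cor_p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n > 2)
  if (abs(r) == 1) return(.Machine$double.xmin)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(tval), df = n - 2)
}

.cor_result <- function(method, r, n) {
  structure(list(method = method, r = r, n = n,
                 p = cor_p_from_r(r, n)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, n = %d, p = %.4g\n",
              x$method, x$r, x$n, x$p))
  invisible(x)
}

#' Pearson correlation test
#'
#' Pearson's r with the two-sided p-value from the exact t-transform.
#' Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @return a `correlation_result`: list with `method`, `r`, `n`, `p`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= 2) stop("need more than two complete pairs")
  .cor_result("pearson", cor(x, y), n)
}

#' Spearman rank correlation test
#'
#' Pearson's formula applied to midranks, with the p-value from the same
#' t-transform (the standard large-sample approximation).
#'
#' @inheritParams pearson_test
#' @return a `correlation_result`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= 2) stop("need more than two complete pairs")
  .cor_result("spearman", cor(rank(x), rank(y)), n)
}

#' Normality-gated two-group comparison
#'
#' The study's group-comparison rule: Shapiro-Wilk normality on each group;
#' if both pass (p > `alpha_norm`) an unpaired two-sided t-test, otherwise
#' a Mann-Whitney U (Wilcoxon rank-sum) test with midranks for ties.
#'
#' @param a,b numeric vectors (the two groups).
#' @param alpha_norm significance level of the normality gate.
#' @return list with `test` ("t" or "mann-whitney"), `statistic`, `p`, and
#'   `normality_p` (the two Shapiro-Wilk p-values; `NA` when a group is
#'   degenerate, which routes to the rank test).
#' @export
compare_groups <- function(a, b, alpha_norm = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 3, length(b) >= 3)
  swp <- function(x) {
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  pa <- swp(a); pb <- swp(b)
  normal <- !is.na(pa) && !is.na(pb) && pa > alpha_norm && pb > alpha_norm
  if (normal) {
    tt <- t.test(a, b, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         normality_p = c(pa, pb))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value, normality_p = c(pa, pb))
  }
}
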