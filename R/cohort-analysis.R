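# Cohort-level analysis: per-field group comparisons and the correlation
# screen between nerve excitability and metabolic measures.

#' Compare the diet groups on every scalar measure
#'
#' Applies the normality-gated comparison ([compare_groups()]) to each
#' numeric per-rat field of a cohort.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param fields fields to compare; defaults to all numeric columns.
#' @return tibble with columns `field`, `chow_mean`, `caf_mean`, `test`,
#'   `statistic`, `p`.
#' @export
cohort_group_tests <- function(cohort, fields = NULL) {
  num <- vapply(cohort, is.numeric, logical(1))
  if (is.null(fields)) fields <- names(cohort)[num]
  rows <- lapply(fields, function(f) {
    a <- cohort[[f]][cohort$group == "chow"]
    b <- cohort[[f]][cohort$group == "caf"]
    res <- compare_groups(a, b)
    tibble::tibble(field = f, chow_mean = mean(a), caf_mean = mean(b),
                   test = res$test, statistic = res$statistic, p = res$p)
  })
  do.call(rbind, rows)
}

#' Correlation screen against a nerve excitability measure
#'
#' Pearson (or Spearman) correlations of one column (superexcitability by
#' default) against a set of metabolic measures across the pooled cohort,
#' with two-sided p-values from the exact t-transform.  No multiplicity
#' correction is applied, matching the study's analysis; pass the output
#' to [stats::p.adjust()] if false-discovery control is wanted.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param outcome column correlated against the others.
#' @param fields metabolic columns to test.
#' @param method `"pearson"` or `"spearman"`.
#' @return tibble with columns `field`, `method`, `r`, `n`, `p`.
#' @export
cohort_correlations <- function(cohort, outcome = "superexcitability",
                                fields = c("fat_mass", "body_weight",
                                           "lean_mass", "HDL", "leptin",
                                           "rpWAT", "HOMA_IR", "gtt_auc"),
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  testfun <- if (method == "pearson") pearson_test else spearman_test
  rows <- lapply(fields, function(f) {
    ct <- testfun(cohort[[outcome]], cohort[[f]])
    tibble::tibble(field = f, method = ct$method, r = ct$r, n = ct$n,
                   p = ct$p)
  })
  do.call(rbind, rows)
}
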