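# Bundled group-mean excitability indices (mean +/- SEM) from the
# cafeteria-diet prediabetes study cohort: chow-fed controls and
# cafeteria-fed (CAF) rats, n = 12-14 per group.  These are the calibration
# targets for the chow baseline model and the CAF re-fit.

#' Group-mean excitability indices of the cafeteria-diet study
#'
#' Returns the recorded tibial motor nerve excitability indices of the
#' chow-fed control or cafeteria-fed (CAF) group as mean and SEM:
#' depolarizing threshold electrotonus averaged over 10-20 ms
#' (`ted_10_20`, %), resting current-threshold slope (`resting_iv_slope`),
#' refractoriness at a 2.5 ms interstimulus interval (%), superexcitability
#' at 5 ms (%, positive = threshold reduced) and subexcitability (%).
#'
#' @param group `"chow"` or `"caf"`.
#' @return tibble with columns `index`, `mean`, `sem`.
#' @export
study_reference_indices <- function(group = c("chow", "caf")) {
  group <- match.arg(group)
  chow <- c(ted_10_20 = 37.48, resting_iv_slope = 1.04,
            refractoriness_2p5 = 6.20, superexcitability_5 = -0.65,
            subexcitability = 8.16)
  chow_sem <- c(0.81, 0.03, 1.63, 0.68, 0.69)
  caf <- c(ted_10_20 = 36.01, resting_iv_slope = 1.06,
           refractoriness_2p5 = 7.81, superexcitability_5 = 2.14,
           subexcitability = 8.00)
  caf_sem <- c(0.95, 0.04, 1.24, 0.83, 0.96)
  if (group == "chow")
    tibble::tibble(index = names(chow), mean = unname(chow),
                   sem = chow_sem)
  else
    tibble::tibble(index = names(caf), mean = unname(caf), sem = caf_sem)
}
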