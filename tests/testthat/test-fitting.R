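# Parameter-recovery behaviour of the curve-fitting layer.  Recorded data
# are synthesized from known parameter sets, so truth is available.  The
# tests use reduced protocol lattices to keep the simulation budget small;
# the full default lattices are exercised by the acceptance suite.

fit_lattices <- list(
  sd_durations = c(0.2, 0.6, 1),
  te_levels = c(40, -40),
  te_delays = c(1.5, 10, 20, 60, 100, 150),
  iv_levels = c(20, 10, -10, -20),
  rc_isis = c(2.5, 3.5, 5, 7, 10, 18, 32, 56, 100, 200)
)

sim_curves <- function(params, noise_sd = 0, seed = 1) {
  do.call(generate_recorded_excitability,
          c(list(params = params, noise_sd = noise_sd, seed = seed),
            fit_lattices))
}

baseline <- default_axon_params()
rec_self <- sim_curves(baseline)

test_that("fitting recorded data generated from the baseline changes nothing", {
  fit <- fit_parameters(baseline, rec_self, "I_pump")
  expect_lt(fit$discrepancy_before, 1e-6)
  expect_lt(fit$discrepancy_after, 1e-6)
  expect_lt(abs(fit$changed_parameters$fitted -
                  fit$changed_parameters$baseline), 2)
})

test_that("a pump-only perturbation is recovered within +/- 2 pA", {
  truth <- set_params(baseline, list(I_pump = baseline$I_pump - 15))
  rec <- sim_curves(truth)
  fit <- fit_parameters(baseline, rec, "I_pump")
  delta <- fit$changed_parameters$fitted - fit$changed_parameters$baseline
  expect_lt(abs(delta - (-15)), 2)
  expect_gt(fit$pct_reduction, 90)
})

test_that("adding a second free parameter never worsens the fit", {
  truth <- set_params(baseline, list(I_pump = baseline$I_pump - 15))
  rec <- sim_curves(truth)
  single <- fit_parameters(baseline, rec, "I_pump")
  start <- list(I_pump = single$changed_parameters$fitted)
  both <- fit_parameters(baseline, rec, c("I_pump", "G_H"),
                         start = start, max_eval = 60)
  expect_lte(both$discrepancy_after, single$discrepancy_after * 1.0001)
})

test_that("the scan ranks the truly perturbed parameter first", {
  truth <- set_params(baseline, list(I_pump = baseline$I_pump - 15))
  rec <- sim_curves(truth)
  scan <- single_parameter_scan(baseline, rec,
                                candidates = c("I_pump", "G_H", "G_BB",
                                               "G_Ks_n", "G_Lk_i"))
  expect_equal(scan$results$parameter[1], "I_pump")
  expect_gt(scan$results$pct_reduction[1], 90)
})

test_that("identical seeds give identical calibration results", {
  targets <- tibble::tibble(
    index = c("refractoriness_2p5", "superexcitability_5"),
    mean = c(6.2, -0.65), sem = c(1.63, 0.68))
  a <- calibrate_baseline(targets, c("G_Kf_i", "I_pump"), seed = 4,
                          n_starts = 1, max_eval = 8, tol_obj = 1e9)
  b <- calibrate_baseline(targets, c("G_Kf_i", "I_pump"), seed = 4,
                          n_starts = 1, max_eval = 8, tol_obj = 1e9)
  expect_identical(a$fit$changed_parameters, b$fit$changed_parameters)
  expect_identical(a$fit$discrepancy_after, b$fit$discrepancy_after)
})

test_that("recording noise raises the discrepancy quadratically", {
  clean <- sim_curves(baseline)
  d_at <- function(sd) {
    mean(vapply(1:3, function(s) {
      discrepancy(sim_curves(baseline, noise_sd = sd, seed = 10 + s), clean)
    }, numeric(1)))
  }
  d1 <- d_at(1)
  d2 <- d_at(2)
  expect_gt(d1, 0)
  expect_gt(d2 / d1, 2)   # ~4 expected for variance scaling
  expect_lt(d2 / d1, 8)
  # distinct seeds give distinct curves
  a <- sim_curves(baseline, noise_sd = 1, seed = 1)
  b <- sim_curves(baseline, noise_sd = 1, seed = 2)
  expect_false(identical(a$rc$threshold_change_pct,
                         b$rc$threshold_change_pct))
})
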