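# Protocol-level behaviour of the threshold tracker on the default model.
# One resting state and control threshold are shared across blocks to keep
# the suite fast.

p_default <- default_axon_params()
rest_default <- resting_state(p_default)
t0_default <- find_threshold(p_default, 1, rest = rest_default)

test_that("threshold search is deterministic and brackets to 0.5%", {
  t_again <- find_threshold(p_default, 1, rest = rest_default)
  expect_identical(t0_default, t_again)
  expect_gt(t0_default, 0)
})

test_that("bisection agrees with a brute-force amplitude scan within 1%", {
  scan <- threshold_scan(p_default, 1, rest = rest_default,
                         lo = 0.8 * t0_default, hi = 1.25 * t0_default,
                         step_frac = 0.0025)
  expect_lt(abs(scan - t0_default) / t0_default, 0.01)
})

test_that("strength-duration thresholds decrease with duration (Weiss behaviour)", {
  sdp <- run_strength_duration(p_default, rest = rest_default)
  thr <- sdp$curve$threshold_pA
  expect_true(all(diff(thr) < 0))          # longer pulses need less current
  q <- thr * sdp$curve$duration_ms
  expect_true(all(diff(q) > 0))            # charge strictly increasing
  expect_gte(sdp$r_squared, 0.99)          # Weiss-law adequacy
  expect_gt(sdp$sdtc, 0)
  expect_gt(sdp$rheobase, 0)
})

test_that("all-or-none firing: a sharp amplitude threshold exists", {
  eps <- 0.02
  cond <- NULL
  fires <- function(amp) {
    tr <- integrate_axon(p_default, stim_pulse(1e-9, 1, amp), 4.2,
                         state0 = rest_default)
    length(attr(tr, "crossings")) > 0
  }
  expect_false(fires((1 - eps) * t0_default))
  expect_true(fires((1 + eps) * t0_default))
})

test_that("zero-amplitude conditioning leaves electrotonus flat", {
  te <- run_threshold_electrotonus(p_default, levels = 0,
                                   delays = c(10, 60, 200),
                                   rest = rest_default, t0 = t0_default)
  expect_true(all(abs(te$curves$threshold_reduction_pct) < 0.6))
})

test_that("depolarizing electrotonus reduces threshold at 10-20 ms", {
  te <- run_threshold_electrotonus(p_default, levels = 40,
                                   delays = c(10, 13, 16, 20),
                                   rest = rest_default, t0 = t0_default)
  expect_gt(te$ted_10_20, 0)
})

test_that("current-threshold relation is monotone near rest", {
  iv <- run_current_threshold(p_default, levels = c(20, 10, -10, -20),
                              rest = rest_default, t0 = t0_default)
  red <- iv$curve$threshold_reduction_pct
  expect_true(all(diff(red) < 0))  # levels stored decreasing
  expect_true(is.finite(iv$resting_iv_slope))
})

test_that("recovery cycle recovers fully by 200 ms and rejects short ISIs", {
  rc <- run_recovery_cycle(p_default, isis = c(2.5, 5, 32, 200),
                           rest = rest_default, rel_tol = 5e-4)
  tc200 <- rc$curve$threshold_change_pct[rc$curve$isi_ms == 200]
  expect_lt(abs(tc200), 0.2)
  expect_error(run_recovery_cycle(p_default, isis = c(1, 5)),
               "2.5 ms minimum")
})

test_that("indices are stable under control-threshold remeasurement", {
  # recompute T0 from scratch and rerun one paradigm: indices shift < 0.1%
  t0_b <- find_threshold(p_default, 1, rest = rest_default,
                         guess = t0_default * 1.07)
  expect_lt(abs(t0_b - t0_default) / t0_default, 0.005)
  rc_a <- run_recovery_cycle(p_default, isis = c(2.5, 5),
                             rest = rest_default, t0 = t0_default)
  rc_b <- run_recovery_cycle(p_default, isis = c(2.5, 5),
                             rest = rest_default, t0 = t0_b)
  expect_lt(abs(rc_a$refractoriness_2p5 - rc_b$refractoriness_2p5), 0.75)
})

test_that("conditioned thresholds match a brute-force scan within 1%", {
  cond <- stim_pulse(1e-9, 1, 2 * t0_default)
  ctx <- list(stimulus = cond, test_onset = 10)
  thr <- find_threshold(p_default, 1, context = ctx, rest = rest_default,
                        guess = t0_default, check_spontaneous = FALSE)
  scan <- threshold_scan(p_default, 1, context = ctx, rest = rest_default,
                         lo = 0.85 * thr, hi = 1.2 * thr,
                         step_frac = 0.005)
  expect_lt(abs(scan - thr) / thr, 0.01)
})
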