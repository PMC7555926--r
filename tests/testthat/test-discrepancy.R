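make_curves <- function(rc_offset = 0, te_offset = 0) {
  suppressWarnings(excitability_curves(
    sd = data.frame(duration_ms = c(0.2, 0.4, 0.6, 0.8, 1),
                    threshold_pA = c(500, 320, 260, 230, 210)),
    te = data.frame(series = rep(c("te_+40", "te_-40"), each = 4),
                    delay_ms = rep(c(1.5, 10, 20, 100), 2),
                    threshold_reduction_pct =
                      c(40, 38, 36, 30, -40, -45, -48, -55) + te_offset),
    iv = data.frame(conditioning_pct = seq(50, -100, by = -50),
                    threshold_reduction_pct = c(40, 0, -60, -130)),
    rc = data.frame(isi_ms = c(2.5, 5, 10, 32, 100, 200),
                    threshold_change_pct =
                      c(6.2, -0.7, 4, 8, 2, 0.1) + rc_offset)
  ))
}

test_that("discrepancy is a pseudo-metric on curve space", {
  a <- make_curves()
  expect_equal(discrepancy(a, a), 0)
  b <- make_curves(rc_offset = 2, te_offset = -1)
  expect_gt(discrepancy(a, b), 0)
  # symmetry
  expect_equal(discrepancy(a, b), discrepancy(b, a))
})

test_that("weights act linearly on their paradigm contribution", {
  a <- make_curves()
  b <- make_curves(rc_offset = 1.5)
  d1 <- discrepancy(a, b)
  d2 <- discrepancy(a, b, discrepancy_weights(w_rc = 6))
  # rc is the only differing paradigm: doubling w_rc doubles the score
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  # a 1-unit offset on every rc point, default weights -> D = 3 * 1^2
  b1 <- make_curves(rc_offset = 1)
  expect_equal(discrepancy(a, b1), 3, tolerance = 1e-12)
})

test_that("lattice mismatches and empty paradigms are rejected", {
  a <- make_curves()
  b <- make_curves()
  b$rc <- b$rc[-2, ]
  expect_error(discrepancy(a, b), "mismatched rc")
  b2 <- make_curves()
  b2$rc <- b2$rc[0, ]
  expect_error(discrepancy(a, b2), "empty rc")
  expect_error(discrepancy_weights(w_sd = -1), "non-negative")
  expect_error(discrepancy_weights(w_sd = 0, w_te = 0, w_iv = 0, w_rc = 0),
               "at least one")
})

test_that("strength-duration enters on the log-threshold scale", {
  a <- make_curves()
  b <- make_curves()
  b$sd$threshold_pA <- a$sd$threshold_pA * 10^(1 / 100)  # +1 unit in 100*log10
  d <- discrepancy(a, b, discrepancy_weights(w_sd = 0.5, w_te = 0,
                                             w_iv = 0, w_rc = 0))
  expect_equal(d, 0.5, tolerance = 1e-9)
})

test_that("Weiss-law fit inverts exact synthetic strength-duration data", {
  durations <- c(0.2, 0.4, 0.6, 0.8, 1)
  rheobase <- 100
  sdtc <- 0.3
  thresholds <- rheobase * (1 + sdtc / durations)
  w <- weiss_fit(durations, thresholds)
  expect_equal(w$rheobase, 100, tolerance = 1e-9)
  expect_equal(w$sdtc, 0.3, tolerance = 1e-9)
  expect_equal(w$r_squared, 1, tolerance = 1e-9)
})
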