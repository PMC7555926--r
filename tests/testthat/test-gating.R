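test_that("linoid rate forms take their analytic limit at V == B", {
  # alpha(V) = A (V - B) / (1 - exp(-(V - B)/C)) -> A * C as V -> B
  rc <- data.frame(
    gate = c("m", "m"), rate = c("alpha", "beta"),
    form = c("linoid", "exp"),
    A = c(0.5, 2), B = c(-40, -40), C = c(8, -10)
  )
  p <- axon_params()
  p$rate_coeffs[p$rate_coeffs$gate == "m", ] <- rc
  r_at_B <- gating_rates("m", -40, p)
  expect_equal(r_at_B$alpha, 0.5 * 8, tolerance = 1e-6)
  # continuous through the singularity
  r_near <- gating_rates("m", -40 + c(-1e-4, 1e-4), p)
  expect_true(all(abs(r_near$alpha - 4) < 1e-3))
  expect_true(all(is.finite(r_near$alpha)))
  # falling linoid limit
  p$rate_coeffs[p$rate_coeffs$gate == "m" &
                  p$rate_coeffs$rate == "alpha",
                c("form", "A", "B", "C")] <-
    list("linoid_down", 0.3, -55, 12)
  expect_equal(gating_rates("m", -55, p)$alpha, 0.3 * 12,
               tolerance = 1e-6)
})

test_that("temperature scaling follows Q10 and is neutral at Q10 = 1", {
  p <- axon_params()
  p$q10[] <- 1
  r37 <- gating_rates("h", -70, p)
  p$T <- 27
  r27 <- gating_rates("h", -70, p)
  expect_equal(r37, r27)

  p2 <- axon_params()
  p2$q10[] <- 3
  base <- gating_rates("s_n", -60, p2)
  p2$T <- p2$T_ref + 10
  warm <- gating_rates("s_n", -60, p2)
  expect_equal(warm$alpha, 3 * base$alpha, tolerance = 1e-12)
  expect_equal(warm$beta, 3 * base$beta, tolerance = 1e-12)
})

test_that("activation steady states are monotone over the physiological range", {
  p <- default_axon_params()
  V <- seq(-100, 40, by = 1)
  m_inf <- gate_steady_state("m", V, p)$x_inf
  expect_true(all(diff(m_inf) > 0))
  # inactivation gate is monotone decreasing
  h_inf <- gate_steady_state("h", V, p)$x_inf
  expect_true(all(diff(h_inf) < 0))
  # rates are non-negative and finite everywhere
  for (g in c("m", "h", "p", "s_n", "s_i", "n_f", "q")) {
    r <- gating_rates(g, V, p)
    expect_true(all(r$alpha >= 0 & is.finite(r$alpha)))
    expect_true(all(r$beta >= 0 & is.finite(r$beta)))
  }
  expect_error(gating_rates("zz", -60, p), "unknown gate_id")
})
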