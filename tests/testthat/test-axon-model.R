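test_that("reported per-channel currents sum to the compartment totals", {
  p <- default_axon_params()
  st <- axon_state(-63.2, -71.5, c(m = 0.2, h = 0.6, p = 0.1, s_n = 0.3,
                                   s_i = 0.25, n_f = 0.15, q = 0.4))
  cur <- membrane_currents(st, p)
  node_sum <- cur[["Na_t"]] + cur[["Na_p"]] + cur[["Ks_node"]] +
    cur[["Kf_node"]] + cur[["leak_node"]] + cur[["pump_node"]]
  inter_sum <- cur[["Ks_internode"]] + cur[["Kf_internode"]] + cur[["H"]] +
    cur[["leak_internode"]] + cur[["pump_internode"]]
  expect_equal(node_sum, cur[["total_node"]], tolerance = 1e-12)
  expect_equal(inter_sum, cur[["total_internode"]], tolerance = 1e-12)

  # consistency with the compiled right-hand side: C dV/dt must equal the
  # negative of (total + coupling) currents computed independently in R
  pk <- axotrace:::.pack_params(p)
  dy <- axotrace:::cpp_rhs(as.numeric(st), pk$pvec, pk$rates, pk$q10, 0, 0)
  expect_equal(p$C_n * dy[1],
               -(cur[["total_node"]] + cur[["coupling"]]),
               tolerance = 1e-9)
  expect_equal(p$C_i * dy[2],
               -(cur[["total_internode"]] - cur[["coupling"]]),
               tolerance = 1e-9)
})

test_that("trivial current identities hold", {
  p <- axon_params(I_pump = 0)
  gates0 <- setNames(rep(0, 7), c("m", "h", "p", "s_n", "s_i", "n_f", "q"))
  st <- axon_state(p$E_Lk, p$E_Lk, gates0)
  cur <- membrane_currents(st, p)
  expect_equal(cur[["total_node"]], 0, tolerance = 1e-12)
  expect_equal(cur[["coupling"]], 0, tolerance = 1e-12)

  # doubling G_NaT doubles the transient Na component only
  st2 <- axon_state(-50, -70, c(m = 0.5, h = 0.5, p = 0.2, s_n = 0.1,
                                s_i = 0.1, n_f = 0.1, q = 0.2))
  c1 <- membrane_currents(st2, p)
  c2 <- membrane_currents(st2, set_params(p, list(G_NaT = 2 * p$G_NaT)))
  expect_equal(c2[["Na_t"]], 2 * c1[["Na_t"]])
  expect_equal(c2[["Ks_node"]], c1[["Ks_node"]])
})

test_that("leak-only model rests exactly at the leak reversal", {
  p <- axon_params(G_NaT = 0, G_Ks_n = 0, G_Ks_i = 0, G_Kf_n = 0,
                   G_Kf_i = 0, G_H = 0, I_pump = 0)
  rs <- resting_state(p)
  expect_equal(rs[["V_n"]], p$E_Lk, tolerance = 1e-6)
  expect_equal(rs[["V_i"]], p$E_Lk, tolerance = 1e-6)
})

test_that("resting state is an equilibrium with gates at steady state", {
  p <- default_axon_params()
  rs <- resting_state(p)
  pk <- axotrace:::.pack_params(p)
  dy <- axotrace:::cpp_rhs(as.numeric(rs), pk$pvec, pk$rates, pk$q10, 0,
                           solver_opts()$tau_floor)
  expect_lt(max(abs(dy[1:2])), 1e-6)
  expect_lt(max(abs(dy[3:9])), 1e-9)

  # fixed point under integration: 100 ms with zero stimulus
  tr <- integrate_axon(p, stim_none(), 100, state0 = rs)
  expect_lt(abs(tr$V_n_mV[nrow(tr)] - rs[["V_n"]]), 1e-3)
})

test_that("reducing the pump current depolarizes the resting potential", {
  p <- default_axon_params()
  rs <- resting_state(p)
  rs2 <- resting_state(set_params(p, list(I_pump = p$I_pump - 15)))
  expect_gt(rs2[["V_n"]], rs[["V_n"]])
  expect_gt(rs2[["V_i"]], rs[["V_i"]])
})

test_that("integration is convergent in the step-size cap", {
  p <- default_axon_params()
  rs <- resting_state(p)
  stim <- stim_pulse(1, 0.5, 30)
  a <- integrate_axon(p, stim, 20, state0 = rs,
                      opts = solver_opts(dt_max = 0.1))
  b <- integrate_axon(p, stim, 20, state0 = rs,
                      opts = solver_opts(dt_max = 0.05))
  expect_lt(abs(a$V_n_mV[nrow(a)] - b$V_n_mV[nrow(b)]), 1e-2)
  # gates stay within [0, 1] throughout
  for (g in c("m", "h", "p", "s_n", "s_i", "n_f", "q")) {
    expect_true(all(a[[g]] >= 0 & a[[g]] <= 1))
  }
})

test_that("a strong brief stimulus elicits an action potential", {
  p <- default_axon_params()
  rs <- resting_state(p)
  t0 <- find_threshold(p, 1, rest = rs)
  tr <- integrate_axon(p, stim_pulse(1e-9, 1, 3 * t0), 5, state0 = rs)
  expect_gt(attr(tr, "vmax"), 0)
  expect_gte(length(attr(tr, "crossings")), 1)
  expect_lt(attr(tr, "crossings")[1], 3)
})

test_that("temperature neutrality: Q10 = 1 trajectories ignore T", {
  p <- default_axon_params()
  p$q10[] <- 1
  rs <- resting_state(p)
  t1 <- integrate_axon(p, stim_pulse(1, 1, 50), 10, state0 = rs)
  p$T <- 25
  t2 <- integrate_axon(p, stim_pulse(1, 1, 50), 10, state0 = rs)
  expect_equal(t1$V_n_mV, t2$V_n_mV, tolerance = 1e-12)
})
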