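# Model dynamics: gating kinetics, membrane currents, the resting-state
# solver ("unclamped" contract) and the trajectory integrator.

#' Voltage-dependent opening and closing rates of a gating variable
#'
#' Evaluates the alpha/beta rate functions of one of the seven gates
#' (`m`, `h`, `p`, `s_n`, `s_i`, `n_f`, `q`), scaled by
#' `Q10^((T - T_ref)/10)`.  The removable singularity of the linoid form at
#' `V == B` is handled by its analytic limit `A * C`.
#'
#' @param gate_id one of the seven gate names.
#' @param V membrane potential(s), mV; vectorised.
#' @param params an `axon_params` object.
#' @return list with numeric vectors `alpha` and `beta` (1/ms).
#' @examples
#' r <- gating_rates("m", -60, axon_params())
#' r$alpha / (r$alpha + r$beta)  # steady state at -60 mV
#' @export
gating_rates <- function(gate_id, V, params) {
  gi <- match(gate_id, GATE_NAMES)
  if (is.na(gi)) stop("unknown gate_id: ", gate_id)
  stopifnot(all(is.finite(V)))
  pk <- .pack_params(params)
  tfac <- (params$T - params$T_ref) / 10
  out <- cpp_gate_rates(gi, as.numeric(V), pk$rates, pk$q10, tfac, 0)
  n <- length(V)
  alpha <- out[seq_len(n)]
  beta <- out[n + seq_len(n)]
  if (any(!is.finite(alpha)) || any(!is.finite(beta)))
    stop("non-finite gating rate for gate ", gate_id)
  list(alpha = alpha, beta = beta)
}

#' Steady-state value and time constant of a gate
#'
#' @inheritParams gating_rates
#' @return list with `x_inf` (dimensionless) and `tau` (ms).
#' @export
gate_steady_state <- function(gate_id, V, params) {
  r <- gating_rates(gate_id, V, params)
  list(x_inf = r$alpha / (r$alpha + r$beta), tau = 1 / (r$alpha + r$beta))
}

.steady_gates <- function(params, V_n, V_i) {
  vsrc <- c(m = V_n, h = V_n, p = V_n, s_n = V_n, s_i = V_i, n_f = V_n,
            q = V_i)
  vapply(GATE_NAMES, function(g) {
    gate_steady_state(g, vsrc[[g]], params)$x_inf
  }, numeric(1))
}

#' Construct an axon state vector
#'
#' @param V_n,V_i nodal and internodal membrane potential, mV.
#' @param gates named vector of the seven gate values in \[0, 1\].
#' @return named numeric of class `axon_state`.
#' @export
axon_state <- function(V_n, V_i, gates) {
  stopifnot(length(gates) == 7, all(GATE_NAMES %in% names(gates)))
  g <- gates[GATE_NAMES]
  if (any(g < 0 | g > 1)) stop("gates must lie in [0, 1]")
  structure(c(V_n = V_n, V_i = V_i, g), class = "axon_state")
}

#' Per-channel membrane currents
#'
#' Decomposes the instantaneous membrane current of both compartments into
#' its components (outward positive).  The coupling current
#' `G_BB * (V_n - V_i)` flows from node to internode.
#'
#' @param state an `axon_state` (named numeric with `V_n`, `V_i` and the
#'   seven gates).
#' @param params an `axon_params` object.
#' @return named numeric vector of currents in pA, including the totals
#'   `total_node`, `total_internode` and `coupling`.
#' @export
membrane_currents <- function(state, params) {
  s <- unclass(state)
  Vn <- s[["V_n"]]; Vi <- s[["V_i"]]
  with(params, {
    i_nat <- G_NaT * s[["m"]]^3 * s[["h"]] * (Vn - E_Na)
    i_nap <- G_NaT * f_NaP * s[["p"]]^3 * (Vn - E_Na)
    i_ks_n <- G_Ks_n * s[["s_n"]] * (Vn - E_K)
    i_kf_n <- G_Kf_n * s[["n_f"]]^4 * (Vn - E_K)
    i_lk_n <- G_Lk_n * (Vn - E_Lk)
    i_pump_n <- f_pump_node * I_pump
    dek <- k_EK_pump * (I_pump_ref - I_pump)  # periaxonal K coupling
    i_ks_i <- G_Ks_i * s[["s_i"]] * (Vi - (E_K + dek))
    i_kf_i <- G_Kf_i * s[["n_f"]]^4 * (Vi - (E_K + dek))
    i_h <- G_H * s[["q"]] * (Vi - E_H)
    i_lk_i <- G_Lk_i * (Vi - (E_Lk + f_K_leak_i * dek))
    i_pump_i <- (1 - f_pump_node) * I_pump
    c(
      Na_t = i_nat, Na_p = i_nap, Ks_node = i_ks_n, Kf_node = i_kf_n,
      leak_node = i_lk_n, pump_node = i_pump_n,
      Ks_internode = i_ks_i, Kf_internode = i_kf_i, H = i_h,
      leak_internode = i_lk_i, pump_internode = i_pump_i,
      coupling = G_BB * (Vn - Vi),
      total_node = i_nat + i_nap + i_ks_n + i_kf_n + i_lk_n + i_pump_n,
      total_internode = i_ks_i + i_kf_i + i_h + i_lk_i + i_pump_i
    )
  })
}

#' Solve the resting state of the model axon
#'
#' Finds the equilibrium of the full system: membrane potentials at which
#' all compartment currents balance with every gate at its voltage-dependent
#' steady state.  The model is always run "unclamped": after any parameter
#' change the resting state must be re-solved (all protocol drivers in this
#' package do so), so that perturbations such as a reduced pump current are
#' allowed to shift the resting membrane potential.
#'
#' The solver relaxes the system by integration and then polishes the
#' equilibrium with a damped Newton iteration on (V_n, V_i).
#'
#' @param params an `axon_params` object.
#' @param opts solver settings from [solver_opts()].
#' @param v_tol convergence tolerance on |dV/dt|, mV/ms.
#' @param relax_ms duration of the relaxation integration, ms.
#' @return an `axon_state` at equilibrium.
#' @export
resting_state <- function(params, opts = solver_opts(), v_tol = 1e-6,
                          relax_ms = 400) {
  validate_axon_params(params)
  pk <- .pack_params(params)
  g0 <- .steady_gates(params, params$E_Lk, params$E_Lk)
  y0 <- c(params$E_Lk, params$E_Lk, g0)

  res <- cpp_integrate(y0, pk$pvec, pk$rates, pk$q10, numeric(0), numeric(0),
                       relax_ms, 0.25, 1e-8, opts$tau_floor, FALSE, 0,
                       relax_ms)
  V <- res$state[1:2]

  resid <- function(V) {
    g <- .steady_gates(params, V[1], V[2])
    dy <- cpp_rhs(c(V, g), pk$pvec, pk$rates, pk$q10, 0, opts$tau_floor)
    dy[1:2]
  }
  for (it in 1:60) {
    f <- resid(V)
    if (max(abs(f)) < v_tol / 10) break
    eps <- 1e-6
    J <- cbind((resid(V + c(eps, 0)) - f) / eps,
               (resid(V + c(0, eps)) - f) / eps)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      Vn <- V + lam * step
      fn <- tryCatch(resid(Vn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          max(abs(fn)) < max(abs(f)) * (1 - 0.25 * lam) + 1e-14) {
        V <- Vn
        break
      }
      lam <- lam / 2
      if (lam < 1e-4) { V <- V + 1e-4 * step; break }
    }
  }
  f <- resid(V)
  if (max(abs(f)) >= v_tol)
    stop(sprintf(
      "resting-state solver failed to converge: |dV/dt| = %.3g mV/ms at V_n = %.2f, V_i = %.2f mV",
      max(abs(f)), V[1], V[2]))
  axon_state(V[1], V[2], .steady_gates(params, V[1], V[2]))
}

# ---- stimulus waveforms -------------------------------------------------

#' Piecewise-constant stimulus waveforms
#'
#' A stimulus is a data frame with columns `time` (ms, the left edge of each
#' segment, starting at 0) and `amplitude` (pA, applied at the node;
#' depolarising positive).  `stim_none()` is the zero stimulus,
#' `stim_pulse()` a rectangular pulse, and `stim_sum()` superimposes any
#' number of waveforms (conditioning plus test stimuli).
#'
#' @param onset pulse onset, ms.
#' @param duration pulse duration, ms.
#' @param amplitude pulse amplitude, pA.
#' @return a stimulus data frame.
#' @export
stim_pulse <- function(onset, duration, amplitude) {
  stopifnot(onset >= 0, duration > 0)
  out <- data.frame(time = c(0, onset, onset + duration),
                    amplitude = c(0, amplitude, 0))
  out[!duplicated(out$time, fromLast = TRUE), , drop = FALSE]
}

#' @rdname stim_pulse
#' @export
stim_none <- function() data.frame(time = 0, amplitude = 0)

#' @rdname stim_pulse
#' @param ... stimulus data frames to superimpose.
#' @export
stim_sum <- function(...) {
  parts <- list(...)
  edges <- sort(unique(unlist(lapply(parts, function(s) s$time))))
  amp <- vapply(edges, function(t0) {
    sum(vapply(parts, function(s) {
      i <- findInterval(t0 + 1e-12, s$time)
      if (i < 1) 0 else s$amplitude[i]
    }, numeric(1)))
  }, numeric(1))
  data.frame(time = edges, amplitude = amp)
}

# Re-express a piecewise-constant stimulus relative to a later origin t0:
# the segment active at t0 becomes the segment starting at time 0.
.stim_shift <- function(stimulus, t0) {
  tm <- stimulus$time - t0
  amp <- stimulus$amplitude
  keep <- tm > 0
  i0 <- findInterval(0, stimulus$time - t0)  # segment active at t0
  out <- data.frame(time = c(0, tm[keep]),
                    amplitude = c(if (i0 >= 1) amp[i0] else 0, amp[keep]))
  out[!duplicated(out$time), , drop = FALSE]
}

.check_stim <- function(stimulus) {
  stopifnot(is.data.frame(stimulus),
            all(c("time", "amplitude") %in% names(stimulus)))
  if (is.unsorted(stimulus$time, strictly = TRUE))
    stop("stimulus edges must be strictly increasing")
  if (stimulus$time[1] < 0) stop("stimulus must start at time >= 0")
  stimulus
}

# Low-level integration returning the raw C++ result.  `pk` lets hot loops
# (threshold bisection) reuse one packed parameter set.
.integrate_raw <- function(params, state0, stimulus, t_end,
                           opts = solver_opts(), record = FALSE,
                           watch = c(0, t_end), pk = NULL) {
  if (is.null(pk)) pk <- .pack_params(params)
  cpp_integrate(as.numeric(state0), pk$pvec, pk$rates, pk$q10,
                stimulus$time, stimulus$amplitude, t_end, opts$dt_max,
                opts$rtol, opts$tau_floor, record, watch[1], watch[2])
}

#' Integrate the axon model over time
#'
#' Runs the model under a piecewise-constant nodal current stimulus using an
#' adaptive Dormand-Prince (RK45) integrator with steps forced onto stimulus
#' edges and capped near them, so that action potentials are resolved.
#'
#' @param params an `axon_params` object.
#' @param stimulus a stimulus data frame (see [stim_pulse()]).
#' @param t_end end time, ms.
#' @param state0 initial `axon_state`; defaults to [resting_state()].
#' @param opts solver settings from [solver_opts()].
#' @return a tibble with columns `time_ms`, `V_n_mV`, `V_i_mV` and the seven
#'   gate variables, one row per accepted integration step.  Attributes
#'   `crossings` (times at which V_n crossed 0 mV upward) and `vmax` carry
#'   the spike-detection summaries.
#' @export
integrate_axon <- function(params, stimulus = stim_none(), t_end = 100,
                           state0 = NULL, opts = solver_opts()) {
  validate_axon_params(params)
  .check_stim(stimulus)
  stopifnot(t_end > 0)
  if (is.null(state0)) state0 <- resting_state(params, opts)
  res <- .integrate_raw(params, state0, stimulus, t_end, opts, record = TRUE)
  tr <- res$trajectory
  colnames(tr) <- c("time_ms", "V_n_mV", "V_i_mV", GATE_NAMES)
  out <- tibble::as_tibble(as.data.frame(tr))
  attr(out, "crossings") <- res$crossings
  attr(out, "vmax") <- res$vmax
  out
}

#' Export a simulated trajectory to CSV
#'
#' @param trajectory tibble returned by [integrate_axon()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(trajectory, path)
  invisible(path)
}
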