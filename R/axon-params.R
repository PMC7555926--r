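# Membrane parameter container for the two-compartment axon model.
#
# The model represents a single myelinated motor axon as a node of Ranvier
# coupled to its internode by the Barrett-Barrett conductance (the current
# pathway through and underneath the myelin sheath).  All driving forces are
# ohmic, G * (V - E).  Units form a self-consistent system: potentials mV,
# time ms, current pA, conductance nS, capacitance pF (pA = nS * mV,
# ms = pF / nS).

GATE_NAMES <- c("m", "h", "p", "s_n", "s_i", "n_f", "q")
RATE_FORMS <- c(linoid = 1L, exp = 2L, sigmoid = 3L, linoid_down = 4L)

SCALAR_PARAM_NAMES <- c(
  "C_n", "C_i", "G_NaT", "f_NaP", "G_Ks_n", "G_Ks_i", "G_Kf_n", "G_Kf_i",
  "G_H", "G_Lk_n", "G_Lk_i", "G_BB", "E_Na", "E_K", "E_H", "E_Lk",
  "I_pump", "f_pump_node", "T", "T_ref", "k_EK_pump", "I_pump_ref",
  "f_K_leak_i"
)

# Build an alpha/beta sigmoid pair from a target steady-state sigmoid
# (half-voltage Vh mV, slope k mV) and time constant tau0 ms:
#   alpha = (1/tau0) / (1 + exp(-(V - Vh)/k))
#   beta  = (1/tau0) / (1 + exp(+(V - Vh)/k))
# so alpha + beta = 1/tau0 at every V: x_inf is exactly the target sigmoid
# and tau is voltage independent, which keeps the system non-stiff over the
# whole physiological voltage range.
.sigmoid_pair <- function(gate, Vh, k, tau0) {
  data.frame(
    gate = gate, rate = c("alpha", "beta"), form = "sigmoid",
    A = 1 / tau0, B = Vh, C = c(k, -k),
    stringsAsFactors = FALSE
  )
}

# Fully general sigmoid rate row (independent amplitude, midpoint and slope
# for alpha and beta); used for gates whose opening and closing limbs have
# different voltage ranges, such as fast Na inactivation.
.sigmoid_rates <- function(gate, A_a, B_a, C_a, A_b, B_b, C_b) {
  data.frame(
    gate = gate, rate = c("alpha", "beta"), form = "sigmoid",
    A = c(A_a, A_b), B = c(B_a, B_b), C = c(C_a, C_b),
    stringsAsFactors = FALSE
  )
}

.default_rate_coeffs <- function() {
  rbind(
    .sigmoid_pair("m", -42.68, 6.0, 0.06),
    .sigmoid_rates("h", A_a = 0.8783, B_a = -58, C_a = -7,
                   A_b = 8, B_b = -25, C_b = 14),
    .sigmoid_pair("p", -76.09, 3.275, 48.63),
    .sigmoid_pair("s_n", -46.45, 9.0, 43.30),
    .sigmoid_pair("s_i", -46.45, 9.0, 43.30),
    .sigmoid_pair("n_f", -54.26, 8.0, 0.829),
    .sigmoid_pair("q", -94.47, -9.0, 111.3)
  )
}

#' Construct membrane parameters for the node/internode axon model
#'
#' Returns the full parameter set describing one model axon: compartment
#' capacitances, maximal channel conductances at the node and internode,
#' leak and Barrett-Barrett (myelin path) conductances, reversal potentials,
#' the electrogenic Na\eqn{^+}/K\eqn{^+}-pump current and the
#' voltage-dependent gating kinetics.  Any field can be overridden; omitted
#' fields take the packaged defaults, which were chosen so that the
#' simulated excitability indices of a healthy chow-fed rat motor axon are
#' close to their recorded group means before any calibration.
#'
#' The pump is modelled as a voltage-independent net outward current
#' (`I_pump`, pA) split between the compartments by `f_pump_node`; the
#' default split is proportional to compartment capacitance.
#'
#' @param ... named scalar overrides (see `SCALAR_PARAM_NAMES`), and/or
#'   `rate_coeffs` (data frame with columns gate, rate, form, A, B, C) and
#'   `q10` (named vector over the seven gates).
#' @return An object of class `axon_params`.
#' @examples
#' p <- axon_params(I_pump = 20)
#' p$I_pump
#' @export
axon_params <- function(...) {
  over <- list(...)
  p <- list(
    C_n = 1.2, C_i = 109.7,
    G_NaT = 120, f_NaP = 0.0092,
    G_Ks_n = 60.95, G_Ks_i = 12.44,
    G_Kf_n = 5.28, G_Kf_i = 10.55,
    G_H = 5.712, G_Lk_n = 1.665, G_Lk_i = 13.82, G_BB = 14.92,
    E_Na = 50, E_K = -90, E_H = -50, E_Lk = -84,
    I_pump = 32.72, f_pump_node = 0.3358,
    T = 37, T_ref = 37,
    k_EK_pump = 0, I_pump_ref = NA_real_, f_K_leak_i = 0.5,
    q10 = c(m = 2.2, h = 2.2, p = 2.2, s_n = 3, s_i = 3, n_f = 3, q = 3),
    rate_coeffs = .default_rate_coeffs()
  )
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0)
    stop("unknown axon parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (is.na(p$f_pump_node)) p$f_pump_node <- p$C_n / (p$C_n + p$C_i)
  # the periaxonal-K anchor defaults to the pump current the axon was
  # built with, so an unperturbed model has no reversal shift
  if (is.na(p$I_pump_ref)) p$I_pump_ref <- p$I_pump
  structure(p, class = "axon_params")
}

#' Default (baseline) axon parameters
#'
#' @return An `axon_params` object with the packaged defaults.
#' @export
default_axon_params <- function() axon_params()

#' Validate an axon parameter set
#'
#' Checks the physical invariants: positive capacitances, non-negative
#' conductances, fractions in \[0, 1\] and the physiological ordering of
#' reversal potentials E_K < E_Lk < E_Na.
#'
#' @param params an `axon_params` object.
#' @return `params`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_axon_params <- function(params) {
  stopifnot(inherits(params, "axon_params"))
  if (!(params$C_n > 0 && params$C_i > 0))
    stop("capacitances must be positive")
  gs <- c("G_NaT", "G_Ks_n", "G_Ks_i", "G_Kf_n", "G_Kf_i", "G_H",
          "G_Lk_n", "G_Lk_i", "G_BB")
  for (g in gs)
    if (params[[g]] < 0) stop("conductance ", g, " must be non-negative")
  if (params$f_NaP < 0 || params$f_NaP > 1)
    stop("f_NaP must lie in [0, 1]")
  if (params$f_pump_node < 0 || params$f_pump_node > 1)
    stop("f_pump_node must lie in [0, 1]")
  if (!(params$E_K < params$E_Lk && params$E_Lk < params$E_Na))
    stop("reversal potentials must satisfy E_K < E_Lk < E_Na")
  if (params$k_EK_pump < 0)
    stop("k_EK_pump must be non-negative")
  if (params$f_K_leak_i < 0 || params$f_K_leak_i > 1)
    stop("f_K_leak_i must lie in [0, 1]")
  rc <- params$rate_coeffs
  need <- c("gate", "rate", "form", "A", "B", "C")
  if (!all(need %in% names(rc))) stop("rate_coeffs is missing columns")
  if (!all(rc$form %in% names(RATE_FORMS)))
    stop("unknown rate functional form in rate_coeffs")
  for (g in GATE_NAMES)
    if (sum(rc$gate == g) != 2)
      stop("rate_coeffs must have one alpha and one beta row per gate")
  invisible(params)
}

#' Modify scalar fields of an axon parameter set
#'
#' @param params an `axon_params` object.
#' @param changes named list or vector of scalar parameter values.
#' @return the updated, validated `axon_params` object.
#' @export
set_params <- function(params, changes) {
  changes <- as.list(changes)
  bad <- setdiff(names(changes), SCALAR_PARAM_NAMES)
  if (length(bad) > 0)
    stop("cannot set non-scalar or unknown parameter(s): ",
         paste(bad, collapse = ", "))
  params[names(changes)] <- changes
  validate_axon_params(params)
  params
}

#' @export
print.axon_params <- function(x, ...) {
  cat("<axon_params> two-compartment myelinated axon\n")
  cat(sprintf("  node:      C_n %.3g pF, G_NaT %.4g nS (f_NaP %.3g), G_Ks_n %.4g, G_Kf_n %.4g, G_Lk_n %.3g nS\n",
              x$C_n, x$G_NaT, x$f_NaP, x$G_Ks_n, x$G_Kf_n, x$G_Lk_n))
  cat(sprintf("  internode: C_i %.4g pF, G_Ks_i %.4g, G_Kf_i %.4g, G_H %.4g, G_Lk_i %.3g nS\n",
              x$C_i, x$G_Ks_i, x$G_Kf_i, x$G_H, x$G_Lk_i))
  cat(sprintf("  coupling G_BB %.4g nS; pump %.4g pA (nodal fraction %.3g)\n",
              x$G_BB, x$I_pump, x$f_pump_node))
  cat(sprintf("  reversals (mV): E_Na %g, E_K %g, E_H %g, E_Lk %g; T %g C (ref %g)\n",
              x$E_Na, x$E_K, x$E_H, x$E_Lk, x$T, x$T_ref))
  invisible(x)
}

# Pack parameters into the flat numeric layout expected by the C++ core.
.pack_params <- function(params) {
  pvec <- unlist(params[SCALAR_PARAM_NAMES], use.names = FALSE)
  rc <- params$rate_coeffs
  m <- matrix(0, nrow = 2 * length(GATE_NAMES), ncol = 4)
  for (gi in seq_along(GATE_NAMES)) {
    for (ri in 1:2) {
      rn <- c("alpha", "beta")[ri]
      row <- rc[rc$gate == GATE_NAMES[gi] & rc$rate == rn, ]
      if (nrow(row) != 1)
        stop("rate_coeffs must have exactly one ", rn, " row for gate ",
             GATE_NAMES[gi])
      m[2 * (gi - 1) + ri, ] <- c(RATE_FORMS[[row$form]], row$A, row$B, row$C)
    }
  }
  list(pvec = pvec, rates = m, q10 = unname(params$q10[GATE_NAMES]))
}

#' Solver settings for the axon model integrator
#'
#' @param dt_max maximal integration step, ms.
#' @param rtol relative error tolerance of the adaptive Dormand-Prince
#'   integrator.
#' @param tau_floor smooth lower bound applied to gate time constants inside
#'   the integrator (ms); both rates of a gate are scaled by
#'   `1 / (1 + (alpha + beta) * tau_floor)`, which leaves every steady state
#'   unchanged while bounding stiffness.  Set to 0 to disable.
#' @return a list of solver settings.
#' @export
solver_opts <- function(dt_max = 0.1, rtol = 1e-8, tau_floor = 0.02) {
  stopifnot(dt_max > 0, rtol > 0, tau_floor >= 0)
  list(dt_max = dt_max, rtol = rtol, tau_floor = tau_floor)
}

# ---- configuration file round-trip --------------------------------------

#' Write axon parameters to a flat YAML configuration file
#'
#' Scalars are written as flat keys with unit comments; gating kinetics as
#' `rate.<gate>.<alpha|beta>.<field>` keys and temperature coefficients as
#' `q10.<gate>`.  Values are serialised with 17 significant digits so the
#' read/write round-trip is exact.
#'
#' @param params an `axon_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_axon_params <- function(params, path) {
  validate_axon_params(params)
  num <- function(x) formatC(x, digits = 17, format = "g")
  units <- c(
    C_n = "pF", C_i = "pF", G_NaT = "nS", f_NaP = "fraction",
    G_Ks_n = "nS", G_Ks_i = "nS", G_Kf_n = "nS", G_Kf_i = "nS", G_H = "nS",
    G_Lk_n = "nS", G_Lk_i = "nS", G_BB = "nS", E_Na = "mV", E_K = "mV",
    E_H = "mV", E_Lk = "mV", I_pump = "pA", f_pump_node = "fraction",
    T = "degC", T_ref = "degC", k_EK_pump = "mV/pA", I_pump_ref = "pA",
    f_K_leak_i = "fraction"
  )
  lines <- c(
    "# axotrace axon model parameters (flat key/value)",
    "config_version: 1"
  )
  for (nm in SCALAR_PARAM_NAMES)
    lines <- c(lines, sprintf("%s: %s  # %s", nm, num(params[[nm]]),
                              units[[nm]]))
  for (g in GATE_NAMES)
    lines <- c(lines, sprintf("q10.%s: %s", g, num(params$q10[[g]])))
  rc <- params$rate_coeffs
  for (i in seq_len(nrow(rc))) {
    key <- sprintf("rate.%s.%s", rc$gate[i], rc$rate[i])
    lines <- c(
      lines,
      sprintf("%s.form: %s", key, rc$form[i]),
      sprintf("%s.A: %s  # 1/ms (scale)", key, num(rc$A[i])),
      sprintf("%s.B: %s  # mV", key, num(rc$B[i])),
      sprintf("%s.C: %s  # mV", key, num(rc$C[i]))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read axon parameters from a configuration file
#'
#' @param path file written by [write_axon_params()].
#' @return an `axon_params` object.
#' @export
read_axon_params <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$config_version))
    stop("not an axotrace parameter file (missing config_version): ", path)
  sc <- y[SCALAR_PARAM_NAMES]
  missing <- SCALAR_PARAM_NAMES[vapply(sc, is.null, logical(1))]
  if (length(missing) > 0)
    stop("parameter file is missing key(s): ", paste(missing, collapse = ", "))
  q10 <- vapply(GATE_NAMES, function(g) {
    v <- y[[paste0("q10.", g)]]
    if (is.null(v)) stop("parameter file is missing key q10.", g)
    as.numeric(v)
  }, numeric(1))
  rows <- list()
  for (g in GATE_NAMES) for (r in c("alpha", "beta")) {
    key <- sprintf("rate.%s.%s", g, r)
    form <- y[[paste0(key, ".form")]]
    if (is.null(form)) stop("parameter file is missing key ", key, ".form")
    rows[[length(rows) + 1]] <- data.frame(
      gate = g, rate = r, form = form,
      A = as.numeric(y[[paste0(key, ".A")]]),
      B = as.numeric(y[[paste0(key, ".B")]]),
      C = as.numeric(y[[paste0(key, ".C")]]),
      stringsAsFactors = FALSE
    )
  }
  args <- c(lapply(sc, as.numeric),
            list(q10 = q10, rate_coeffs = do.call(rbind, rows)))
  names(args)[seq_along(SCALAR_PARAM_NAMES)] <- SCALAR_PARAM_NAMES
  p <- do.call(axon_params, args)
  validate_axon_params(p)
  p
}
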