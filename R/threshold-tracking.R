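# In-silico threshold tracking: the stimulus-threshold search and the four
# excitability paradigms (strength-duration, threshold electrotonus,
# current-threshold, recovery cycle), plus extraction of the scalar
# excitability indices.
#
# In a single-axon model the response is all-or-none, so "threshold" is the
# minimal 1-ms (or stated-duration) current that elicits an action
# potential, the standard modelling correspondence to tracking a criterion
# fraction of the compound muscle action potential experimentally.

DEFAULT_TE_DELAYS <- c(1.5, 4, 7, 10, 13, 16, 20, 26, 33, 42, 60, 80, 100,
                       110, 130, 160, 200)
DEFAULT_TE_LEVELS <- c(40, 20, -20, -40)
DEFAULT_IV_LEVELS <- seq(50, -100, by = -10)
DEFAULT_RC_ISIS <- c(2.5, 3, 3.5, 4, 4.5, 5, 6, 7, 8, 10, 13, 18, 24, 32,
                     43, 56, 75, 100, 140, 200)
DEFAULT_SD_DURATIONS <- c(0.2, 0.4, 0.6, 0.8, 1.0)
SUBEXC_WINDOW <- c(10, 100)

.ap_in_window <- function(params, state0, stimulus, window, opts,
                          pk = NULL) {
  t_end <- max(window[2] + 0.2, max(stimulus$time) + 0.2)
  res <- .integrate_raw(params, state0, stimulus, t_end, opts,
                        record = FALSE, watch = window, pk = pk)
  length(res$crossings) > 0
}

#' Find the stimulus current threshold of the model axon
#'
#' Bisects on the amplitude of a rectangular test stimulus until the
#' relative bracket width falls below `rel_tol` (0.5% by default); an action
#' potential is scored when the nodal potential crosses 0 mV within 3 ms of
#' test-stimulus onset.  The returned threshold is the bracket midpoint.
#' With a conditioning `context` the test pulse is superimposed on the
#' conditioning waveform at the stated onset time.
#'
#' @param params an `axon_params` object.
#' @param duration test stimulus duration, ms.
#' @param context optional conditioning: a list with elements `stimulus`
#'   (waveform data frame) and `test_onset` (ms).
#' @param rest resting `axon_state`; solved from `params` if omitted
#'   (unclamped contract).
#' @param guess optional starting estimate, pA, used to seed the bracket.
#' @param upper upper search bound, pA; beyond it the axon is declared
#'   inexcitable.
#' @param rel_tol relative bracket width at convergence.
#' @param check_spontaneous verify that no action potential occurs at zero
#'   test amplitude (error "spontaneous activity" otherwise).
#' @param opts solver settings.
#' @return threshold current, pA.
#' @export
find_threshold <- function(params, duration = 1, context = NULL, rest = NULL,
                           guess = NULL, upper = 5e5, rel_tol = 0.005,
                           check_spontaneous = TRUE, opts = solver_opts()) {
  stopifnot(duration > 0)
  if (is.null(rest)) rest <- resting_state(params, opts)
  if (is.null(context)) {
    cond <- NULL
    onset <- 0
  } else {
    cond <- .check_stim(context$stimulus)
    onset <- context$test_onset
    stopifnot(is.numeric(onset), onset >= 0)
  }
  pk <- .pack_params(params)
  if (!is.null(cond) && onset > 1) {
    # the conditioning up to test onset is identical for every probed
    # amplitude: integrate it once and bisect only over the test window
    pre <- .integrate_raw(params, rest, cond, onset, opts,
                          watch = c(0, onset), pk = pk)
    state0 <- pre$state
    tail_stim <- .stim_shift(cond, onset)
    window <- c(1e-9, 3)
    build <- function(amp) stim_sum(tail_stim, stim_pulse(1e-9, duration,
                                                          amp))
  } else {
    state0 <- rest
    window <- c(onset + 1e-9, onset + 3)
    build <- function(amp) {
      test <- stim_pulse(max(onset, 1e-9), duration, amp)
      if (is.null(cond)) test else stim_sum(cond, test)
    }
  }
  fires <- function(amp) .ap_in_window(params, state0, build(amp), window,
                                       opts, pk = pk)

  if (check_spontaneous && fires(0))
    stop("spontaneous activity: action potential at zero test amplitude")

  lo <- 0
  hi <- if (!is.null(guess) && is.finite(guess) && guess > 0) guess * 1.15
        else 200
  it <- 0
  while (!fires(hi)) {
    lo <- hi
    hi <- hi * 1.6
    it <- it + 1
    if (hi > upper || it > 60)
      stop("inexcitable: no action potential up to the search bound (",
           format(upper), " pA)")
  }
  if (lo == 0 && !is.null(guess) && guess > 0) {
    cand <- guess * 0.85
    if (cand < hi) {
      if (fires(cand)) hi <- cand else lo <- cand
    }
  }
  while ((hi - lo) / ((hi + lo) / 2) > rel_tol) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}

#' Threshold by brute-force amplitude scan
#'
#' Independent slow oracle for [find_threshold()]: scans amplitudes on a
#' fixed linear grid and returns the smallest firing amplitude.
#'
#' @inheritParams find_threshold
#' @param lo,hi scan range, pA.
#' @param step_frac grid step as a fraction of the range.
#' @return threshold current, pA.
#' @export
threshold_scan <- function(params, duration = 1, context = NULL, rest = NULL,
                           lo, hi, step_frac = 0.0025,
                           opts = solver_opts()) {
  if (is.null(rest)) rest <- resting_state(params, opts)
  onset <- if (is.null(context)) 0 else context$test_onset
  cond <- if (is.null(context)) NULL else .check_stim(context$stimulus)
  window <- c(onset + 1e-9, onset + 3)
  pk <- .pack_params(params)
  amps <- seq(lo, hi, by = (hi - lo) * step_frac)
  for (a in amps) {
    test <- stim_pulse(max(onset, 1e-9), duration, a)
    stim <- if (is.null(cond)) test else stim_sum(cond, test)
    if (.ap_in_window(params, rest, stim, window, opts, pk = pk)) return(a)
  }
  stop("inexcitable: no action potential in scan range")
}

#' Fit Weiss's law to a strength-duration curve
#'
#' Linear regression of stimulus charge `Q = I * t` on duration `t`:
#' the slope is the rheobase and the intercept/slope ratio the
#' strength-duration time constant (SDTC).
#'
#' @param durations stimulus durations, ms.
#' @param thresholds threshold currents, pA.
#' @return list with `rheobase` (pA), `sdtc` (ms) and `r_squared`.
#' @export
weiss_fit <- function(durations, thresholds) {
  stopifnot(length(durations) == length(thresholds), length(durations) >= 2)
  q <- thresholds * durations
  fit <- lm(q ~ durations)
  rheobase <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(rheobase = rheobase, sdtc = unname(coef(fit)[1]) / rheobase,
       r_squared = r2)
}

#' Strength-duration protocol
#'
#' Measures thresholds for rectangular stimuli of several durations and
#' reduces them by Weiss's law to rheobase and SDTC.
#'
#' @param params an `axon_params` object.
#' @param durations stimulus durations, ms.
#' @param rest optional pre-solved resting state.
#' @param opts solver settings.
#' @param rel_tol threshold bisection tolerance.
#' @param guess_env optional environment caching per-point threshold
#'   guesses across repeated protocol runs (used by the fitting layer).
#' @return list with `curve` (tibble duration_ms, threshold_pA), `rheobase`,
#'   `sdtc`, `r_squared`.
#' @export
run_strength_duration <- function(params, durations = DEFAULT_SD_DURATIONS,
                                  rest = NULL, opts = solver_opts(),
                                  rel_tol = 0.005, guess_env = NULL) {
  if (is.null(rest)) rest <- resting_state(params, opts)
  thr <- numeric(length(durations))
  guess <- NULL
  for (i in order(durations, decreasing = TRUE)) {
    key <- paste0("sd", durations[i])
    g <- if (!is.null(guess_env) && !is.null(guess_env[[key]]))
      guess_env[[key]] else guess
    thr[i] <- find_threshold(params, durations[i], rest = rest,
                             guess = g, check_spontaneous = (i == 1),
                             rel_tol = rel_tol, opts = opts)
    if (!is.null(guess_env)) guess_env[[key]] <- thr[i]
    guess <- thr[i] * 1.2
  }
  w <- weiss_fit(durations, thr)
  c(list(curve = tibble::tibble(duration_ms = durations,
                                threshold_pA = thr)), w)
}

#' Threshold electrotonus protocol
#'
#' 100 ms subthreshold conditioning currents at the given percentages of the
#' unconditioned 1-ms threshold; test thresholds at a lattice of delays from
#' conditioning onset.  Threshold reduction is
#' `100 * (T0 - T(delay)) / T0` (positive when the axon is more excitable).
#' `ted_10_20` is the mean reduction on the +40% curve over delays in
#' \[10, 20\] ms.
#'
#' @param params an `axon_params` object.
#' @param levels conditioning levels, % of unconditioned threshold.
#' @param delays test delays from conditioning onset, ms.
#' @param cond_ms conditioning duration, ms.
#' @inheritParams run_strength_duration
#' @param rest optional pre-solved resting state.
#' @param t0 optional pre-measured unconditioned threshold, pA.
#' @param opts solver settings.
#' @return list with `curves` (tibble series, delay_ms,
#'   threshold_reduction_pct), `ted_10_20` and `t0`.
#' @export
run_threshold_electrotonus <- function(params, levels = DEFAULT_TE_LEVELS,
                                       delays = DEFAULT_TE_DELAYS,
                                       cond_ms = 100, rest = NULL, t0 = NULL,
                                       opts = solver_opts(),
                                       rel_tol = 0.005, guess_env = NULL) {
  if (is.null(rest)) rest <- resting_state(params, opts)
  if (is.null(t0)) t0 <- find_threshold(params, 1, rest = rest,
                                        rel_tol = rel_tol, opts = opts)
  rows <- list()
  for (lev in levels) {
    cond <- stim_pulse(1e-9, cond_ms, lev / 100 * t0)
    guess <- t0
    red <- numeric(length(delays))
    for (j in seq_along(delays)) {
      key <- paste0("te", lev, "_", delays[j])
      g <- if (!is.null(guess_env) && !is.null(guess_env[[key]]))
        guess_env[[key]] else guess
      thr <- find_threshold(params, 1,
                            context = list(stimulus = cond,
                                           test_onset = delays[j]),
                            rest = rest, guess = g, rel_tol = rel_tol,
                            check_spontaneous = FALSE, opts = opts)
      if (!is.null(guess_env)) guess_env[[key]] <- thr
      red[j] <- 100 * (t0 - thr) / t0
      guess <- thr
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      series = sprintf("te_%+d", as.integer(lev)), delay_ms = delays,
      threshold_reduction_pct = red)
  }
  curves <- do.call(rbind, rows)
  dep <- curves[curves$series == "te_+40" &
                  curves$delay_ms >= 10 & curves$delay_ms <= 20, ]
  ted <- if (nrow(dep) > 0) mean(dep$threshold_reduction_pct) else NA_real_
  list(curves = curves, ted_10_20 = ted, t0 = t0)
}

#' Current-threshold (I/V) protocol
#'
#' 200 ms polarising currents from +50% to -100% of the unconditioned
#' threshold in 10% steps, with the test threshold measured at the end of
#' conditioning.  The resting I/V slope is the two-point slope of threshold
#' reduction against conditioning level between the -10% and +10% points.
#'
#' @inheritParams run_threshold_electrotonus
#' @param levels conditioning levels, % of unconditioned threshold.
#' @param cond_ms conditioning duration, ms.
#' @return list with `curve` (tibble conditioning_pct,
#'   threshold_reduction_pct), `resting_iv_slope` and `t0`.
#' @export
run_current_threshold <- function(params, levels = DEFAULT_IV_LEVELS,
                                  cond_ms = 200, rest = NULL, t0 = NULL,
                                  opts = solver_opts(), rel_tol = 0.005,
                                  guess_env = NULL) {
  if (is.null(rest)) rest <- resting_state(params, opts)
  if (is.null(t0)) t0 <- find_threshold(params, 1, rest = rest,
                                        rel_tol = rel_tol, opts = opts)
  levels <- sort(levels, decreasing = TRUE)
  red <- rep(NA_real_, length(levels))
  guess <- t0
  for (j in seq_along(levels)) {
    lev <- levels[j]
    # the polarizing current stays on through the test window so that the
    # threshold is measured at the end of conditioning, not after it: the
    # nodal time constant is far shorter than any conditioning effect
    cond <- stim_pulse(1e-9, cond_ms + 4, lev / 100 * t0)
    key <- paste0("iv", lev)
    g <- if (!is.null(guess_env) && !is.null(guess_env[[key]]))
      guess_env[[key]] else guess
    thr <- tryCatch(
      find_threshold(params, 1,
                     context = list(stimulus = cond, test_onset = cond_ms),
                     rest = rest, guess = g, rel_tol = rel_tol,
                     check_spontaneous = FALSE, opts = opts),
      error = function(e) {
        if (grepl("inexcitable", conditionMessage(e))) NA_real_ else stop(e)
      })
    if (!is.na(thr)) guess <- thr
    if (!is.null(guess_env) && !is.na(thr)) guess_env[[key]] <- thr
    red[j] <- if (is.na(thr)) NA_real_ else 100 * (t0 - thr) / t0
  }
  need <- c(10, -10)
  if (any(is.na(red[match(need, levels)])))
    stop("I/V protocol: threshold missing at a level needed for the slope")
  slope <- (red[match(10, levels)] - red[match(-10, levels)]) / 20
  list(curve = tibble::tibble(conditioning_pct = levels,
                              threshold_reduction_pct = red),
       resting_iv_slope = slope, t0 = t0)
}

#' Recovery cycle protocol
#'
#' A supramaximal (2x threshold, 1 ms) conditioning stimulus followed by
#' test stimuli at interstimulus intervals from 2.5 to 200 ms (onset to
#' onset).  Threshold change is `100 * (T(isi) - T0) / T0`.  The derived
#' indices are refractoriness at 2.5 ms, superexcitability at 5 ms
#' (reported as threshold *reduction*, positive = more excitable) and
#' subexcitability (largest late threshold increase over ISIs 10-100 ms,
#' floored at zero).
#'
#' @inheritParams run_threshold_electrotonus
#' @param isis interstimulus intervals, ms (minimum 2.5).
#' @param supra_factor conditioning amplitude as a multiple of threshold.
#' @return list with `curve` (tibble isi_ms, threshold_change_pct),
#'   `refractoriness_2p5`, `superexcitability_5`, `subexcitability`, `t0`.
#' @export
run_recovery_cycle <- function(params, isis = DEFAULT_RC_ISIS,
                               supra_factor = 2, rest = NULL, t0 = NULL,
                               rel_tol = 0.005, opts = solver_opts(),
                               guess_env = NULL) {
  if (any(isis < 2.5))
    stop("recovery-cycle ISIs below the 2.5 ms minimum")
  if (is.unsorted(isis, strictly = TRUE)) stop("ISIs must be increasing")
  if (is.null(rest)) rest <- resting_state(params, opts)
  if (is.null(t0)) t0 <- find_threshold(params, 1, rest = rest,
                                        rel_tol = rel_tol, opts = opts)
  cond <- stim_pulse(1e-9, 1, supra_factor * t0)
  if (!.ap_in_window(params, rest, cond, c(0, 3), opts))
    stop("recovery-cycle conditioning stimulus failed to elicit an action potential")
  chg <- numeric(length(isis))
  guess <- t0
  for (j in rev(seq_along(isis))) {  # long ISIs first: thresholds near T0
    key <- paste0("rc", isis[j])
    g <- if (!is.null(guess_env) && !is.null(guess_env[[key]]))
      guess_env[[key]] else guess
    thr <- find_threshold(params, 1,
                          context = list(stimulus = cond,
                                         test_onset = isis[j]),
                          rest = rest, guess = g, rel_tol = rel_tol,
                          check_spontaneous = FALSE, opts = opts)
    if (!is.null(guess_env)) guess_env[[key]] <- thr
    chg[j] <- 100 * (thr - t0) / t0
    guess <- thr
  }
  late <- chg[isis >= SUBEXC_WINDOW[1] & isis <= SUBEXC_WINDOW[2]]
  idx <- function(x) if (length(x) > 0) x else NA_real_
  list(curve = tibble::tibble(isi_ms = isis, threshold_change_pct = chg),
       refractoriness_2p5 = idx(chg[isis == 2.5]),
       superexcitability_5 = -idx(chg[isis == 5]),
       subexcitability = if (length(late) > 0) max(0, max(late))
                         else NA_real_,
       t0 = t0)
}

# ---- containers ---------------------------------------------------------

#' Excitability curves from the four threshold-tracking paradigms
#'
#' Bundles the per-paradigm curves into a validated container: `sd`
#' (duration_ms, threshold_pA), `te` (series, delay_ms,
#' threshold_reduction_pct), `iv` (conditioning_pct,
#' threshold_reduction_pct) and `rc` (isi_ms, threshold_change_pct).
#'
#' @param sd,te,iv,rc per-paradigm data frames as described above.
#' @return an object of class `excitability_curves`.
#' @export
excitability_curves <- function(sd, te, iv, rc) {
  sd <- tibble::as_tibble(sd); te <- tibble::as_tibble(te)
  iv <- tibble::as_tibble(iv); rc <- tibble::as_tibble(rc)
  stopifnot(all(c("duration_ms", "threshold_pA") %in% names(sd)),
            all(c("series", "delay_ms", "threshold_reduction_pct") %in%
                  names(te)),
            all(c("conditioning_pct", "threshold_reduction_pct") %in%
                  names(iv)),
            all(c("isi_ms", "threshold_change_pct") %in% names(rc)))
  if (is.unsorted(sd$duration_ms, strictly = TRUE))
    stop("strength-duration durations must be strictly increasing")
  for (s in unique(te$series))
    if (is.unsorted(te$delay_ms[te$series == s], strictly = TRUE))
      stop("threshold-electrotonus delays must be strictly increasing")
  if (is.unsorted(rc$isi_ms, strictly = TRUE))
    stop("recovery-cycle ISIs must be strictly increasing")
  if (any(rc$isi_ms < 2.5))
    warning("recovery-cycle ISIs below the 2.5 ms minimum interstimulus interval")
  structure(list(sd = sd, te = te, iv = iv, rc = rc),
            class = "excitability_curves")
}

#' Restrict excitability curves to a sub-lattice
#'
#' Returns the subset of a curve set lying on the given (coarser) lattices,
#' e.g. to rank scan candidates on a lean lattice of the same recording
#' that is later used densely.
#'
#' @param curves an `excitability_curves` object.
#' @param lattices named list as produced by [scan_lattices()].
#' @return an `excitability_curves` object.
#' @export
curves_subset <- function(curves, lattices) {
  te_series <- sprintf("te_%+d", as.integer(lattices$te_levels))
  suppressWarnings(excitability_curves(
    sd = curves$sd[curves$sd$duration_ms %in% lattices$sd_durations, ],
    te = curves$te[curves$te$series %in% te_series &
                     curves$te$delay_ms %in% lattices$te_delays, ],
    iv = curves$iv[curves$iv$conditioning_pct %in% lattices$iv_levels, ],
    rc = curves$rc[curves$rc$isi_ms %in% lattices$rc_isis, ]
  ))
}

#' @export
print.excitability_curves <- function(x, ...) {
  cat("<excitability_curves>\n")
  cat(sprintf("  sd: %d durations; te: %d series x %d delays; iv: %d levels; rc: %d ISIs\n",
              nrow(x$sd), length(unique(x$te$series)),
              length(unique(x$te$delay_ms)), nrow(x$iv), nrow(x$rc)))
  invisible(x)
}

#' Run all threshold-tracking paradigms
#'
#' @param params an `axon_params` object.
#' @param sd_durations,te_levels,te_delays,iv_levels,rc_isis protocol
#'   lattices (config-exposed defaults honour the protocol constraints:
#'   minimum recovery-cycle ISI 2.5 ms, 100 ms electrotonus and 200 ms
#'   current-threshold conditioning, recovery cycle spanning 200 ms).
#' @param opts solver settings.
#' @inheritParams run_strength_duration
#' @return an `excitability_curves` object; the scalar indices are attached
#'   as attribute `indices`.
#' @export
run_excitability_protocols <- function(params,
                                       sd_durations = DEFAULT_SD_DURATIONS,
                                       te_levels = DEFAULT_TE_LEVELS,
                                       te_delays = DEFAULT_TE_DELAYS,
                                       iv_levels = DEFAULT_IV_LEVELS,
                                       rc_isis = DEFAULT_RC_ISIS,
                                       opts = solver_opts(),
                                       rel_tol = 0.005, guess_env = NULL) {
  validate_axon_params(params)
  rest <- resting_state(params, opts)
  g0 <- if (!is.null(guess_env)) guess_env[["t0"]] else NULL
  t0 <- find_threshold(params, 1, rest = rest, guess = g0,
                       rel_tol = rel_tol, opts = opts)
  if (!is.null(guess_env)) guess_env[["t0"]] <- t0
  sd <- run_strength_duration(params, sd_durations, rest = rest,
                              opts = opts, rel_tol = rel_tol,
                              guess_env = guess_env)
  te <- run_threshold_electrotonus(params, te_levels, te_delays,
                                   rest = rest, t0 = t0, opts = opts,
                                   rel_tol = rel_tol, guess_env = guess_env)
  iv <- run_current_threshold(params, iv_levels, rest = rest, t0 = t0,
                              opts = opts, rel_tol = rel_tol,
                              guess_env = guess_env)
  rc <- run_recovery_cycle(params, rc_isis, rest = rest, t0 = t0,
                           opts = opts, guess_env = guess_env)
  curves <- excitability_curves(sd$curve, te$curves, iv$curve, rc$curve)
  attr(curves, "indices") <- c(
    ted_10_20 = te$ted_10_20, resting_iv_slope = iv$resting_iv_slope,
    refractoriness_2p5 = rc$refractoriness_2p5,
    superexcitability_5 = rc$superexcitability_5,
    subexcitability = rc$subexcitability, sdtc = sd$sdtc,
    rheobase = sd$rheobase, t0 = t0)
  curves
}

#' Scalar excitability indices of a model axon
#'
#' Computes the five recorded excitability indices (TEd 10-20 ms, resting
#' I/V slope, refractoriness at 2.5 ms, superexcitability at 5 ms,
#' subexcitability) and optionally SDTC/rheobase, evaluating only the
#' lattice points each index needs; this is the fast path used by the
#' calibration objective.
#'
#' @param params an `axon_params` object.
#' @param include_sd also run the strength-duration paradigm.
#' @param opts solver settings.
#' @param rel_tol threshold bisection tolerance.
#' @param guess_env optional threshold warm-start cache (see
#'   [run_strength_duration()]).
#' @return named numeric vector of indices.
#' @export
excitability_indices <- function(params, include_sd = FALSE,
                                 opts = solver_opts(), rel_tol = 0.005,
                                 guess_env = NULL) {
  validate_axon_params(params)
  rest <- resting_state(params, opts)
  g0 <- if (!is.null(guess_env)) guess_env[["t0"]] else NULL
  t0 <- find_threshold(params, 1, rest = rest, guess = g0,
                       rel_tol = rel_tol, opts = opts)
  if (!is.null(guess_env)) guess_env[["t0"]] <- t0
  te <- run_threshold_electrotonus(params, levels = 40,
                                   delays = c(10, 13, 16, 20),
                                   rest = rest, t0 = t0, opts = opts,
                                   rel_tol = rel_tol,
                                   guess_env = guess_env)
  iv <- run_current_threshold(params, levels = c(10, -10), rest = rest,
                              t0 = t0, opts = opts, rel_tol = rel_tol,
                              guess_env = guess_env)
  rc <- run_recovery_cycle(params,
                           isis = c(2.5, 5, 10, 13, 18, 24, 32, 43, 56, 75,
                                    100),
                           rest = rest, t0 = t0, rel_tol = rel_tol,
                           opts = opts, guess_env = guess_env)
  out <- c(ted_10_20 = te$ted_10_20, resting_iv_slope = iv$resting_iv_slope,
           refractoriness_2p5 = rc$refractoriness_2p5,
           superexcitability_5 = rc$superexcitability_5,
           subexcitability = rc$subexcitability, t0 = t0)
  if (include_sd) {
    sdp <- run_strength_duration(params, rest = rest, opts = opts)
    out <- c(out, sdtc = sdp$sdtc, rheobase = sdp$rheobase)
  }
  out
}
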