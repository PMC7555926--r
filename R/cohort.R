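# Seeded synthetic rat cohorts with the statistical structure the analysis
# assumes: two diet groups (chow control vs cafeteria-fed, CAF) matching the
# recorded group means/SEMs, a configurable correlation structure between
# superexcitability and the metabolic measures, glucose-tolerance curves,
# probit-governed von Frey up-down sequences and noisy "recorded"
# excitability curves generated from the axon model.

.default_field_stats <- function() {
  # chow / CAF group means and SEMs (n = 14 per group); fat and lean mass
  # and fasting insulin are not tabulated in the study and carry
  # representative values for 13-15 week Sprague-Dawley rats on these diets
  tibble::tibble(
    field = c("body_weight", "naso_anal_length", "fat_mass", "lean_mass",
              "rpWAT", "liver_weight", "FBG", "insulin", "leptin",
              "triglycerides", "HDL", "TNF_alpha", "IL6",
              "superexcitability", "SNAP"),
    chow_mean = c(548, 26.7, 70, 420, 4.0, 14.1, 5.0, 12, 2.1, 116, 58.23,
                  1418, 891.0, -0.65, 19.06),
    chow_sem = c(11, 0.3, 5, 8, 0.4, 0.4, 0.1, 1.5, 0.4, 7.3, 2.61, 115,
                 52.2, 0.68, 1.73),
    caf_mean = c(765, 28.2, 190, 480, 14.3, 18.9, 5.5, 35, 5.7, 157, 40.93,
                 2761, 1173.1, 2.14, 19.91),
    caf_sem = c(26, 0.2, 15, 12, 1.2, 0.7, 0.1, 4, 0.5, 9.5, 1.80, 563,
                143.4, 0.83, 2.64)
  )
}

.default_correlations <- function() {
  # pooled-cohort targets: superexcitability vs metabolic measures, plus
  # the strong interrelation of the adiposity measures
  rbind(
    data.frame(a = "superexcitability",
               b = c("fat_mass", "body_weight", "lean_mass", "HDL",
                     "leptin", "rpWAT"),
               r = c(0.497, 0.483, 0.469, -0.495, 0.484, 0.506)),
    data.frame(a = c("body_weight", "body_weight", "fat_mass", "fat_mass",
                     "fat_mass", "body_weight", "leptin", "leptin", "HDL"),
               b = c("fat_mass", "lean_mass", "lean_mass", "leptin",
                     "rpWAT", "rpWAT", "body_weight", "rpWAT", "fat_mass"),
               r = c(0.92, 0.90, 0.85, 0.65, 0.75, 0.72, 0.60, 0.55,
                     -0.40))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles everything the generator needs: group sizes, per-field group
#' means and SEMs (within-group SDs are reconstructed as
#' `SEM * sqrt(n_ref)`), the target pooled correlation structure, the
#' glucose-tolerance curve shape, the von Frey psychometric parameters and
#' the excitability noise level.
#'
#' @param n_per_group rats per diet group.
#' @param seed integer seed.
#' @param field_stats tibble of per-field group means/SEMs (see the
#'   default for the schema).
#' @param correlations data frame `a`, `b`, `r` of target pooled Pearson
#'   correlations.
#' @param n_ref group size underlying the printed SEMs.
#' @param gtt list: per-group baseline (mmol/L, the 13-week fasting
#'   glucose), peak amplitude `A` (mmol/L), `t_peak` (min) and `noise_sd`
#'   (mmol/L).
#' @param vonfrey list: per-group latent 50% threshold `theta_g` (g), its
#'   between-rat log10 SD, and the within-rat psychometric slope `sigma`
#'   (log10 g).
#' @param excitability_noise_sd multiplicative log-threshold noise, %.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 14, seed = 1,
                          field_stats = .default_field_stats(),
                          correlations = .default_correlations(),
                          n_ref = 14,
                          gtt = list(
                            baseline = c(chow = 4.8, caf = 5.4),
                            A = c(chow = 4.5, caf = 7.5),
                            t_peak = c(chow = 30, caf = 45),
                            noise_sd = 0.3),
                          vonfrey = list(
                            theta_g = c(chow = 3.0, caf = 4.0),
                            log10_sd = 0.18, sigma = 0.15),
                          excitability_noise_sd = 1) {
  stopifnot(n_per_group >= 0, n_ref > 1,
            all(c("field", "chow_mean", "chow_sem", "caf_mean", "caf_sem")
                %in% names(field_stats)),
            all(field_stats$chow_sem > 0), all(field_stats$caf_sem > 0))
  structure(list(n_per_group = n_per_group, seed = seed,
                 field_stats = field_stats, correlations = correlations,
                 n_ref = n_ref, gtt = gtt, vonfrey = vonfrey,
                 excitability_noise_sd = excitability_noise_sd),
            class = "cohort_config")
}

# Pooled target correlation -> common within-group correlation.  For two
# equal groups with means mu_g +/- d/2 and within-group SDs sx, sy, the
# pooled covariance is cov_w + dx*dy/4 and the pooled variance
# sx^2 + dx^2/4, so the within-group correlation that realises a pooled
# target r_t is
#   r_w = (r_t * sqrt((sx^2+dx^2/4)(sy^2+dy^2/4)) - dx*dy/4) / (sx*sy).
.within_group_corr <- function(cfg) {
  fs <- cfg$field_stats
  k <- nrow(fs)
  sx <- (fs$chow_sem + fs$caf_sem) / 2 * sqrt(cfg$n_ref)
  dx <- fs$caf_mean - fs$chow_mean
  R <- diag(k)
  rownames(R) <- colnames(R) <- fs$field
  for (i in seq_len(nrow(cfg$correlations))) {
    a <- cfg$correlations$a[i]; b <- cfg$correlations$b[i]
    rt <- cfg$correlations$r[i]
    ia <- match(a, fs$field); ib <- match(b, fs$field)
    if (is.na(ia) || is.na(ib))
      stop("correlation target references unknown field: ", a, " / ", b)
    num <- rt * sqrt((sx[ia]^2 + dx[ia]^2 / 4) * (sx[ib]^2 + dx[ib]^2 / 4)) -
      dx[ia] * dx[ib] / 4
    rw <- num / (sx[ia] * sx[ib])
    rw <- min(max(rw, -0.95), 0.95)
    R[ia, ib] <- R[ib, ia] <- rw
  }
  R
}

# Nearest positive-semidefinite repair (logged via message when needed).
.repaired_corr <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(R)
  rep <- Matrix::nearPD(R, corr = TRUE, do2eigen = TRUE)
  message(sprintf(
    "correlation matrix repaired to nearest PSD (min eigenvalue %.3g, Frobenius change %.3g)",
    min(ev), norm(as.matrix(rep$mat) - R, "F")))
  as.matrix(rep$mat)
}

#' Generate a synthetic two-group rat cohort
#'
#' Draws correlated metabolic and electrophysiological fields per rat from
#' group-specific multivariate normals (Cholesky factor of the repaired
#' within-group correlation matrix), truncated at physiological floors,
#' then attaches a glucose-tolerance curve and a von Frey up-down response
#' sequence to each rat.  Deterministic for a given configuration seed.
#'
#' @param cfg a [cohort_config()].
#' @return tibble with one row per rat: `id`, `group`, the metabolic
#'   fields, derived `HOMA_IR`, `TyG`, `lee_index`, `gtt_auc` and
#'   `vonfrey_50pwt`, plus list-columns `gtt` and `vonfrey` carrying the
#'   raw curves and response sequences.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  fs <- cfg$field_stats
  if (cfg$n_per_group == 0) {
    out <- tibble::tibble(id = character(0), group = character(0))
    for (f in fs$field) out[[f]] <- numeric(0)
    return(out)
  }
  R <- .repaired_corr(.within_group_corr(cfg))
  L <- chol(R)
  rows <- list()
  for (grp in c("chow", "caf")) {
    mu <- if (grp == "chow") fs$chow_mean else fs$caf_mean
    sdv <- (if (grp == "chow") fs$chow_sem else fs$caf_sem) * sqrt(cfg$n_ref)
    Z <- matrix(rnorm(cfg$n_per_group * nrow(fs)), nrow = cfg$n_per_group)
    X <- Z %*% L
    X <- sweep(X, 2, sdv, `*`)
    X <- sweep(X, 2, mu, `+`)
    colnames(X) <- fs$field
    # physiological floors: masses, lengths, concentrations stay positive
    positive <- setdiff(fs$field, "superexcitability")
    for (f in positive) X[, f] <- pmax(X[, f], 0.02 * abs(mean(X[, f])))
    df <- tibble::as_tibble(as.data.frame(X))
    df$id <- sprintf("%s_%02d", grp, seq_len(cfg$n_per_group))
    df$group <- grp
    rows[[grp]] <- df
  }
  out <- rbind(rows$chow, rows$caf)
  out <- out[, c("id", "group", fs$field)]

  out$gtt <- lapply(seq_len(nrow(out)), function(i)
    generate_gtt(cfg, out$group[i]))
  out$vonfrey <- lapply(seq_len(nrow(out)), function(i) {
    theta <- 10^(log10(cfg$vonfrey$theta_g[[out$group[i]]]) +
                   rnorm(1, 0, cfg$vonfrey$log10_sd))
    generate_vonfrey_sequence(cfg, theta)
  })
  out$HOMA_IR <- homa_ir(out$insulin, out$FBG)
  out$TyG <- tyg_index(out$triglycerides, out$FBG * 18)
  out$lee_index <- lee_index(out$body_weight, out$naso_anal_length)
  out$gtt_auc <- vapply(out$gtt, function(g)
    gtt_auc(g$minute, g$glucose), numeric(1))
  out$vonfrey_50pwt <- vapply(out$vonfrey, vonfrey_50pwt, numeric(1))
  out
}

#' Generate one glucose-tolerance curve
#'
#' The excursion is a gamma-pulse on top of the fasting baseline:
#' `glucose(t) = baseline + A * (t/t_peak) * exp(1 - t/t_peak)`, evaluated
#' on the study's sampling lattice \{0, 15, 30, 45, 60, 90, 120, 180\} min,
#' with seeded Gaussian noise added at the post-baseline points.
#'
#' @param cfg a [cohort_config()].
#' @param group `"chow"` or `"caf"`.
#' @param baseline optional fasting glucose override, mmol/L.
#' @return tibble with columns `minute` and `glucose` (mmol/L).
#' @export
generate_gtt <- function(cfg, group, baseline = NULL) {
  g <- cfg$gtt
  b <- if (is.null(baseline)) g$baseline[[group]] else baseline
  A <- g$A[[group]]
  tp <- g$t_peak[[group]]
  minutes <- c(0, 15, 30, 45, 60, 90, 120, 180)
  glucose <- b + A * (minutes / tp) * exp(1 - minutes / tp)
  noise <- c(0, rnorm(length(minutes) - 1, 0, g$noise_sd))
  tibble::tibble(minute = minutes, glucose = pmax(glucose + noise, 0.5))
}

#' Generate one von Frey up-down response sequence
#'
#' Responses are drawn from the probit psychometric function
#' `P(positive | force f) = Phi((log10 f - log10 theta) / sigma)` and the
#' presentation order follows the up-down rule: start at 2 g, move one
#' filament lighter after a positive response and one heavier after a
#' negative one, stopping after four responses beyond the first change or
#' at the edge of the set.
#'
#' @param cfg a [cohort_config()].
#' @param theta the rat's latent 50% threshold, g.
#' @param filaments filament set, g.
#' @return tibble with columns `filament_g` and `response` (`"+"`/`"-"`).
#' @export
generate_vonfrey_sequence <- function(cfg, theta,
                                      filaments = vf_filament_set()) {
  sigma <- cfg$vonfrey$sigma
  nf <- length(filaments)
  idx <- match(VF_START_G, filaments)
  fil <- integer(0)
  resp <- logical(0)
  repeat {
    pr <- pnorm((log10(filaments[idx]) - log10(theta)) / max(sigma, 1e-9))
    r <- runif(1) < pr
    fil <- c(fil, idx)
    resp <- c(resp, r)
    changed <- any(resp != resp[1])
    post <- if (changed) length(resp) - match(TRUE, resp != resp[1]) + 1
            else 0
    nxt <- idx + if (r) -1L else 1L
    if ((changed && post >= 5) || nxt < 1 || nxt > nf) break
    idx <- nxt
  }
  tibble::tibble(filament_g = filaments[fil],
                 response = ifelse(resp, "+", "-"))
}

#' Generate noisy "recorded" excitability curves from the axon model
#'
#' Runs all threshold-tracking paradigms on `params` and perturbs every
#' measured threshold (including the unconditioned control threshold)
#' multiplicatively by `exp(eps)`, `eps ~ N(0, noise_sd/100)`; percentage
#' curves are recomputed from the noisy thresholds.  This is the synthetic
#' stand-in for recorded group-mean data in fitting tests.
#'
#' @param params an `axon_params` object.
#' @param noise_sd log-threshold noise SD, %.
#' @param seed integer seed.
#' @param ... protocol lattice overrides passed to
#'   [run_excitability_protocols()].
#' @param rel_tol threshold bisection tolerance of the simulated
#'   recording; finer than the interactive default so that quantisation
#'   stays well below the recording noise.
#' @param opts solver settings.
#' @return an `excitability_curves` object.
#' @export
generate_recorded_excitability <- function(params, noise_sd = 1, seed = 1,
                                           ..., rel_tol = 0.0025,
                                           opts = solver_opts()) {
  curves <- run_excitability_protocols(params, ..., rel_tol = rel_tol,
                                       opts = opts)
  if (noise_sd == 0) return(curves)
  set.seed(seed)
  s <- noise_sd / 100
  jit <- function() exp(rnorm(1, 0, s))
  t0 <- attr(curves, "indices")[["t0"]]
  t0n <- t0 * jit()
  sd_c <- curves$sd
  sd_c$threshold_pA <- sd_c$threshold_pA *
    exp(rnorm(nrow(sd_c), 0, s))
  redo_red <- function(red) {
    thr <- t0 * (1 - red / 100) * exp(rnorm(length(red), 0, s))
    100 * (t0n - thr) / t0n
  }
  te <- curves$te
  te$threshold_reduction_pct <- redo_red(te$threshold_reduction_pct)
  iv <- curves$iv
  iv$threshold_reduction_pct <- redo_red(iv$threshold_reduction_pct)
  rc <- curves$rc
  thr_rc <- t0 * (1 + rc$threshold_change_pct / 100) *
    exp(rnorm(nrow(rc), 0, s))
  rc$threshold_change_pct <- 100 * (thr_rc - t0n) / t0n
  excitability_curves(sd_c, te, iv, rc)
}
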