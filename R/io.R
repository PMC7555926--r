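# File interchange: excitability-curve CSV schema and cohort CSVs.
#
# Excitability curves are written as one CSV per paradigm with the header
# `paradigm,series,x_ms_or_pct,threshold_change_pct` (the strength-duration
# file carries absolute thresholds in a `threshold_pA` column instead).
# Values round-trip exactly.

.curve_schema <- list(
  sd = c("paradigm", "series", "x_ms_or_pct", "threshold_pA"),
  te = c("paradigm", "series", "x_ms_or_pct", "threshold_change_pct"),
  iv = c("paradigm", "series", "x_ms_or_pct", "threshold_change_pct"),
  rc = c("paradigm", "series", "x_ms_or_pct", "threshold_change_pct")
)

#' Write excitability curves to CSV files
#'
#' Writes `sd.csv`, `te.csv`, `iv.csv` and `rc.csv` into `dir` using the
#' versioned curve schema; numbers are serialised so that a read/write
#' round-trip reproduces them exactly.
#'
#' @param curves an `excitability_curves` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_excitability_csv <- function(curves, dir) {
  stopifnot(inherits(curves, "excitability_curves"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- function(x) formatC(x, digits = 17, format = "g")
  wr <- function(df, path) {
    lines <- c(paste(names(df), collapse = ","),
               apply(df, 1, function(r) paste(r, collapse = ",")))
    writeLines(lines, path)
  }
  sd_df <- data.frame(paradigm = "sd", series = "sd",
                      x_ms_or_pct = num(curves$sd$duration_ms),
                      threshold_pA = num(curves$sd$threshold_pA))
  wr(sd_df, file.path(dir, "sd.csv"))
  te_df <- data.frame(paradigm = "te", series = curves$te$series,
                      x_ms_or_pct = num(curves$te$delay_ms),
                      threshold_change_pct =
                        num(curves$te$threshold_reduction_pct))
  wr(te_df, file.path(dir, "te.csv"))
  iv_df <- data.frame(paradigm = "iv", series = "iv",
                      x_ms_or_pct = num(curves$iv$conditioning_pct),
                      threshold_change_pct =
                        num(curves$iv$threshold_reduction_pct))
  wr(iv_df, file.path(dir, "iv.csv"))
  rc_df <- data.frame(paradigm = "rc", series = "rc",
                      x_ms_or_pct = num(curves$rc$isi_ms),
                      threshold_change_pct =
                        num(curves$rc$threshold_change_pct))
  wr(rc_df, file.path(dir, "rc.csv"))
  invisible(dir)
}

.read_curve_file <- function(path, paradigm) {
  if (!file.exists(path))
    stop("missing excitability file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- .curve_schema[[paradigm]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  for (col in setdiff(need, c("paradigm", "series"))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value in column %s at line %d",
                   basename(path), col, bad[1] + 1))
    df[[col]] <- v
  }
  df
}

#' Read excitability curves from CSV files
#'
#' Counterpart of [write_excitability_csv()].  Schema violations are
#' reported with the offending file, column and line; recovery-cycle ISIs
#' below the 2.5 ms minimum interstimulus interval raise a validation
#' warning.
#'
#' @param dir directory containing `sd.csv`, `te.csv`, `iv.csv`, `rc.csv`.
#' @return an `excitability_curves` object.
#' @export
read_excitability_csv <- function(dir) {
  sd_df <- .read_curve_file(file.path(dir, "sd.csv"), "sd")
  te_df <- .read_curve_file(file.path(dir, "te.csv"), "te")
  iv_df <- .read_curve_file(file.path(dir, "iv.csv"), "iv")
  rc_df <- .read_curve_file(file.path(dir, "rc.csv"), "rc")
  excitability_curves(
    sd = tibble::tibble(duration_ms = sd_df$x_ms_or_pct,
                        threshold_pA = sd_df$threshold_pA),
    te = tibble::tibble(series = te_df$series,
                        delay_ms = te_df$x_ms_or_pct,
                        threshold_reduction_pct =
                          te_df$threshold_change_pct),
    iv = tibble::tibble(conditioning_pct = iv_df$x_ms_or_pct,
                        threshold_reduction_pct =
                          iv_df$threshold_change_pct),
    rc = tibble::tibble(isi_ms = rc_df$x_ms_or_pct,
                        threshold_change_pct = rc_df$threshold_change_pct)
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `rats.csv` (one row per rat, scalar fields), `gtt.csv` and
#' `vonfrey.csv` (long format keyed by rat id) into `dir`.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scalar <- cohort[, !vapply(cohort, is.list, logical(1))]
  readr::write_csv(scalar, file.path(dir, "rats.csv"))
  gtt <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    g <- cohort$gtt[[i]]
    tibble::tibble(id = cohort$id[i], minute = g$minute,
                   glucose = g$glucose)
  }))
  readr::write_csv(gtt, file.path(dir, "gtt.csv"))
  vf <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    v <- cohort$vonfrey[[i]]
    tibble::tibble(id = cohort$id[i], presentation = seq_len(nrow(v)),
                   filament_g = v$filament_g, response = v$response)
  }))
  readr::write_csv(vf, file.path(dir, "vonfrey.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir directory containing `rats.csv`, `gtt.csv`, `vonfrey.csv`.
#' @return tibble with the same structure as [generate_cohort()] output.
#' @export
read_cohort_csv <- function(dir) {
  rats <- readr::read_csv(file.path(dir, "rats.csv"),
                          show_col_types = FALSE)
  gtt <- readr::read_csv(file.path(dir, "gtt.csv"), show_col_types = FALSE)
  vf <- readr::read_csv(file.path(dir, "vonfrey.csv"),
                        show_col_types = FALSE)
  rats$gtt <- lapply(rats$id, function(i)
    tibble::as_tibble(gtt[gtt$id == i, c("minute", "glucose")]))
  rats$vonfrey <- lapply(rats$id, function(i) {
    v <- vf[vf$id == i, ]
    v <- v[order(v$presentation), ]
    tibble::tibble(filament_g = v$filament_g, response = v$response)
  })
  rats
}

#' Assemble and persist a run configuration
#'
#' Collects everything that determines a pipeline run — solver settings,
#' protocol lattices, discrepancy weights, seeds and file paths — so the
#' resolved configuration can be written next to the outputs for
#' provenance.  `write_run_config()` adds the package version.
#'
#' @param paths named list of input/output paths.
#' @param opts solver settings from [solver_opts()].
#' @param lattices named list of protocol lattices.
#' @param weights discrepancy weights.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(paths = list(), opts = solver_opts(),
                       lattices = list(sd_durations = DEFAULT_SD_DURATIONS,
                                       te_levels = DEFAULT_TE_LEVELS,
                                       te_delays = DEFAULT_TE_DELAYS,
                                       iv_levels = DEFAULT_IV_LEVELS,
                                       rc_isis = DEFAULT_RC_ISIS),
                       weights = discrepancy_weights(), seed = 1) {
  structure(list(paths = paths, opts = opts, lattices = lattices,
                 weights = weights, seed = seed), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$package_version <- as.character(utils::packageVersion("axotrace"))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(paths = y$paths, opts = do.call(solver_opts, y$opts),
                    lattices = y$lattices,
                    weights = do.call(discrepancy_weights, y$weights),
                    seed = y$seed)
  attr(cfg, "package_version") <- y$package_version
  cfg
}
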