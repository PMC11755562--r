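#' Assay configuration for the simulated digestion readout
#'
#' Kinetic, sampling and noise parameters of the synthetic fluorescence
#' readout.  Defaults mirror the study conditions: hourly sampling to 5 h,
#' scoring at the 3 h reference time where the no-peptide control has
#' reached its plateau (k0 = 1 per hour gives >= 95 percent saturation at
#' 3 h), three replicates per condition, and the x5-x500 molar-equivalence
#' dose ladder.
#'
#' @param f_max saturation fluorescence (arbitrary units).
#' @param k0 control digestion rate constant (per hour).
#' @param times sampling times (hours).
#' @param ref_time reference time for scoring (hours; must be in `times`).
#' @param n_rep replicates per condition.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   noise.
#' @param doses molar-equivalence levels for dose-response runs.
#' @param default_dose single-dose panel concentration (molar equivalents;
#'   the study standard is 500).
#' @param seed RNG seed.
#' @return A list of class `pia_assay_config`.
#' @export
assay_config <- function(f_max = 100, k0 = 1.0, times = 0:5, ref_time = 3,
                         n_rep = 3L, noise_cv = 0.05,
                         doses = c(5, 50, 150, 500), default_dose = 500,
                         seed = 1L) {
  stopifnot(f_max > 0, k0 > 0, n_rep >= 1L, noise_cv >= 0,
            ref_time %in% times, all(doses > 0))
  structure(list(f_max = f_max, k0 = k0, times = times, ref_time = ref_time,
                 n_rep = as.integer(n_rep), noise_cv = noise_cv,
                 doses = doses, default_dose = default_dose,
                 seed = as.integer(seed)),
            class = "pia_assay_config")
}

#' Per-peptide inhibitory effect parameters
#'
#' The simulator treats a blocking peptide as a competitive modifier of the
#' digestion rate: at dose d (molar equivalents) the rate constant is
#' k0 / (1 + d / d50), so d50 is the dose at which the rate halves.  The
#' saturation level is unchanged by default (`plateau_shift = 1`), matching
#' the observed behaviour of delayed catalysis with an unchanged plateau; a
#' `plateau_shift` of 0 marks a peptide whose product band is not measurable
#' at all (the nuclease-induction phenotype).
#'
#' @param peptide_id identifier.
#' @param d50 dose halving the rate constant (molar equivalents, > 0).
#' @param plateau_shift multiplier on `f_max` in \[0, 1\].
#' @return A one-row data.frame.
#' @export
peptide_effect <- function(peptide_id, d50, plateau_shift = 1) {
  stopifnot(d50 > 0, plateau_shift >= 0, plateau_shift <= 1)
  data.frame(peptide_id = as.character(peptide_id), d50 = d50,
             plateau_shift = plateau_shift)
}

#' Expected (noise-free) fluorescence time course
#'
#' F(t) = f_max * plateau_shift * (1 - exp(-k_eff t)) with
#' k_eff = k0 / (1 + dose / d50).  F(0) = 0, F is non-decreasing, and for
#' `plateau_shift = 1` the asymptote is dose-independent.
#'
#' @param effect a [peptide_effect()] row (ignored when `dose = 0`).
#' @param dose molar equivalents (>= 0; 0 gives the control curve).
#' @param config an [assay_config()].
#' @param times evaluation times (defaults to `config$times`).
#' @return Numeric vector of expected fluorescence values.
#' @export
expected_curve <- function(effect, dose, config, times = config$times) {
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (dose == 0) {
    k <- config$k0
    shift <- 1
  } else {
    k <- config$k0 / (1 + dose / effect$d50)
    shift <- effect$plateau_shift
  }
  config$f_max * shift * (1 - exp(-k * times))
}

simulate_measurements <- function(grid, config) {
  n <- nrow(grid)
  eps <- stats::rnorm(n, 0, config$noise_cv)
  grid$fluorescence_au <- pmax(0, grid$expected * (1 + eps))
  grid$expected <- NULL
  grid
}

#' Simulate a full-panel assay at a single dose
#'
#' For every peptide effect, every sampling time and every replicate (plus
#' the shared no-peptide control) draws fluorescence = expected value *
#' (1 + eps), eps ~ Normal(0, noise_cv), clamped at zero.  Fully
#' reproducible from `config$seed`.
#'
#' @param effects data.frame of [peptide_effect()] rows.
#' @param config an [assay_config()].
#' @param dose molar equivalents applied to every peptide (default
#'   `config$default_dose`).
#' @return data.frame with columns `peptide_id` ("no_peptide" for the
#'   control), `dose`, `time_h`, `replicate`, `fluorescence_au`.
#' @export
simulate_panel <- function(effects, config, dose = config$default_dose) {
  stopifnot(nrow(effects) >= 1L)
  rows <- list(expand.grid(peptide_id = "no_peptide", dose = 0,
                           time_h = config$times,
                           replicate = seq_len(config$n_rep),
                           stringsAsFactors = FALSE))
  rows[[1]]$expected <- rep(expected_curve(NULL, 0, config),
                            times = config$n_rep)
  for (i in seq_len(nrow(effects))) {
    g <- expand.grid(peptide_id = effects$peptide_id[i], dose = dose,
                     time_h = config$times,
                     replicate = seq_len(config$n_rep),
                     stringsAsFactors = FALSE)
    g$expected <- rep(expected_curve(effects[i, ], dose, config),
                      times = config$n_rep)
    rows[[i + 1L]] <- g
  }
  grid <- do.call(rbind, rows)
  with_seed(config$seed, simulate_measurements(grid, config))
}

#' Simulate a dose-response series for one peptide
#'
#' Measurements at the reference time across `config$doses` plus the
#' no-peptide control; with `noise_cv = 0` the implied relative intensity
#' decreases strictly with dose.
#'
#' @param effect a [peptide_effect()] row.
#' @param config an [assay_config()].
#' @return data.frame in the [simulate_panel()] format.
#' @export
simulate_dose_response <- function(effect, config) {
  grids <- list(expand.grid(peptide_id = "no_peptide", dose = 0,
                            time_h = config$ref_time,
                            replicate = seq_len(config$n_rep),
                            stringsAsFactors = FALSE))
  grids[[1]]$expected <- config$f_max * (1 - exp(-config$k0 * config$ref_time))
  for (d in config$doses) {
    g <- expand.grid(peptide_id = effect$peptide_id, dose = d,
                     time_h = config$ref_time,
                     replicate = seq_len(config$n_rep),
                     stringsAsFactors = FALSE)
    g$expected <- expected_curve(effect, d, config, times = config$ref_time)
    grids[[length(grids) + 1L]] <- g
  }
  grid <- do.call(rbind, grids)
  with_seed(config$seed, simulate_measurements(grid, config))
}

#' Write / read measurement tables as TSV
#'
#' Columns peptide_id, dose, time_h, replicate, fluorescence_au; `#` lines
#' are provenance comments.
#'
#' @param measurements data.frame in the [simulate_panel()] format.
#' @param path file path.
#' @param provenance_header optional `#` comment lines.
#' @return `path` invisibly (write); data.frame (read).
#' @export
write_measurements <- function(measurements, path, provenance_header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance_header))
    writeLines(paste0("# ", provenance_header), con)
  utils::write.table(measurements, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop("measurement file not found: ", path, call. = FALSE)
  need <- c("peptide_id", "dose", "time_h", "replicate", "fluorescence_au")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(need %in% names(df)))
    stop("measurement file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}
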