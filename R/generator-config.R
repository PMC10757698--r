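#' Default configuration of the synthetic EOD experiment generator
#'
#' Returns the full set of generator defaults as a nested list. The defaults
#' emulate the assay's study conditions: 8 fish with baseline EOD frequencies
#' drawn from 650--1000 Hz, a 30-min baseline / 5-min immersion / 180-min
#' post-treatment timeline, anesthetic concentrations of 0 (control), 30, 45
#' and 60 uL/L, dose-dependent frequency drops whose post-treatment recovery
#' follows the four-parameter recovery model (see
#' [evaluate_recovery_model()]), Poisson chirp trains with sech-shaped
#' frequency excursions, and amplitude-collapse episodes at the highest dose.
#'
#' Components:
#' \describe{
#'   \item{n_fish, f0_range_hz, concentrations_ul_l}{experimental design:
#'     number of fish, the uniform range their baseline frequency f0 is drawn
#'     from (once per fish, reused across conditions), and the treatment set.}
#'   \item{phases}{durations in seconds of the baseline, treatment and
#'     post-treatment phases (1800 / 300 / 10800).}
#'   \item{drop_latency_s}{delay after immersion before the frequency starts
#'     to fall (60 s; the fish begin lowering the frequency within 1--2 min of
#'     exposure).}
#'   \item{recovery}{per-concentration recovery-model parameters `a` (floor,
#'     dimensionless), `b` (min), `c` (asymptote, dimensionless), `d` (1/min)
#'     used both for the in-treatment decline target (`a * f0`) and the
#'     post-treatment trajectory `f0 * F(t)`.}
#'   \item{fish_effect_sd}{between-fish standard deviation of the drop floor
#'     `a` (dimensionless, default 0.02), reproducing the scatter of
#'     individual fish around the pooled recovery curve.}
#'   \item{jitter}{slow baseline wander: mean-reverting Gaussian random walk
#'     with stationary sd `sd_rel * f0` (default 0.0035, i.e. 0.35% of f0) and
#'     e-folding time `tau_s` (45 s), realized on a `dt_s` (1 s) grid. The
#'     default is calibrated so the coefficient of variation of the 59
#'     baseline median frequencies falls within 0.12--0.59%.}
#'   \item{chirps}{Poisson chirp rates (events/min) before
#'     (`rate_pre_per_min`, 0.05) and during the 30-min window after treatment
#'     (`rate_post_per_min`, 4 for treated fish), and the sampling ranges of
#'     peak rise (Hz), shape parameter alpha (1/s) and relative amplitude dip.}
#'   \item{amplitude}{baseline peak amplitude, multiplicative movement-jitter
#'     model, and the collapse model for 60 uL/L: probability 0.5 per fish,
#'     onset 210 s after immersion with a 30-s sigmoidal drop to a 10% floor,
#'     linear recovery over 360 s after return to the home tank.}
#'   \item{temperature}{water temperature samples: mean (26 C), slow drift sd,
#'     and 600-s cadence.}
#'   \item{waveform}{carrier synthesis: sampling rate (40 kHz), harmonic
#'     weights (1, 0.3, 0.1), harmonic phases (rad), additive Gaussian noise
#'     sd relative to unit amplitude (0.05).}
#'   \item{render_waveforms}{if `TRUE`, [generate_experiment()] renders raw
#'     voltage traces for every recording (memory- and time-intensive at full
#'     timeline length); if `FALSE` only ground-truth profiles are kept.}
#' }
#'
#' @return A named list of generator settings.
#' @export
#' @examples
#' cfg <- default_generator_config()
#' cfg$n_fish
default_generator_config <- function() {
  list(
    n_fish = 8L,
    f0_range_hz = c(650, 1000),
    concentrations_ul_l = c(0, 30, 45, 60),
    phases = list(baseline_s = 1800, treatment_s = 300, post_s = 10800),
    drop_latency_s = 60,
    recovery = list(
      `0`  = list(a = 1,      b = 1,      c = 1,      d = 0),
      `30` = list(a = 0.7465, b = 1.4568, c = 1.0089, d = -3.2299e-5),
      `45` = list(a = 0.6344, b = 1.4064, c = 1.0084, d = -3.3821e-5),
      `60` = list(a = 0.5649, b = 1.5816, c = 1.0131, d = -6.2321e-5)
    ),
    fish_effect_sd = 0.02,
    jitter = list(sd_rel = 0.0035, tau_s = 45, dt_s = 1),
    chirps = list(
      rate_pre_per_min = 0.05,
      rate_post_per_min = 4,
      post_window_s = 1800,
      delta_f_range_hz = c(30, 150),
      alpha_range_per_s = c(200, 1500),
      amp_dip_range = c(0.1, 0.6)
    ),
    amplitude = list(
      base = 1,
      jitter_sd = 0.1,
      jitter_tau_s = 10,
      collapse = list(prob_60 = 0.5, onset_s = 210, onset_ramp_s = 30,
                      floor = 0.1, recovery_s = 360)
    ),
    temperature = list(mean_c = 26, drift_sd_c = 0, cadence_s = 600),
    waveform = list(sample_rate_hz = 40000, harmonics = c(1, 0.3, 0.1),
                    harmonic_phases_rad = c(0, 0, 0), noise_sd = 0.05),
    render_waveforms = FALSE
  )
}

#' Merge user overrides into the default generator configuration
#'
#' Recursively replaces entries of [default_generator_config()] with the
#' values supplied in `overrides` (a nested list with the same names).
#'
#' @param overrides nested list of settings to replace.
#' @return the merged configuration list.
#' @export
generator_config <- function(overrides = list()) {
  merge_lists(default_generator_config(), overrides)
}

#' @noRd
merge_lists <- function(base, overrides) {
  if (!is.list(overrides)) return(overrides)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a generator configuration from a YAML or JSON document
#'
#' Loads a nested override document (same structure as
#' [default_generator_config()]) and merges it over the defaults. Format is
#' chosen by extension: `.json` via jsonlite, anything else via yaml (the
#' `yaml` package must be installed for YAML input).
#'
#' @param path path to the configuration document.
#' @return the merged configuration list.
#' @export
read_generator_config <- function(path) {
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      eod_stop("reading YAML configuration requires the 'yaml' package",
               "eod_bad_config")
    yaml::read_yaml(path)
  }
  generator_config(overrides)
}
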