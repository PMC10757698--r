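# Full multi-fish, multi-treatment synthetic experiments.

#' Generate a complete synthetic anesthesia experiment
#'
#' Emulates the assay's randomized complete block design: each of `n_fish`
#' fish receives every treatment condition once (random order per fish, one
#' recording per fish-condition pair, 8 x 4 = 32 recordings by default). The
#' baseline frequency `f0` of a fish is drawn once and reused across its four
#' conditions. Every recording carries complete ground truth: the frequency
#' profile, the chirp event log, and the amplitude profile including any
#' collapse episode (drawn with probability `prob_60` at 60 uL/L).
#'
#' Regeneration with the same `(config, seed)` is bit-identical. The caller's
#' RNG state is left untouched.
#'
#' @param config generator configuration (see [default_generator_config()]).
#' @param seed integer seed governing every random draw.
#' @return Object of class `eod_experiment`: list with `config`, `seed`,
#'   `fish` (data.frame: `fish`, `f0_hz`), `design` (data.frame: `fish`,
#'   `concentration_ul_l`, `day`), and `recordings`, a list keyed
#'   `"fish<j>_c<conc>"` whose entries hold `fish`, `concentration_ul_l`,
#'   `day`, `profile`, `chirps`, `amplitude`, `temperature` (data.frame),
#'   and `recording` (rendered waveform, or `NULL` unless
#'   `config$render_waveforms` is `TRUE`).
#' @export
#' @examples
#' cfg <- generator_config(list(n_fish = 2, concentrations_ul_l = c(0, 60),
#'                              phases = list(baseline_s = 120,
#'                                            treatment_s = 60, post_s = 300)))
#' exp <- generate_experiment(cfg, seed = 1)
#' names(exp$recordings)
generate_experiment <- function(config = default_generator_config(), seed) {
  if (missing(seed)) eod_stop("a seed is mandatory", "eod_bad_config")
  n_fish <- config$n_fish
  concs <- config$concentrations_ul_l
  if (n_fish < 1) eod_stop("n_fish must be >= 1", "eod_bad_config")

  with_seed(seed, {
    f0 <- runif(n_fish, config$f0_range_hz[1], config$f0_range_hz[2])
    fish_tbl <- data.frame(fish = seq_len(n_fish), f0_hz = f0)

    # randomized complete block design: each fish is a block, the order of
    # the conditions within the block is a random permutation
    design <- do.call(rbind, lapply(seq_len(n_fish), function(j) {
      data.frame(fish = j, concentration_ul_l = sample(concs),
                 day = seq_along(concs))
    }))

    recordings <- list()
    for (row in seq_len(nrow(design))) {
      j <- design$fish[row]
      conc <- design$concentration_ul_l[row]
      fe <- if (conc > 0) rnorm(1, 0, config$fish_effect_sd) else 0
      prof <- make_frequency_profile(config, condition = conc,
                                     f0 = f0[j], fish_effect = fe)
      chirped <- insert_chirps(
        prof,
        rate_pre = config$chirps$rate_pre_per_min,
        rate_post = if (conc > 0) config$chirps$rate_post_per_min
                    else config$chirps$rate_pre_per_min,
        shape_ranges = config$chirps,
        post_window_s = config$chirps$post_window_s
      )
      prof <- chirped$profile
      collapse <- conc == max(concs) && conc > 0 &&
        runif(1) < config$amplitude$collapse$prob_60
      aprof <- make_amplitude_profile(config$amplitude, prof,
                                      collapse = collapse)
      temp <- data.frame(
        time_s = seq(0, prof$duration_s, by = config$temperature$cadence_s)
      )
      temp$temp_c <- config$temperature$mean_c +
        if (config$temperature$drift_sd_c > 0)
          cumsum(rnorm(nrow(temp), 0, config$temperature$drift_sd_c)) else 0

      rec <- NULL
      if (isTRUE(config$render_waveforms)) {
        rec <- synthesize_waveform(
          prof, aprof, config$waveform,
          metadata = list(fish = j, concentration_ul_l = conc,
                          temperature = temp)
        )
      }
      key <- sprintf("fish%d_c%s", j, format(conc))
      recordings[[key]] <- list(
        fish = j, concentration_ul_l = conc, day = design$day[row],
        profile = prof, chirps = chirped$chirps, amplitude = aprof,
        temperature = temp, recording = rec
      )
    }

    structure(list(config = config, seed = seed, fish = fish_tbl,
                   design = design, recordings = recordings),
              class = "eod_experiment")
  })
}

#' @exportS3Method base::print
print.eod_experiment <- function(x, ...) {
  cat(sprintf("<eod_experiment> %d fish x %d conditions = %d recordings (seed %s)\n",
              nrow(x$fish), length(x$config$concentrations_ul_l),
              length(x$recordings), format(x$seed)))
  invisible(x)
}

#' Median-frequency series computed directly from a ground-truth profile
#'
#' Evaluates the profile's instantaneous frequency on a fine grid and reduces
#' it exactly like the tracker's median stage: the median within 1-min
#' windows placed every 30 s. This gives the noise-free analogue of running
#' [track_frequency()] + [median_frequency_series()] on a rendered waveform,
#' and is what the full-timeline pipeline uses where rendering all 215-min
#' recordings would be pointless.
#'
#' @param profile an `eod_profile`.
#' @param start_s,end_s portion of the profile to summarize.
#' @param interval_s spacing of window starts (s).
#' @param window_s window length (s).
#' @param dt_s evaluation grid step (s).
#' @param align `"center"` stamps each value at the window center,
#'   `"right"` at the window end. With `"right"` the first window is
#'   truncated at `start_s` so that a value exists at every grid point
#'   `start_s + k * interval_s`, `k = 1, 2, ...`.
#' @return data.frame with `time_s` and `median_hz`.
#' @export
profile_median_series <- function(profile, start_s = 0,
                                  end_s = profile$duration_s,
                                  interval_s = 30, window_s = 60, dt_s = 0.25,
                                  align = c("center", "right")) {
  align <- match.arg(align)
  grid <- seq(start_s, end_s, by = dt_s)
  f <- profile_frequency(profile, grid)
  if (align == "center") {
    starts <- seq(start_s, end_s - window_s, by = interval_s)
    med <- vapply(starts, function(s) {
      stats::median(f[grid >= s & grid < s + window_s])
    }, numeric(1))
    data.frame(time_s = starts + window_s / 2, median_hz = med)
  } else {
    ends <- seq(start_s + interval_s, end_s, by = interval_s)
    med <- vapply(ends, function(e) {
      stats::median(f[grid >= max(start_s, e - window_s) & grid < e])
    }, numeric(1))
    data.frame(time_s = ends, median_hz = med)
  }
}
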