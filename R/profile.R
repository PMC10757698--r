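# Ground-truth frequency and amplitude profiles of a synthetic EOD recording.
#
# A profile is a deterministic object once created: all randomness (baseline
# wander, chirp times) is realized at construction time, so evaluating it at
# arbitrary times is reproducible and side-effect free.

#' Build the ground-truth EOD frequency profile of one recording
#'
#' Constructs the instantaneous-frequency trajectory for one fish under one
#' treatment condition: a stationary baseline around `f0` with slow
#' mean-reverting wander, a latency followed by a smooth decline toward
#' `a * f0` during the immersion phase, and a post-treatment recovery
#' following the four-parameter model `f0 * F(t)` (see
#' [evaluate_recovery_model()]; `t` in minutes from the return to the home
#' tank). The control condition (0 uL/L) has no drop.
#'
#' @param config generator configuration, see [default_generator_config()].
#' @param condition treatment concentration in uL/L; must name an entry of
#'   `config$recovery` (0, 30, 45, 60 by default).
#' @param f0 baseline EOD frequency in Hz; overrides any value in `config`.
#' @param fish_effect additive perturbation of the drop floor `a` for this
#'   fish (dimensionless); 0 for the pooled curve.
#' @param jitter logical; realize the baseline wander? Uses the current RNG
#'   stream. `FALSE` gives a noise-free deterministic profile.
#' @return An object of class `eod_profile` with fields `f0`, `condition`,
#'   `phases` (data.frame with `phase`, `start_s`, `end_s`), `recovery`
#'   (effective parameters), `duration_s`, the realized jitter path, and an
#'   (initially empty) chirp table. Evaluate it with [profile_frequency()].
#' @seealso [insert_chirps()], [synthesize_waveform()]
#' @export
make_frequency_profile <- function(config = default_generator_config(),
                                   condition = 0, f0 = 800,
                                   fish_effect = 0, jitter = TRUE) {
  if (!is.numeric(f0) || length(f0) != 1 || !is.finite(f0) || f0 <= 0)
    eod_stop("baseline frequency f0 must be a single positive number",
             "eod_bad_config")
  ph <- config$phases
  durs <- c(ph$baseline_s, ph$treatment_s, ph$post_s)
  if (any(!is.finite(unlist(durs))) || any(unlist(durs) < 0))
    eod_stop("phase durations must be non-negative", "eod_bad_config")
  key <- as.character(condition)
  if (!key %in% names(config$recovery))
    eod_stop(sprintf("no recovery parameters configured for condition '%s'", key),
             "eod_bad_config")
  rec <- config$recovery[[key]]
  if (condition > 0) {
    rec$a <- min(1, max(0.05, rec$a + fish_effect))
  }

  b0 <- ph$baseline_s
  t1 <- b0 + ph$treatment_s
  dur <- t1 + ph$post_s
  phases <- data.frame(
    phase = c("baseline", "treatment", "post"),
    start_s = c(0, b0, t1),
    end_s = c(b0, t1, dur),
    stringsAsFactors = FALSE
  )

  jit <- config$jitter
  path <- if (jitter && jit$sd_rel > 0) {
    ou_path(floor(dur / jit$dt_s) + 2L, jit$sd_rel * f0, jit$tau_s, jit$dt_s)
  } else {
    numeric(0)
  }

  structure(list(
    f0 = f0,
    condition = condition,
    phases = phases,
    duration_s = dur,
    recovery = rec,
    drop_latency_s = config$drop_latency_s,
    jitter = list(path = path, dt_s = jit$dt_s),
    chirps = empty_chirp_table()
  ), class = "eod_profile")
}

#' @noRd
empty_chirp_table <- function() {
  data.frame(time_s = numeric(0), delta_f_hz = numeric(0),
             alpha_per_s = numeric(0), amp_dip = numeric(0),
             support_s = numeric(0))
}

#' @exportS3Method base::print
print.eod_profile <- function(x, ...) {
  cat(sprintf("<eod_profile> f0 = %.1f Hz, condition = %s uL/L, %.1f min, %d chirps\n",
              x$f0, format(x$condition), x$duration_s / 60, nrow(x$chirps)))
  invisible(x)
}

#' Evaluate the instantaneous EOD frequency of a profile
#'
#' @param profile an `eod_profile`.
#' @param t times in seconds from the start of the recording (vectorized).
#' @param chirps include the chirp excursions? (default `TRUE`).
#' @return instantaneous frequency in Hz at each `t`.
#' @export
profile_frequency <- function(profile, t, chirps = TRUE) {
  f <- profile_base_frequency(profile, t)
  if (length(profile$jitter$path) > 0) {
    f <- f + interp_path(profile$jitter$path, profile$jitter$dt_s, t)
  }
  if (chirps && nrow(profile$chirps) > 0) {
    ch <- profile$chirps
    for (i in seq_len(nrow(ch))) {
      xi <- t - ch$time_s[i]
      in_support <- abs(xi) <= ch$support_s[i]
      if (any(in_support)) {
        f[in_support] <- f[in_support] +
          ch$delta_f_hz[i] * chirp_phi(xi[in_support], ch$alpha_per_s[i])
      }
    }
  }
  f
}

#' Deterministic (jitter- and chirp-free) part of the frequency profile
#' @noRd
profile_base_frequency <- function(profile, t) {
  ph <- profile$phases
  b0 <- ph$end_s[1]; t1 <- ph$end_s[2]
  f0 <- profile$f0
  rec <- profile$recovery
  f <- rep(f0, length(t))
  if (profile$condition > 0 && rec$a < 1) {
    # on compressed timelines the latency cannot swallow the whole
    # immersion phase; keep at least half of it for the decline
    lat <- min(profile$drop_latency_s, 0.5 * (t1 - b0))
    ramp_len <- max(1e-9, (t1 - b0) - lat)
    in_trt <- t >= b0 & t < t1
    if (any(in_trt)) {
      u <- (t[in_trt] - b0 - lat) / ramp_len
      f[in_trt] <- f0 * (1 - (1 - rec$a) * smoothstep(u))
    }
  }
  in_post <- t >= t1
  if (any(in_post)) {
    tp_min <- (t[in_post] - t1) / 60
    f[in_post] <- f0 * evaluate_recovery_model(rec, tp_min)
  }
  f
}

#' Insert Poisson chirp trains into a frequency profile
#'
#' Chirps are additive frequency excursions `delta_f * Phi(t - t_event;
#' alpha)` with the sech shape [chirp_phi()]. Event times follow a Poisson
#' process with rate `rate_pre` (events/min) during the baseline and
#' treatment phases and during the post-treatment remainder, and `rate_post`
#' during the first `post_window_s` seconds after the return to the home
#' tank. Each chirp's support is truncated where its shape falls below 1% of
#' the peak (|xi| = 5.3/alpha). Events whose supports would overlap are
#' redrawn; events still overlapping after `max_redraw` attempts are dropped
#' with a warning.
#'
#' @param profile an `eod_profile`.
#' @param rate_pre,rate_post event rates in chirps/min (>= 0).
#' @param shape_ranges list with `delta_f_range_hz`, `alpha_range_per_s`,
#'   `amp_dip_range`; defaults from [default_generator_config()].
#' @param post_window_s length of the boosted post-treatment window (s).
#' @param max_redraw redraw attempts per overlapping event.
#' @return list with elements `profile` (chirps attached) and `chirps`
#'   (the ground-truth event table: `time_s`, `delta_f_hz`, `alpha_per_s`,
#'   `amp_dip`, `support_s`).
#' @export
insert_chirps <- function(profile, rate_pre = 0.05, rate_post = 4,
                          shape_ranges = default_generator_config()$chirps,
                          post_window_s = shape_ranges$post_window_s,
                          max_redraw = 50) {
  if (rate_pre < 0 || rate_post < 0)
    eod_stop("chirp rates must be non-negative", "eod_bad_config")
  ph <- profile$phases
  t1 <- ph$end_s[2]
  post_win_end <- min(t1 + post_window_s, profile$duration_s)
  segments <- data.frame(
    start = c(0, t1, post_win_end),
    end = c(t1, post_win_end, profile$duration_s),
    rate = c(rate_pre, rate_post, rate_pre)
  )
  segments <- segments[segments$end > segments$start & segments$rate > 0, ]

  draw_event <- function(seg) {
    data.frame(
      time_s = runif(1, seg$start, seg$end),
      delta_f_hz = runif(1, shape_ranges$delta_f_range_hz[1],
                         shape_ranges$delta_f_range_hz[2]),
      alpha_per_s = runif(1, shape_ranges$alpha_range_per_s[1],
                          shape_ranges$alpha_range_per_s[2])
    )
  }

  events <- empty_chirp_table()
  for (s in seq_len(nrow(segments))) {
    seg <- segments[s, ]
    n <- rpois(1, seg$rate * (seg$end - seg$start) / 60)
    for (i in seq_len(n)) {
      ev <- draw_event(seg)
      ev$amp_dip <- runif(1, shape_ranges$amp_dip_range[1],
                          shape_ranges$amp_dip_range[2])
      ev$support_s <- 5.3 / ev$alpha_per_s
      tries <- 0
      while (overlaps_any(ev, events) && tries < max_redraw) {
        ev$time_s <- runif(1, seg$start, seg$end)
        tries <- tries + 1
      }
      if (overlaps_any(ev, events)) {
        warning("dropping a chirp that could not be placed without overlap")
      } else {
        events <- rbind(events, ev)
      }
    }
  }
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  profile$chirps <- events
  list(profile = profile, chirps = events)
}

#' @noRd
overlaps_any <- function(ev, events) {
  if (nrow(events) == 0) return(FALSE)
  any(abs(events$time_s - ev$time_s) < (events$support_s + ev$support_s))
}

#' Build the ground-truth amplitude profile of one recording
#'
#' Baseline peak amplitude with multiplicative log-normal movement jitter
#' (mean-reverting on a 1-s grid), optional suppression of that jitter while
#' the fish is anesthetized (movement ceases), and optional amplitude-collapse
#' episodes: a sigmoidal drop to `floor` times baseline starting `onset_s`
#' after immersion, held until the fish is returned, followed by a linear
#' recovery over `recovery_s`.
#'
#' @param config amplitude section of the generator configuration.
#' @param profile the matching `eod_profile` (provides phase boundaries).
#' @param collapse logical; insert a collapse episode?
#' @return object of class `eod_amplitude`; evaluate with [amplitude_value()].
#' @export
make_amplitude_profile <- function(config = default_generator_config()$amplitude,
                                   profile, collapse = FALSE) {
  ph <- profile$phases
  dur <- profile$duration_s
  path <- if (config$jitter_sd > 0) {
    ou_path(floor(dur) + 2L, config$jitter_sd, config$jitter_tau_s, 1)
  } else numeric(0)

  events <- data.frame(onset_s = numeric(0), ramp_s = numeric(0),
                       floor = numeric(0), hold_end_s = numeric(0),
                       recovery_s = numeric(0))
  if (collapse) {
    cl <- config$collapse
    events <- data.frame(onset_s = ph$start_s[2] + cl$onset_s,
                         ramp_s = cl$onset_ramp_s,
                         floor = cl$floor,
                         hold_end_s = ph$end_s[2],
                         recovery_s = cl$recovery_s)
  }
  structure(list(
    base = config$base,
    jitter = list(path = path, dt_s = 1),
    suppress_jitter = profile$condition > 0,
    phases = ph,
    duration_s = dur,
    collapse_events = events
  ), class = "eod_amplitude")
}

#' Evaluate the ground-truth peak amplitude of a recording
#'
#' @param aprof an `eod_amplitude` profile.
#' @param t times in seconds (vectorized).
#' @return amplitude in signal units (>= 0) at each `t`.
#' @export
amplitude_value <- function(aprof, t) {
  a <- rep(aprof$base, length(t))
  if (length(aprof$jitter$path) > 0) {
    jit <- interp_path(aprof$jitter$path, aprof$jitter$dt_s, t)
    if (isTRUE(aprof$suppress_jitter)) {
      # movement (and hence electrode-relative jitter) fades during anesthesia
      # and returns within ~3 min of the fish's return to the home tank
      ph <- aprof$phases
      fade <- 1 - 0.9 * smoothstep((t - ph$start_s[2] - 60) / 60) *
        (1 - smoothstep((t - ph$start_s[3]) / 180))
      jit <- jit * fade
    }
    a <- a * exp(jit)
  }
  ev <- aprof$collapse_events
  for (i in seq_len(nrow(ev))) {
    shape <- rep(1, length(t))
    drop <- smoothstep((t - ev$onset_s[i]) / ev$ramp_s[i])
    shape <- 1 - (1 - ev$floor[i]) * drop
    after <- t > ev$hold_end_s[i]
    if (any(after)) {
      recov <- pmin(1, (t[after] - ev$hold_end_s[i]) / ev$recovery_s[i])
      shape[after] <- ev$floor[i] + (1 - ev$floor[i]) * recov
    }
    a <- a * shape
  }
  pmax(a, 0)
}
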