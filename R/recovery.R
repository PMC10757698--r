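# Baseline normalization, the four-parameter recovery model, maximum
# frequency drops, and amplitude-envelope analysis.

#' Normalize a median-frequency series to its baseline
#'
#' Divides every value by the median of the baseline-window medians and
#' re-references time so that `t = 0` is the instant the fish is returned to
#' its home tank.
#'
#' @param series data.frame with `time_s` and `median_hz` (from
#'   [median_frequency_series()] or [profile_median_series()]).
#' @param baseline_window `c(start_s, end_s)` of the baseline used for the
#'   normalizing median (typically the 30 min before immersion).
#' @param t_return_s absolute time of the return to the home tank (start of
#'   the post phase).
#' @return data.frame with `t_min` (minutes from return) and `y`
#'   (dimensionless normalized frequency), with the baseline median attached
#'   as attribute `baseline_median_hz`.
#' @export
normalize_frequency <- function(series, baseline_window, t_return_s) {
  base_vals <- series$median_hz[series$time_s >= baseline_window[1] &
                                series$time_s <= baseline_window[2]]
  if (length(base_vals) == 0)
    eod_stop("no values inside the baseline window", "eod_bad_config")
  base_med <- stats::median(base_vals)
  if (!is.finite(base_med) || base_med <= 0)
    eod_stop("baseline median must be positive", "eod_bad_config")
  out <- data.frame(t_min = (series$time_s - t_return_s) / 60,
                    y = series$median_hz / base_med)
  attr(out, "baseline_median_hz") <- base_med
  out
}

#' Evaluate the four-parameter recovery model
#'
#' `F(t) = a + ((c - a) t + d t^2) / (b + t)`: the normalized EOD frequency
#' trajectory after the fish's return from the anesthetic bath. `F(0) = a`
#' (the extrapolated drop floor), `F` approaches `c + d t` for `t >> b`, and
#' `b` (min) sets the recovery's characteristic time.
#'
#' @param params list or named vector with `a` (dimensionless), `b` (min),
#'   `c` (dimensionless), `d` (1/min).
#' @param t time in minutes from the return to the home tank (vectorized).
#' @return model value (dimensionless normalized frequency).
#' @export
#' @examples
#' p <- list(a = 0.5649, b = 1.5816, c = 1.0131, d = -6.2321e-5)
#' evaluate_recovery_model(p, 0)    # = a
#' evaluate_recovery_model(p, 30)
evaluate_recovery_model <- function(params, t) {
  p <- as.list(params)
  p$a + ((p$c - p$a) * t + p$d * t^2) / (p$b + t)
}

#' Fit the recovery model to normalized post-treatment data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' [evaluate_recovery_model()] against pooled normalized frequency points.
#' Started from `a = min(y)`, `c = 1`, `d = 0` and `b = 1` min, with
#' fall-back restarts over `b` in `restart_b` on failure.
#'
#' @param series data.frame with `t_min` and `y` (see
#'   [normalize_frequency()]); post-treatment points only (`t_min >= 0`
#'   enforced here).
#' @param restart_b initial values of `b` (min) tried in order.
#' @return list of class `eod_recovery_fit` with `params` (a, b, c, d),
#'   `sigma` (residual sd), `rss`, `n`, and `fit` (the underlying `nls`
#'   object). Signals `eod_fit_failed` when no start converges.
#' @export
fit_recovery_model <- function(series, restart_b = c(1, 0.5, 2, 5)) {
  dat <- series[series$t_min >= 0 & is.finite(series$y), , drop = FALSE]
  if (nrow(dat) < 8)
    eod_stop("need at least 8 post-treatment points", "eod_bad_config")
  if (stats::sd(dat$y) < 1e-10 * abs(mean(dat$y))) {
    # exactly flat series: the model degenerates to a = c = mean(y)
    return(structure(list(params = list(a = mean(dat$y), b = restart_b[1],
                                        c = mean(dat$y), d = 0),
                          sigma = 0, rss = 0, n = nrow(dat), fit = NULL),
                     class = "eod_recovery_fit"))
  }
  residual_fn <- function(par) {
    dat$y - evaluate_recovery_model(as.list(par), dat$t_min)
  }
  best <- NULL
  for (b0 in restart_b) {
    start <- c(a = min(dat$y), b = b0, c = 1, d = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = residual_fn,
                         lower = c(a = 0, b = 1e-3, c = 0, d = -Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best))
    eod_stop(sprintf(
      "recovery-model fit failed to converge from starts b = {%s}",
      paste(restart_b, collapse = ", ")), "eod_fit_failed")
  cf <- as.list(best$par)
  res <- residual_fn(best$par)
  structure(list(params = cf[c("a", "b", "c", "d")],
                 sigma = stats::sd(res), rss = sum(res^2), n = nrow(dat),
                 fit = best),
            class = "eod_recovery_fit")
}

#' @exportS3Method base::print
print.eod_recovery_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<eod_recovery_fit> a = %.4f, b = %.4f min, c = %.4f, d = %.3e /min (n = %d, sigma = %.2e)\n",
    p$a, p$b, p$c, p$d, x$n, x$sigma))
  invisible(x)
}

#' Maximum frequency drop of a median series relative to baseline
#'
#' @param series_hz median frequencies (Hz) over the interval of interest
#'   (numeric vector or data.frame with `median_hz`).
#' @param baseline_median_hz the baseline median frequency (Hz).
#' @return list with `drop_hz` (`baseline - min(series)`) and `drop_norm`
#'   (`drop_hz / baseline`).
#' @export
max_frequency_drop <- function(series_hz, baseline_median_hz) {
  if (is.data.frame(series_hz)) series_hz <- series_hz$median_hz
  if (length(series_hz) == 0)
    eod_stop("empty series", "eod_bad_config")
  drop <- baseline_median_hz - min(series_hz)
  list(drop_hz = drop, drop_norm = drop / baseline_median_hz)
}

#' Peak-to-peak amplitude envelope of a recording
#'
#' Per-window `max - min` of the raw signal; with EOD fundamentals of
#' several hundred Hz, the default 1-s window spans hundreds of discharge
#' cycles.
#'
#' @param recording an `eod_recording`.
#' @param window_s envelope window length in seconds.
#' @return data.frame with `time_s` (window centers) and `p2p`.
#' @export
amplitude_envelope <- function(recording, window_s = 1) {
  x <- recording$samples
  n <- length(x)
  nw <- max(2L, round(window_s * recording$rate))
  nwin <- n %/% nw
  if (nwin == 0) eod_stop("recording shorter than one window", "eod_bad_config")
  m <- matrix(x[seq_len(nwin * nw)], nrow = nw)
  p2p <- apply(m, 2, max) - apply(m, 2, min)
  data.frame(time_s = recording$start_s + (seq_len(nwin) - 0.5) * nw / recording$rate,
             p2p = p2p)
}

#' Detect amplitude-collapse episodes in an envelope
#'
#' Flags maximal runs where the peak-to-peak envelope stays below
#' `fraction` times the baseline envelope median for at least
#' `min_duration_s`.
#'
#' @param envelope data.frame from [amplitude_envelope()].
#' @param baseline_median_p2p median envelope during the baseline phase.
#' @param fraction collapse threshold as a fraction of baseline (default
#'   0.3).
#' @param min_duration_s minimum episode duration in seconds (default 10).
#' @return data.frame with `onset_s`, `offset_s`, `duration_s` (empty when
#'   no collapse).
#' @export
detect_amplitude_collapse <- function(envelope, baseline_median_p2p,
                                      fraction = 0.3, min_duration_s = 10) {
  below <- envelope$p2p < fraction * baseline_median_p2p
  runs <- true_runs(below)
  if (nrow(runs) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0)))
  dt <- stats::median(diff(envelope$time_s))
  out <- data.frame(
    onset_s = envelope$time_s[runs$start] - dt / 2,
    offset_s = envelope$time_s[runs$end] + dt / 2
  )
  out$duration_s <- out$offset_s - out$onset_s
  out[out$duration_s >= min_duration_s, , drop = FALSE]
}
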