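# Window-by-window dominant-frequency tracking with an adaptive search band.
#
# Each analysis window k is searched for the highest spectral peak inside
# [0.9, 1.1] x f_{d,k-1}; the window can then be bandpass-filtered to
# [0.4, 1.4] x f_{d,k} for downstream chirp analysis.

#' Tracker configuration
#'
#' @param window_s analysis window length in seconds. The default 50 ms gives
#'   ~20 Hz raw resolution, refined by quadratic peak interpolation.
#' @param step_s window step in seconds (0 < step <= window).
#' @param search_band multiplicative search band around the previous window's
#'   dominant frequency (default `c(0.9, 1.1)`).
#' @param filter_band multiplicative bandpass band around the current
#'   window's dominant frequency (default `c(0.4, 1.4)`), applied when
#'   `retain_filtered = TRUE`.
#' @param interpolate refine the peak by quadratic interpolation of the
#'   log-power spectrum?
#' @param pad_factor zero-padding factor before the FFT (sub-bin peak
#'   localization).
#' @param min_peak_fraction minimum fraction of in-band power that must lie
#'   within the peak's main lobe for the peak to count; windows failing this
#'   (e.g. transfer gaps) carry the previous frequency forward and are
#'   flagged.
#' @param retain_filtered keep the per-window zero-phase bandpass-filtered
#'   signal (4th-order Butterworth, forward-backward)?
#' @return list of class `eod_track_config`.
#' @export
track_config <- function(window_s = 0.05, step_s = 0.025,
                         search_band = c(0.9, 1.1),
                         filter_band = c(0.4, 1.4),
                         interpolate = TRUE, pad_factor = 4,
                         min_peak_fraction = 0.3,
                         retain_filtered = FALSE) {
  if (step_s <= 0 || step_s > window_s)
    eod_stop("need 0 < step_s <= window_s", "eod_bad_config")
  if (search_band[1] >= search_band[2] || filter_band[1] >= filter_band[2])
    eod_stop("band factor pairs must be ordered low < high", "eod_bad_config")
  structure(list(window_s = window_s, step_s = step_s,
                 search_band = search_band, filter_band = filter_band,
                 interpolate = interpolate, pad_factor = pad_factor,
                 min_peak_fraction = min_peak_fraction,
                 retain_filtered = retain_filtered),
            class = "eod_track_config")
}

#' High-resolution tracker configuration for chirp analysis
#'
#' A 5-ms window stepped every 1.25 ms resolves the ~10--50 ms chirp
#' excursions that the default 50-ms configuration smears out.
#' @param ... overrides passed to [track_config()].
#' @return list of class `eod_track_config`.
#' @export
chirp_track_config <- function(...) {
  args <- list(...)
  defaults <- list(window_s = 0.005, step_s = 0.00125)
  do.call(track_config, merge_lists(defaults, args))
}

#' @noRd
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Locate the dominant peak of a power spectrum inside a band
#'
#' @param power one-sided power spectrum (bins 0..nfft/2).
#' @param df_hz bin width of `power`.
#' @param band c(lo, hi) in Hz.
#' @param pad_factor padded bins per raw bin (main-lobe width heuristic).
#' @return list(freq, ok) where ok = FALSE when no acceptable in-band local
#'   maximum exists.
#' @noRd
spectral_peak <- function(power, df_hz, band, interpolate = TRUE,
                          pad_factor = 4, min_peak_fraction = 0.3) {
  nb <- length(power)
  lo <- max(2L, ceiling(band[1] / df_hz) + 1L)
  hi <- min(nb - 1L, floor(band[2] / df_hz) + 1L)
  if (hi < lo) return(list(freq = NA_real_, ok = FALSE))
  idx <- lo:hi
  j <- idx[which.max(power[idx])]
  # must be a local maximum of the spectrum, not a rising band edge
  if (power[j] <= power[j - 1L] || power[j] < power[j + 1L])
    return(list(freq = NA_real_, ok = FALSE))
  # concentration veto: a genuine discharge peak holds most in-band power
  # within its main lobe (or within +/- 2% of the peak frequency, whichever
  # is wider -- slow frequency wander broadens long-segment averages)
  lobe <- max(1L, 2L * pad_factor, ceiling(0.02 * (j - 1L)))
  lobe_idx <- max(1L, j - lobe):min(nb, j + lobe)
  band_power <- sum(power[idx])
  if (band_power <= 0 ||
      sum(power[intersect(lobe_idx, idx)]) < min_peak_fraction * band_power)
    return(list(freq = NA_real_, ok = FALSE))
  delta <- 0
  if (interpolate && j > 1L && j < nb) {
    y <- log(pmax(power[(j - 1L):(j + 1L)], .Machine$double.xmin))
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom < 0) delta <- max(-0.5, min(0.5, 0.5 * (y[1] - y[3]) / denom))
  }
  f <- (j - 1L + delta) * df_hz
  list(freq = min(band[2], max(band[1], f)), ok = TRUE)
}

#' Dominant frequency of one analysis window
#'
#' Computes the Hann-tapered, zero-padded power spectrum of `x` and returns
#' the frequency of its highest peak restricted to `band`, refined by
#' quadratic interpolation of the log power around the peak bin.
#'
#' @param x samples of one analysis window.
#' @param rate sampling rate in Hz.
#' @param band numeric `c(lo, hi)` search band in Hz (within Nyquist).
#' @param interpolate,pad_factor,min_peak_fraction see [track_config()].
#' @return dominant frequency in Hz. Signals a classed error
#'   (`eod_no_peak`) when no acceptable local maximum lies in the band.
#' @export
dominant_frequency <- function(x, rate, band, interpolate = TRUE,
                               pad_factor = 4, min_peak_fraction = 0.3) {
  if (length(x) == 0) eod_stop("empty window", "eod_bad_config")
  if (band[2] > rate / 2)
    eod_stop("search band exceeds the Nyquist frequency", "eod_bad_config")
  n <- length(x)
  nfft <- 2^ceiling(log2(n * pad_factor))
  xw <- c(x * hann_window(n), numeric(nfft - n))
  sp <- Mod(stats::fft(xw)[1:(nfft %/% 2 + 1L)])^2
  pk <- spectral_peak(sp, rate / nfft, band, interpolate, pad_factor,
                      min_peak_fraction)
  if (!pk$ok)
    eod_stop("no spectral peak found inside the search band", "eod_no_peak")
  pk$freq
}

#' Initial dominant frequency of the baseline recording
#'
#' Averages Hann periodograms of consecutive segments across the baseline
#' phase (Welch estimate) and takes the highest peak within a plausible EOD
#' band.
#'
#' @param recording an `eod_recording`. The baseline phase boundaries are
#'   taken from `recording$metadata$phases` when present, otherwise the whole
#'   recording is treated as baseline.
#' @param band plausible fundamental band in Hz (default 500--1200).
#' @param segment_s Welch segment length in seconds.
#' @return the initial dominant frequency `f_d0` in Hz. Signals `eod_no_peak`
#'   when the baseline holds no concentrated spectral peak (e.g. silence or
#'   white noise).
#' @export
baseline_dominant_frequency <- function(recording, band = c(500, 1200),
                                        segment_s = 1) {
  rate <- recording$rate
  ph <- recording$metadata$phases
  x <- recording$samples
  if (!is.null(ph)) {
    i <- which(ph$phase == "baseline")
    if (length(i) == 1) {
      a <- max(1L, floor((ph$start_s[i] - recording$start_s) * rate) + 1L)
      b <- min(length(x), floor((ph$end_s[i] - recording$start_s) * rate))
      if (b > a) x <- x[a:b]
    }
  }
  if (length(x) < rate * 0.1)
    eod_stop("baseline phase is empty", "eod_bad_config")
  n <- min(length(x), floor(segment_s * rate))
  nfft <- 2^ceiling(log2(n))
  w <- hann_window(n)
  nseg <- length(x) %/% n
  acc <- numeric(nfft %/% 2 + 1L)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * n + 1L):(s * n)] * w
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - n)))[1:(nfft %/% 2 + 1L)])^2
  }
  pk <- spectral_peak(acc / nseg, rate / nfft, band, interpolate = TRUE,
                      pad_factor = 1L, min_peak_fraction = 0.5)
  if (!pk$ok)
    eod_stop("no dominant spectral peak in the baseline recording",
             "eod_no_peak")
  pk$freq
}

#' Track the dominant EOD frequency window by window
#'
#' For each window `k` the search band is `[0.9, 1.1] x f_{d,k-1}` (factors
#' from `config$search_band`); the dominant frequency is the interpolated
#' argmax of the in-band power spectrum. Windows without an acceptable peak
#' (transfer gaps) carry the previous frequency forward and are flagged. When
#' `config$retain_filtered` is set, each window is additionally zero-phase
#' bandpass-filtered to `[0.4, 1.4] x f_{d,k}` and retained.
#'
#' @param recording an `eod_recording`.
#' @param config an `eod_track_config`.
#' @param f_d0 initial dominant frequency in Hz; computed with
#'   [baseline_dominant_frequency()] when `NULL`.
#' @param baseline_band plausible band passed on when `f_d0` is computed.
#' @return An `eod_track`: data.frame with columns `k`, `time_s` (window
#'   centers, absolute), `freq_hz`, `amp_rms` (per-window RMS of the raw
#'   signal, used by the chirp detector's low-amplitude veto), `flagged`,
#'   and attributes `rate`,
#'   `config`, `f_d0`, `start_s`, `duration_s` and (optionally) `filtered`,
#'   a list of per-window filtered signals.
#' @export
track_frequency <- function(recording, config = track_config(), f_d0 = NULL,
                            baseline_band = c(500, 1200)) {
  if (is.null(f_d0)) {
    f_d0 <- baseline_dominant_frequency(recording, band = baseline_band)
  }
  if (!is.finite(f_d0) || f_d0 <= 0)
    eod_stop("f_d0 must be positive", "eod_bad_config")
  x <- recording$samples
  rate <- recording$rate
  nw <- max(2L, round(config$window_s * rate))
  step <- max(1L, round(config$step_s * rate))
  if (length(x) < nw)
    eod_stop("recording shorter than one analysis window", "eod_bad_config")
  starts <- seq.int(1L, length(x) - nw + 1L, by = step)
  nwin <- length(starts)
  nfft <- 2^ceiling(log2(nw * config$pad_factor))
  w <- hann_window(nw)
  df <- rate / nfft
  nyq_cap <- 0.95 * rate / 2

  freq <- numeric(nwin)
  amp <- numeric(nwin)
  flagged <- logical(nwin)
  filtered <- if (config$retain_filtered) vector("list", nwin) else NULL
  f_prev <- f_d0
  chunk <- max(16L, 2L^22L %/% nfft)
  offsets <- 0:(nw - 1L)
  i0 <- 1L
  while (i0 <= nwin) {
    i1 <- min(nwin, i0 + chunk - 1L)
    m <- i1 - i0 + 1L
    raw <- matrix(x[rep(starts[i0:i1], each = nw) + offsets], nw, m)
    amp[i0:i1] <- sqrt(colMeans(raw * raw))
    M <- matrix(0, nfft, m)
    M[seq_len(nw), ] <- raw * w
    P <- Mod(stats::mvfft(M)[1:(nfft %/% 2 + 1L), , drop = FALSE])^2
    for (i in seq_len(m)) {
      band <- c(config$search_band[1] * f_prev,
                min(nyq_cap, config$search_band[2] * f_prev))
      pk <- spectral_peak(P[, i], df, band, config$interpolate,
                          config$pad_factor, config$min_peak_fraction)
      k <- i0 + i - 1L
      if (pk$ok) {
        freq[k] <- pk$freq
      } else {
        freq[k] <- f_prev
        flagged[k] <- TRUE
      }
      f_prev <- freq[k]
      if (config$retain_filtered) {
        filtered[[k]] <- bandpass_window(x[starts[k] + offsets], rate,
                                         config$filter_band * freq[k])
      }
    }
    i0 <- i1 + 1L
  }

  out <- data.frame(
    k = seq_len(nwin),
    time_s = recording$start_s + (starts - 1L + nw / 2) / rate,
    freq_hz = freq,
    amp_rms = amp,
    flagged = flagged
  )
  structure(out,
            rate = rate, config = config, f_d0 = f_d0,
            start_s = recording$start_s,
            duration_s = length(x) / rate,
            filtered = filtered,
            class = c("eod_track", "data.frame"))
}

#' Zero-phase 4th-order Butterworth bandpass of one window
#' @noRd
bandpass_window <- function(x, rate, band_hz) {
  nyq <- rate / 2
  lo <- max(band_hz[1] / nyq, 1e-4)
  hi <- min(band_hz[2] / nyq, 0.99)
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Median-frequency series of a track
#'
#' Reduces a dominant-frequency track to the assay's summary cadence: the
#' median of the tracked frequencies within 1-min windows placed every 30 s.
#' A 30-min track yields exactly 59 values (2 * (duration_min - 1) + 1).
#'
#' @param track an `eod_track`, or any data.frame with `time_s` and
#'   `freq_hz` columns.
#' @param interval_s spacing of consecutive windows (s).
#' @param window_s window length (s).
#' @param duration_s total extent of the track; taken from the track
#'   attribute when available.
#' @param start_s absolute time the summary windows start from; defaults to
#'   the track's recording start.
#' @return data.frame with `time_s` (window centers) and `median_hz`.
#'   Signals `eod_empty_series` when the track is shorter than one window.
#' @export
median_frequency_series <- function(track, interval_s = 30, window_s = 60,
                                    duration_s = NULL, start_s = NULL) {
  t0 <- start_s %||% attr(track, "start_s") %||% min(track$time_s)
  dur <- duration_s %||% attr(track, "duration_s") %||%
    (max(track$time_s) - t0)
  if (dur < window_s)
    eod_stop("track shorter than one summary window", "eod_empty_series")
  starts <- seq(t0, t0 + dur - window_s, by = interval_s)
  med <- vapply(starts, function(s) {
    stats::median(track$freq_hz[track$time_s >= s & track$time_s < s + window_s])
  }, numeric(1))
  data.frame(time_s = starts + window_s / 2, median_hz = med)
}

#' Temperature-adjust an EOD frequency to a reference temperature
#'
#' Multiplies `freq` by `q10^((t_ref - temp_c) / 10)`, the standard Q10
#' normalization of physiological rates (Q10 = 1.56 for the EOD of
#' A. leptorhynchus, reference 26 C).
#'
#' @param freq frequency in Hz (vectorized).
#' @param temp_c water temperature in degrees Celsius at the measurement.
#' @param t_ref reference temperature (default 26).
#' @param q10 Q10 coefficient (default 1.56).
#' @param valid_range physiologically plausible temperature range; values
#'   outside it are rejected.
#' @return adjusted frequency in Hz.
#' @export
adjust_temperature <- function(freq, temp_c, t_ref = 26, q10 = 1.56,
                               valid_range = c(20, 35)) {
  if (any(temp_c < valid_range[1] | temp_c > valid_range[2]))
    eod_stop("temperature outside the configured physiological range",
             "eod_bad_config")
  freq * q10^((t_ref - temp_c) / 10)
}

#' Coefficient of variation in percent
#'
#' `cv = 100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return cv in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2)
    eod_stop("cv needs at least two values", "eod_bad_config")
  m <- mean(values)
  if (!is.finite(m) || abs(m) < .Machine$double.eps * 100)
    eod_stop("cv undefined for (near-)zero mean", "eod_undefined_cv")
  100 * stats::sd(values) / m
}
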