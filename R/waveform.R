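# Rendering of the quasi-sinusoidal EOD carrier from ground-truth profiles.

#' Render a raw EOD voltage trace from ground-truth profiles
#'
#' Synthesizes `A(t) * sum_h w_h sin(2 pi h theta(t) + phi_h) + noise`, where
#' `theta(t)` is the running integral of the instantaneous frequency profile
#' (trapezoid-free cumulative sum at the sampling rate, which keeps the phase
#' error below one sample period times the frequency slope). Chirp amplitude
#' dips are applied as multiplicative factors `1 - dip * Phi(xi; alpha)`.
#'
#' @param profile an `eod_profile` (see [make_frequency_profile()]).
#' @param amplitude an `eod_amplitude` or `NULL` for constant unit amplitude.
#' @param waveform_config list with `sample_rate_hz`, `harmonics` (weights),
#'   `harmonic_phases_rad`, `noise_sd`; see [default_generator_config()].
#' @param metadata named list stored on the recording (fish id, concentration,
#'   temperature samples, ...). Phase boundaries are always attached.
#' @param from_s,to_s portion of the profile to render (defaults: all of it).
#' @return An object of class `eod_recording`: list with `samples` (numeric
#'   vector), `rate` (Hz), `start_s`, and `metadata` (contains `phases`).
#' @export
synthesize_waveform <- function(profile, amplitude = NULL,
                                waveform_config = default_generator_config()$waveform,
                                metadata = list(), from_s = 0,
                                to_s = profile$duration_s) {
  rate <- waveform_config$sample_rate_hz
  w <- waveform_config$harmonics
  hphase <- waveform_config$harmonic_phases_rad
  if (length(hphase) < length(w)) hphase <- rep_len(hphase, length(w))
  n_harm <- length(w)

  f_max <- profile$f0 +
    (if (length(profile$jitter$path)) max(abs(profile$jitter$path)) else 0) +
    (if (nrow(profile$chirps)) max(profile$chirps$delta_f_hz) else 0)
  if (rate < 4 * f_max * n_harm)
    eod_stop(sprintf(
      "sampling rate %.0f Hz is below 4x the highest modeled harmonic (%.0f Hz)",
      rate, f_max * n_harm), "eod_aliasing")

  n <- floor((to_s - from_s) * rate)
  if (n <= 0) eod_stop("empty rendering interval", "eod_bad_config")
  samples <- numeric(n)
  chunk <- 2^20
  phase_carry <- 0
  ch <- profile$chirps
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(n, i0 + chunk - 1L)
    t <- from_s + (seq.int(i0, i1) - 1L) / rate
    f <- profile_frequency(profile, t)
    theta <- phase_carry + 2 * pi * cumsum(f) / rate
    phase_carry <- theta[length(theta)]
    x <- numeric(length(t))
    for (h in seq_len(n_harm)) {
      if (w[h] != 0) x <- x + w[h] * sin(h * theta + hphase[h])
    }
    a <- if (is.null(amplitude)) rep(1, length(t)) else amplitude_value(amplitude, t)
    if (nrow(ch) > 0) {
      for (j in seq_len(nrow(ch))) {
        xi <- t - ch$time_s[j]
        in_sup <- abs(xi) <= ch$support_s[j]
        if (any(in_sup)) {
          a[in_sup] <- a[in_sup] *
            (1 - ch$amp_dip[j] * chirp_phi(xi[in_sup], ch$alpha_per_s[j]))
        }
      }
    }
    x <- x * a
    if (waveform_config$noise_sd > 0) {
      x <- x + rnorm(length(x), 0, waveform_config$noise_sd)
    }
    samples[i0:i1] <- x
    i0 <- i1 + 1L
  }

  md <- metadata
  md$phases <- profile$phases
  structure(list(samples = samples, rate = rate, start_s = from_s,
                 metadata = md),
            class = "eod_recording")
}

#' @exportS3Method base::print
print.eod_recording <- function(x, ...) {
  cat(sprintf("<eod_recording> %.1f s at %.0f Hz (%d samples)\n",
              length(x$samples) / x$rate, x$rate, length(x$samples)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `eod_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$rate
}

#' Write a recording as 32-bit float mono WAV plus a JSON sidecar
#'
#' The WAV file holds the raw samples (IEEE float, mono); the sidecar
#' `<path>.json` holds the start time and all metadata, including phase
#' boundaries and temperature samples.
#'
#' @param recording an `eod_recording`.
#' @param path output WAV path.
#' @return `path`, invisibly.
#' @export
write_recording_wav <- function(recording, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(recording$samples)
  byte_rate <- recording$rate * 4
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(3), con, size = 2, endian = "little")  # IEEE float
  writeBin(as.integer(1), con, size = 2, endian = "little")  # mono
  writeBin(as.integer(recording$rate), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(4), con, size = 2, endian = "little")
  writeBin(as.integer(32), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, size = 4, endian = "little")
  writeBin(as.numeric(recording$samples), con, size = 4, endian = "little")
  sidecar <- list(start_s = recording$start_s, rate_hz = recording$rate,
                  metadata = recording$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a recording written by [write_recording_wav()]
#'
#' Minimal reader for 32-bit float mono WAV with the package's JSON sidecar.
#'
#' @param path WAV path.
#' @return an `eod_recording`.
#' @export
read_recording_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) eod_stop("not a RIFF/WAV file", "eod_bad_file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    eod_stop("not a WAV file", "eod_bad_file")
  rate <- NULL; samples <- NULL; fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
    } else if (id == "data") {
      if (is.null(fmt) || fmt[1] != 3 || fmt[2] != 1)
        eod_stop("only 32-bit float mono WAV is supported", "eod_bad_file")
      samples <- readBin(con, "numeric", size %/% 4, size = 4,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) eod_stop("no data chunk found", "eod_bad_file")
  side_path <- paste0(path, ".json")
  start_s <- 0; md <- list()
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    start_s <- side$start_s %||% 0
    md <- side$metadata %||% list()
    if (!is.null(md$phases)) md$phases <- as.data.frame(md$phases)
  }
  structure(list(samples = samples, rate = rate, start_s = start_s,
                 metadata = md),
            class = "eod_recording")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
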