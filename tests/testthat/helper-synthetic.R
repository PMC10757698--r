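# Shared fixtures, all generated in code at test time.

# generator config with short phases and a light single-harmonic carrier,
# for tests that render waveforms
quick_config <- function(baseline_s = 60, treatment_s = 30, post_s = 120,
                         rate = 8000, noise_sd = 0, n_fish = 2,
                         concentrations = c(0, 60)) {
  generator_config(list(
    n_fish = n_fish,
    concentrations_ul_l = concentrations,
    phases = list(baseline_s = baseline_s, treatment_s = treatment_s,
                  post_s = post_s),
    waveform = list(sample_rate_hz = rate, harmonics = 1,
                    harmonic_phases_rad = 0, noise_sd = noise_sd)
  ))
}

# noise- and drop-free profile at a fixed frequency
flat_profile <- function(f0 = 800, duration_s = 20) {
  cfg <- generator_config(list(
    phases = list(baseline_s = duration_s, treatment_s = 0, post_s = 0)))
  make_frequency_profile(cfg, condition = 0, f0 = f0, jitter = FALSE)
}

# build an eod_recording directly from an instantaneous-frequency vector
# sampled at `rate` (amplitude `amp`, additive Gaussian noise `noise_sd`)
recording_from_freq <- function(f_inst, rate = 8000, amp = 1, noise_sd = 0,
                                start_s = 0, metadata = list()) {
  theta <- 2 * pi * cumsum(f_inst) / rate
  x <- amp * sin(theta)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  structure(list(samples = x, rate = rate, start_s = start_s,
                 metadata = metadata),
            class = "eod_recording")
}

# pure tone recording
tone_recording <- function(f0 = 800, duration_s = 2, rate = 8000, ...) {
  recording_from_freq(rep(f0, round(duration_s * rate)), rate = rate, ...)
}

# a flat-profile recording containing the given chirp table
chirped_recording <- function(chirps, f0 = 800, duration_s = 20,
                              rate = 8000, noise_sd = 0.05) {
  p <- flat_profile(f0, duration_s)
  chirps$support_s <- 5.3 / chirps$alpha_per_s
  if (is.null(chirps$amp_dip)) chirps$amp_dip <- 0.3
  p$chirps <- chirps
  wc <- list(sample_rate_hz = rate, harmonics = 1, harmonic_phases_rad = 0,
             noise_sd = noise_sd)
  synthesize_waveform(p, NULL, wc)
}

# independent brute-force oracle for the exact two-tailed sign test:
# enumerate all 2^n equally likely sign patterns
sign_test_enumeration <- function(n, n_minority) {
  patterns <- sum(choose(n, 0:n_minority))
  min(1, 2 * patterns / 2^n)
}

# simulate balanced split-plot data from the mixed model
simulate_mixed_data <- function(delta = c(1, -0.002, 5e-4, 1e-5),
                                sigma_beta = 0.02, sigma_eps = 0.01,
                                n_fish = 8, concs = c(0, 60), ks = 1:15) {
  grid <- expand.grid(k = ks, fish = seq_len(n_fish),
                      concentration_ul_l = concs)
  grid$t_min <- grid$k / 2
  unit <- interaction(grid$concentration_ul_l, grid$fish, drop = TRUE)
  b <- rnorm(nlevels(unit), 0, sigma_beta)[as.integer(unit)]
  grid$y <- delta[1] + delta[2] * grid$concentration_ul_l +
    delta[3] * grid$t_min +
    delta[4] * grid$concentration_ul_l * grid$t_min +
    b + rnorm(nrow(grid), 0, sigma_eps)
  grid
}

table2_params <- list(
  `30` = list(a = 0.7465, b = 1.4568, c = 1.0089, d = -3.2299e-5),
  `45` = list(a = 0.6344, b = 1.4064, c = 1.0084, d = -3.3821e-5),
  `60` = list(a = 0.5649, b = 1.5816, c = 1.0131, d = -6.2321e-5)
)
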