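test_that("normalization divides by the baseline median and re-references time", {
  series <- data.frame(time_s = seq(0, 3600, 30),
                       median_hz = rep(852, 121))
  norm <- normalize_frequency(series, baseline_window = c(0, 1800),
                              t_return_s = 2100)
  expect_true(all(norm$y == 1))
  expect_equal(attr(norm, "baseline_median_hz"), 852)
  expect_equal(norm$t_min[1], -35)

  series$median_hz[121] <- 620
  norm <- normalize_frequency(series, c(0, 1800), 2100)
  expect_equal(norm$y[121], 0.7277, tolerance = 1e-4)
  # round trip
  expect_equal(norm$y * attr(norm, "baseline_median_hz"), series$median_hz)
  # scaling all raw frequencies leaves the normalized series unchanged
  scaled <- series; scaled$median_hz <- scaled$median_hz * 3.7
  expect_equal(normalize_frequency(scaled, c(0, 1800), 2100)$y, norm$y)
  expect_error(normalize_frequency(series, c(-100, -50), 2100),
               class = "eod_bad_config")
})

test_that("the recovery model evaluates to its closed-form identities", {
  for (p in table2_params) {
    expect_identical(evaluate_recovery_model(p, 0), p$a)  # F(0) = a
  }
  expect_equal(evaluate_recovery_model(table2_params$`60`, 30), 0.9889,
               tolerance = 1e-4)
  expect_equal(evaluate_recovery_model(table2_params$`30`, 0), 0.7465)
  # large-t behaviour: F(t) -> c + d t + O(1/t)
  p <- table2_params$`45`
  t <- seq(1000, 5000, 250)
  expect_lt(max(abs(evaluate_recovery_model(p, t) - (p$c + p$d * t))), 1e-3)
  slope <- diff(evaluate_recovery_model(p, c(1000, 2000))) / 1000
  expect_equal(slope, p$d, tolerance = 0.02)
})

test_that("noiseless model data refit to sub-0.1% relative error", {
  t <- seq(0, 180, by = 0.5)
  for (p in table2_params) {
    series <- data.frame(t_min = t, y = evaluate_recovery_model(p, t))
    fit <- fit_recovery_model(series)
    for (nm in c("a", "b", "c", "d")) {
      expect_lt(abs(fit$params[[nm]] - p[[nm]]) / abs(p[[nm]]), 1e-3)
    }
    expect_lt(fit$sigma, 1e-8)
  }
})

test_that("fit is idempotent on its own noiseless predictions", {
  t <- seq(0, 180, by = 0.5)
  p <- table2_params$`60`
  fit1 <- fit_recovery_model(data.frame(
    t_min = t, y = evaluate_recovery_model(p, t) + rnorm(length(t), 0, 0.01)))
  pred <- data.frame(t_min = t,
                     y = evaluate_recovery_model(fit1$params, t))
  fit2 <- fit_recovery_model(pred)
  for (nm in c("a", "b", "c", "d")) {
    expect_equal(fit2$params[[nm]], fit1$params[[nm]], tolerance = 1e-4)
  }
})

test_that("noisy data recover a and c within 2% and b within 15%", {
  t <- seq(0, 180, by = 0.5)
  p <- table2_params$`45`
  truth <- evaluate_recovery_model(p, t)
  set.seed(14)
  err <- replicate(30, {
    fit <- fit_recovery_model(data.frame(t_min = t,
                                         y = truth + rnorm(length(t), 0, 0.01)))
    c(a = abs(fit$params$a - p$a) / p$a,
      b = abs(fit$params$b - p$b) / p$b,
      c = abs(fit$params$c - p$c) / p$c)
  })
  expect_lt(stats::quantile(err["a", ], 0.9), 0.02)
  expect_lt(stats::quantile(err["c", ], 0.9), 0.02)
  expect_lt(stats::quantile(err["b", ], 0.9), 0.15)
})

test_that("a constant series fits the degenerate flat model", {
  series <- data.frame(t_min = seq(0, 60, 0.5), y = 1)
  fit <- fit_recovery_model(series)
  expect_equal(fit$params$a, 1, tolerance = 1e-3)
  expect_equal(fit$params$c, 1, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  expect_error(fit_recovery_model(data.frame(t_min = 1:3, y = rep(1, 3))),
               class = "eod_bad_config")
})

test_that("maximum frequency drop is the baseline-to-minimum excursion", {
  expect_equal(max_frequency_drop(rep(800, 10), 800)$drop_hz, 0)
  d <- max_frequency_drop(c(850, 620, 700), 852)
  expect_equal(d$drop_hz, 232)
  expect_equal(d$drop_norm, 232 / 852)
  # appending values above the minimum cannot change the drop
  d2 <- max_frequency_drop(c(850, 620, 700, 900, 845), 852)
  expect_equal(d2$drop_hz, d$drop_hz)
})

test_that("the peak-to-peak envelope tracks amplitude including collapse", {
  # pure sine of amplitude A has envelope 2A
  rec <- recording_from_freq(rep(700, 8000 * 3), rate = 8000, amp = 0.7)
  env <- amplitude_envelope(rec, window_s = 1)
  expect_equal(env$p2p, rep(1.4, 3), tolerance = 0.01)
  zero <- structure(list(samples = numeric(8000), rate = 8000, start_s = 0,
                         metadata = list()), class = "eod_recording")
  expect_equal(amplitude_envelope(zero)$p2p, 0)

  # generator collapse: onset 210 s into treatment, 10% floor
  cfg <- quick_config(baseline_s = 60, treatment_s = 300, post_s = 420)
  p <- make_frequency_profile(cfg, condition = 60, f0 = 700, jitter = FALSE)
  ap <- make_amplitude_profile(generator_config()$amplitude, p,
                               collapse = TRUE)
  ap$jitter$path <- numeric(0)  # isolate the collapse shape
  rec <- synthesize_waveform(p, ap, list(sample_rate_hz = 8000, harmonics = 1,
                                         harmonic_phases_rad = 0,
                                         noise_sd = 0))
  env <- amplitude_envelope(rec, window_s = 1)
  base_med <- stats::median(env$p2p[env$time_s < 60])
  events <- detect_amplitude_collapse(env, base_med)
  expect_equal(nrow(events), 1)
  expect_equal(events$onset_s, 60 + 210, tolerance = 16)
  # floor reached: envelope bottoms out near 10% of baseline
  expect_equal(min(env$p2p) / base_med, 0.1, tolerance = 0.02)
  # degenerate threshold never fires
  expect_equal(nrow(detect_amplitude_collapse(env, base_med, fraction = 0)), 0)
  # no-collapse recording yields an empty list
  ap0 <- make_amplitude_profile(generator_config()$amplitude, p,
                                collapse = FALSE)
  ap0$jitter$path <- numeric(0)
  rec0 <- synthesize_waveform(p, ap0, list(sample_rate_hz = 8000,
                                           harmonics = 1,
                                           harmonic_phases_rad = 0,
                                           noise_sd = 0))
  env0 <- amplitude_envelope(rec0, window_s = 1)
  expect_equal(nrow(detect_amplitude_collapse(env0, base_med)), 0)
})
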