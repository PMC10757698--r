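test_that("control profiles are constant at f0 and invalid inputs are rejected", {
  p <- make_frequency_profile(condition = 0, f0 = 800, jitter = FALSE)
  t <- seq(0, p$duration_s, by = 30)
  expect_equal(profile_frequency(p, t), rep(800, length(t)))

  expect_error(make_frequency_profile(f0 = -5), class = "eod_bad_config")
  expect_error(make_frequency_profile(f0 = 0), class = "eod_bad_config")
  cfg <- generator_config(list(phases = list(baseline_s = -1)))
  expect_error(make_frequency_profile(cfg, f0 = 800), class = "eod_bad_config")
})

test_that("post-treatment profile follows the recovery model scaled by f0", {
  for (conc in c(30, 45, 60)) {
    p <- make_frequency_profile(condition = conc, f0 = 1, jitter = FALSE)
    post_start <- p$phases$start_s[3]
    t_min <- c(0, 0.5, 1, 2, 5, 10, 30, 60, 180)
    expect_equal(profile_frequency(p, post_start + t_min * 60),
                 evaluate_recovery_model(table2_params[[as.character(conc)]],
                                         t_min),
                 tolerance = 1e-12)
  }
  # direct arithmetic value at t = 30 min, 60 uL/L
  p60 <- make_frequency_profile(condition = 60, f0 = 1, jitter = FALSE)
  expect_equal(profile_frequency(p60, p60$phases$start_s[3] + 30 * 60),
               0.9889, tolerance = 1e-4)
  # scaling by f0 is exact
  p800 <- make_frequency_profile(condition = 60, f0 = 800, jitter = FALSE)
  expect_equal(profile_frequency(p800, p800$phases$start_s[3] + c(0, 600)),
               800 * profile_frequency(p60, p60$phases$start_s[3] + c(0, 600)))
})

test_that("treatment phase declines continuously from f0 toward a*f0", {
  p <- make_frequency_profile(condition = 60, f0 = 800, jitter = FALSE)
  b0 <- p$phases$start_s[2]; t1 <- p$phases$start_s[3]
  f_trt <- profile_frequency(p, seq(b0, t1, by = 1))
  expect_true(all(diff(f_trt) <= 1e-9))
  expect_equal(f_trt[1], 800)
  expect_equal(f_trt[length(f_trt)], 800 * 0.5649, tolerance = 1e-6)
  # continuity at the return instant
  expect_lt(abs(profile_frequency(p, t1 - 1e-3) -
                  profile_frequency(p, t1 + 1e-3)), 0.5)
})

test_that("insert_chirps with zero rates leaves the profile unchanged", {
  p <- flat_profile(800, 60)
  out <- insert_chirps(p, rate_pre = 0, rate_post = 0)
  expect_equal(nrow(out$chirps), 0)
  t <- seq(0, 60, by = 0.1)
  expect_equal(profile_frequency(out$profile, t), rep(800, length(t)))
})

test_that("a single chirp peaks at f0 + delta_f at its event time", {
  p <- flat_profile(800, 20)
  p$chirps <- data.frame(time_s = 10, delta_f_hz = 60, alpha_per_s = 500,
                         amp_dip = 0.3, support_s = 5.3 / 500)
  t <- seq(0, 20, by = 1e-4)
  f <- profile_frequency(p, t)
  expect_equal(max(f), 860)
  expect_equal(t[which.max(f)], 10, tolerance = 1e-3)
  expect_equal(profile_frequency(p, 10), 860)
})

test_that("chirp event counts follow the configured Poisson rate", {
  cfg <- generator_config(list(
    phases = list(baseline_s = 0, treatment_s = 0, post_s = 1800)))
  p <- make_frequency_profile(cfg, condition = 0, f0 = 800, jitter = FALSE)
  set.seed(7)
  out <- insert_chirps(p, rate_pre = 0, rate_post = 5, post_window_s = 1800)
  # mean 150, 3 sigma band by the Poisson law
  expect_gt(nrow(out$chirps), 150 - 3 * sqrt(150))
  expect_lt(nrow(out$chirps), 150 + 3 * sqrt(150))
  # log is sorted, every event inside the record, supports do not overlap
  expect_true(!is.unsorted(out$chirps$time_s))
  gaps <- diff(out$chirps$time_s)
  supp <- out$chirps$support_s
  expect_true(all(gaps >= (supp[-length(supp)] + supp[-1])))
  # ground-truth completeness: the profile equals base + logged excursions
  t <- sort(c(out$chirps$time_s, runif(50, 0, 1800)))
  manual <- profile_frequency(out$profile, t, chirps = FALSE)
  for (i in seq_len(nrow(out$chirps))) {
    manual <- manual + out$chirps$delta_f_hz[i] *
      chirp_phi(t - out$chirps$time_s[i], out$chirps$alpha_per_s[i]) *
      (abs(t - out$chirps$time_s[i]) <= out$chirps$support_s[i])
  }
  expect_equal(profile_frequency(out$profile, t), manual, tolerance = 1e-12)
  expect_error(insert_chirps(p, rate_pre = -1), class = "eod_bad_config")
})

test_that("rendered waveforms are phase-continuous pure tones at the profile frequency", {
  rec <- chirped_recording(data.frame(time_s = numeric(0),
                                      delta_f_hz = numeric(0),
                                      alpha_per_s = numeric(0),
                                      amp_dip = numeric(0)),
                           f0 = 700, duration_s = 3, rate = 40000,
                           noise_sd = 0)
  # periodogram peak of any 1-s slice at 700 Hz
  for (s in 0:2) {
    slice <- rec$samples[(s * 40000 + 1):((s + 1) * 40000)]
    expect_equal(dominant_frequency(slice, 40000, c(500, 900)), 700,
                 tolerance = 1e-3)
  }
  # phase-continuity bound: |x[i+1] - x[i]| <= 2 pi f_max / rate * A
  expect_lt(max(abs(diff(rec$samples))), 2 * pi * 700 / 40000 * 1.0001)
})

test_that("waveform synthesis is deterministic and rejects aliasing", {
  p <- flat_profile(800, 2)
  wc <- list(sample_rate_hz = 8000, harmonics = 1, harmonic_phases_rad = 0,
             noise_sd = 0.05)
  set.seed(11); r1 <- synthesize_waveform(p, NULL, wc)
  set.seed(11); r2 <- synthesize_waveform(p, NULL, wc)
  expect_identical(r1$samples, r2$samples)

  wc$harmonics <- c(1, 0.3, 0.1)
  wc$sample_rate_hz <- 6000  # 3rd harmonic at 2400 Hz needs >= 9600
  expect_error(synthesize_waveform(p, NULL, wc), class = "eod_aliasing")
})

test_that("generate_experiment emulates the randomized complete block design", {
  cfg <- quick_config(baseline_s = 60, treatment_s = 30, post_s = 60,
                      n_fish = 3, concentrations = c(0, 30, 60))
  exp1 <- generate_experiment(cfg, seed = 5)
  expect_s3_class(exp1, "eod_experiment")
  expect_length(exp1$recordings, 9)
  # one recording per (fish, condition) pair
  keys <- t(sapply(exp1$recordings, function(r)
    c(r$fish, r$concentration_ul_l)))
  expect_equal(nrow(unique(keys)), 9)
  # f0 drawn once per fish and reused across conditions
  for (j in 1:3) {
    f0s <- sapply(exp1$recordings[keys[, 1] == j], function(r) r$profile$f0)
    expect_equal(unname(diff(range(f0s))), 0)
  }
  # treatment order per fish is a permutation of the condition set
  for (j in 1:3) {
    ord <- exp1$design$concentration_ul_l[exp1$design$fish == j]
    expect_setequal(ord, c(0, 30, 60))
  }
  # regeneration from the same seed is identical
  exp2 <- generate_experiment(cfg, seed = 5)
  expect_identical(exp1, exp2)
  expect_false(identical(exp1, generate_experiment(cfg, seed = 6)))
})

test_that("a single-fish control experiment has no drop and no chirp boost", {
  cfg <- quick_config(baseline_s = 120, treatment_s = 30, post_s = 120,
                      n_fish = 1, concentrations = 0)
  exp <- generate_experiment(cfg, seed = 3)
  expect_length(exp$recordings, 1)
  entry <- exp$recordings[[1]]
  f <- profile_frequency(entry$profile, seq(0, 270, 0.5), chirps = FALSE)
  expect_lt(diff(range(f)), 0.05 * entry$profile$f0)  # jitter only
  expect_equal(nrow(entry$amplitude$collapse_events), 0)
})

test_that("generate_experiment leaves the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(generate_experiment(quick_config(n_fish = 1,
                                             concentrations = 0), seed = 9))
  expect_identical(runif(1), before)
})

test_that("generator configuration can be loaded from a JSON document", {
  path <- file.path(tempdir(), "cfg.json")
  on.exit(unlink(path))
  jsonlite::write_json(list(n_fish = 3, jitter = list(sd_rel = 0.002)),
                       path, auto_unbox = TRUE)
  cfg <- read_generator_config(path)
  expect_equal(cfg$n_fish, 3)
  expect_equal(cfg$jitter$sd_rel, 0.002)
  expect_equal(cfg$jitter$tau_s, 45)  # untouched default
})
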