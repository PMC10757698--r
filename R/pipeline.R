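# End-to-end orchestration: generation -> summarization -> chirp counting ->
# recovery fitting -> statistics, as one reproducible run.

#' Run the full assay analysis on a synthetic experiment
#'
#' Executes every stage of the assay on a generated experiment and collects
#' the analogues of the study's figures and tables: per-recording baseline
#' medians and cv values, maximum frequency drops, chirp counts before and
#' after treatment, pooled recovery-model fits per concentration, the
#' sign-test comparisons (frequency change, drop differences, chirp-count
#' increases), and the sliding-window recovery times.
#'
#' Two execution modes share every downstream stage:
#' \describe{
#'   \item{`"profile"` (default)}{median-frequency series and chirp logs are
#'     taken from the generator's ground truth. This runs the full 215-min,
#'     32-recording design in seconds and is the mode the statistical stages
#'     are exercised in.}
#'   \item{`"waveform"`}{raw voltage traces are rendered and pushed through
#'     [track_frequency()], [median_frequency_series()] and
#'     [detect_chirps()]. Intended for reduced timelines; requires
#'     `config$render_waveforms = TRUE`.}
#' }
#'
#' Identical `(config, seed)` reproduce the report exactly.
#'
#' @param config generator configuration (see [default_generator_config()]).
#' @param seed integer seed for the generated experiment.
#' @param mode `"profile"` or `"waveform"`.
#' @param alpha significance level used throughout (default 0.01,
#'   two-tailed).
#' @param do_recovery_time run the sliding-window recovery-time stage?
#'   (The stage refits the mixed model over many windows and dominates run
#'   time.)
#' @param outdir optional directory; when given, every table is written as
#'   CSV, fits and the report as JSON, plus a config snapshot.
#' @return list of class `eod_run_report`; see Details.
#' @export
run_full_analysis <- function(config = default_generator_config(), seed,
                              mode = c("profile", "waveform"),
                              alpha = 0.01, do_recovery_time = TRUE,
                              outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "waveform" && !isTRUE(config$render_waveforms))
    eod_stop("waveform mode requires config$render_waveforms = TRUE",
             "eod_bad_config")
  exp <- generate_experiment(config, seed)
  concs <- sort(unique(exp$design$concentration_ul_l))
  k_max <- floor(config$phases$post_s / 30)

  per_rec <- lapply(exp$recordings, function(entry) {
    summarize_recording(entry, mode, k_max)
  })
  rec_tbl <- do.call(rbind, lapply(per_rec, function(s) {
    data.frame(fish = s$fish, concentration_ul_l = s$concentration_ul_l,
               baseline_median_hz = s$baseline_median_hz,
               cv_percent = s$cv_percent,
               change_15min_hz = s$change_15min_hz,
               drop_hz = s$drop_hz, drop_norm = s$drop_norm,
               chirps_pre30 = s$chirps_pre30, chirps_post30 = s$chirps_post30,
               chirp_increase = s$chirps_post30 - s$chirps_pre30,
               n_collapse_events = s$n_collapse_events)
  }))
  rownames(rec_tbl) <- NULL

  by_fish <- function(col, conc) {
    v <- rec_tbl[rec_tbl$concentration_ul_l == conc, ]
    v[order(v$fish), col]
  }

  # frequency change, 30 min before vs 15 min after onset of anesthesia
  freq_change_tests <- lapply(concs, function(cc) {
    d <- by_fish("change_15min_hz", cc)
    st <- sign_test_exact(d)
    data.frame(concentration_ul_l = cc, p_value = st$p_value,
               median = stats::median(d), lo = min(d), hi = max(d))
  })
  freq_change_tests <- do.call(rbind, freq_change_tests)

  # normalized maximum drops, consecutive treatment pairs
  pair_test <- function(col, c_a, c_b) {
    d <- by_fish(col, c_a) - by_fish(col, c_b)
    st <- sign_test_exact(d)
    data.frame(comparison = sprintf("%g vs %g", c_a, c_b),
               p_value = st$p_value, median = stats::median(d),
               lo = min(d), hi = max(d))
  }
  treated <- concs[concs > 0]
  drop_pairs <- if (length(treated))
    cbind(treated, c(0, treated[-length(treated)])) else
      matrix(numeric(0), 0, 2)
  drop_tests <- do.call(rbind, lapply(seq_len(nrow(drop_pairs)), function(i) {
    # drops are reported as negative changes, matching the study's tables
    d <- -(by_fish("drop_norm", drop_pairs[i, 1]) -
             by_fish("drop_norm", drop_pairs[i, 2]))
    st <- sign_test_exact(d)
    data.frame(comparison = sprintf("%g vs %g", drop_pairs[i, 1],
                                    drop_pairs[i, 2]),
               p_value = st$p_value, median = stats::median(d),
               lo = min(d), hi = max(d))
  }))

  # chirp-count increases: each concentration vs control, then between pairs
  chirp_vs_control <- do.call(rbind, lapply(treated, function(cc) {
    pair_test("chirp_increase", cc, 0)
  }))
  chirp_pairs <- if (length(treated) >= 2) t(utils::combn(treated, 2)) else
    matrix(numeric(0), 0, 2)
  chirp_between <- do.call(rbind, lapply(seq_len(nrow(chirp_pairs)), function(i) {
    pair_test("chirp_increase", chirp_pairs[i, 2], chirp_pairs[i, 1])
  }))

  # pooled recovery-model fits per concentration
  treated_names <- if (length(treated)) paste0("c", treated) else character(0)
  recovery_fits <- lapply(stats::setNames(as.list(treated), treated_names),
                          function(cc) {
    keys <- names(per_rec)[vapply(per_rec, function(s)
      s$concentration_ul_l == cc, logical(1))]
    pooled <- do.call(rbind, lapply(keys, function(k) per_rec[[k]]$post_norm))
    fit <- fit_recovery_model(pooled)
    fit$fit <- NULL  # keep the report serializable
    fit
  })

  # sliding-window recovery times, each concentration against control
  recovery_times <- NULL
  if (do_recovery_time) {
    recovery_times <- lapply(stats::setNames(as.list(treated), treated_names),
                             function(cc) {
      sel <- vapply(per_rec, function(s)
        s$concentration_ul_l %in% c(0, cc), logical(1))
      dat <- mixed_model_data(
        lapply(per_rec[sel], function(s) s$post_norm),
        fish = vapply(per_rec[sel], function(s) s$fish, numeric(1)),
        concentration = vapply(per_rec[sel], function(s)
          s$concentration_ul_l, numeric(1)),
        t_grid_min = seq_len(k_max) / 2
      )
      rt <- recovery_time(dat, window_len = 15, alpha = alpha)
      list(r = rt$r, t_r_min = rt$t_r_min, recovered = rt$recovered,
           n_windows_examined = length(rt$p_adjusted))
    })
  }

  report <- structure(list(
    seed = seed, mode = mode, alpha = alpha,
    design = exp$design,
    recordings = rec_tbl,
    freq_change_tests = freq_change_tests,
    drop_tests = drop_tests,
    chirp_tests_vs_control = chirp_vs_control,
    chirp_tests_between = chirp_between,
    recovery_fits = lapply(recovery_fits, function(f)
      c(f$params, list(sigma = f$sigma, n = f$n))),
    recovery_times = recovery_times,
    amplitude_note = if (mode == "profile")
      "collapse events reported from ground truth (profile mode)" else
        "collapse events detected from the rendered envelope"
  ), class = "eod_run_report")

  if (!is.null(outdir)) write_report(report, config, outdir)
  report
}

#' @noRd
summarize_recording <- function(entry, mode, k_max) {
  prof <- entry$profile
  ph <- prof$phases
  b_start <- ph$start_s[1]; b_end <- ph$end_s[1]
  trt_start <- ph$start_s[2]
  post_start <- ph$start_s[3]; post_end <- ph$end_s[3]

  if (mode == "profile") {
    base_series <- profile_median_series(prof, b_start, b_end)
    after_series <- profile_median_series(prof, trt_start, post_end,
                                          align = "right")
    events <- entry$chirps
  } else {
    rec <- entry$recording
    f_d0 <- baseline_dominant_frequency(rec)
    track <- track_frequency(rec, track_config(window_s = 0.5, step_s = 0.25),
                             f_d0 = f_d0)
    full_series <- median_frequency_series(track)
    base_series <- full_series[full_series$time_s < b_end, ]
    after_series <- median_frequency_series(
      track[track$time_s >= trt_start, ],
      duration_s = post_end - trt_start, start_s = trt_start)
    ctrack <- track_frequency(rec, chirp_track_config(), f_d0 = f_d0)
    events <- detect_chirps(ctrack)
  }

  # temperature adjustment to the 26 C reference (identity when the tank
  # sits at the reference)
  t_med <- stats::median(entry$temperature$temp_c)
  base_series$median_hz <- adjust_temperature(base_series$median_hz, t_med)
  after_series$median_hz <- adjust_temperature(after_series$median_hz, t_med)

  baseline_median <- stats::median(base_series$median_hz)
  cv <- coefficient_of_variation(base_series$median_hz)

  win15 <- after_series[after_series$time_s >= trt_start &
                          after_series$time_s <= trt_start + 900, ]
  change15 <- stats::median(win15$median_hz) - baseline_median
  drop <- max_frequency_drop(after_series$median_hz, baseline_median)

  post_series <- after_series[after_series$time_s > post_start &
                                after_series$time_s <= post_start + k_max * 30, ]
  post_norm <- data.frame(t_min = (post_series$time_s - post_start) / 60,
                          y = post_series$median_hz / baseline_median)

  summary_tbl <- chirp_rate_summary(events, ph)
  list(
    fish = entry$fish, concentration_ul_l = entry$concentration_ul_l,
    baseline_median_hz = baseline_median, cv_percent = cv,
    change_15min_hz = change15,
    drop_hz = drop$drop_hz, drop_norm = drop$drop_norm,
    chirps_pre30 = summary_tbl$count[summary_tbl$interval == "pre30"],
    chirps_post30 = summary_tbl$count[summary_tbl$interval == "post30"],
    n_collapse_events = nrow(entry$amplitude$collapse_events),
    post_norm = post_norm
  )
}

#' @noRd
write_report <- function(report, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$recordings,
                   file.path(outdir, "recordings.csv"), row.names = FALSE)
  utils::write.csv(report$freq_change_tests,
                   file.path(outdir, "freq_change_tests.csv"), row.names = FALSE)
  if (!is.null(report$drop_tests))
    utils::write.csv(report$drop_tests,
                     file.path(outdir, "drop_tests.csv"), row.names = FALSE)
  chirp_tbl <- rbind(report$chirp_tests_vs_control, report$chirp_tests_between)
  if (!is.null(chirp_tbl))
    utils::write.csv(chirp_tbl, file.path(outdir, "chirp_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report$recovery_fits,
                       file.path(outdir, "recovery_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$recovery_times))
    jsonlite::write_json(report$recovery_times,
                         file.path(outdir, "recovery_times.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = report$seed, mode = report$mode,
                            alpha = report$alpha, config = config),
                       file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @exportS3Method base::print
print.eod_run_report <- function(x, ...) {
  cat(sprintf("<eod_run_report> seed %s, %s mode, %d recordings\n",
              format(x$seed), x$mode, nrow(x$recordings)))
  cat("  frequency-change sign tests (p):",
      paste(sprintf("%g uL/L: %.4f", x$freq_change_tests$concentration_ul_l,
                    x$freq_change_tests$p_value), collapse = "; "), "\n")
  if (!is.null(x$recovery_times)) {
    cat("  recovery times (min):",
        paste(sprintf("%s: %.1f", names(x$recovery_times),
                      vapply(x$recovery_times, function(r)
                        r$t_r_min %||% NA_real_, numeric(1))),
              collapse = "; "), "\n")
  }
  invisible(x)
}
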