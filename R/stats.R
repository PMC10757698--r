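# The assay's statistical procedures: exact sign test and its minimal-n
# design rule, the split-plot linear mixed model, the joint
# concentration-effect test, and the sliding-window recovery-time estimator.

#' Exact two-tailed related-samples sign test
#'
#' Ties (zero differences) are dropped and `n` reduced; the two-tailed
#' p-value is `min(1, 2 * P(Bin(n, 1/2) <= min(n+, n-)))`.
#'
#' @param differences numeric vector of paired differences.
#' @return list of class `eod_sign_test` with `n`, `n_positive`,
#'   `n_negative`, `p_value`. Signals `eod_undefined_test` when every
#'   difference is zero.
#' @export
#' @examples
#' sign_test_exact(rep(-1, 8))$p_value   # 0.0078
sign_test_exact <- function(differences) {
  d <- differences[differences != 0]
  if (length(d) == 0)
    eod_stop("all differences are ties; the sign test is undefined",
             "eod_undefined_test")
  n <- length(d)
  npos <- sum(d > 0)
  nneg <- n - npos
  p <- min(1, 2 * stats::pbinom(min(npos, nneg), n, 0.5))
  structure(list(n = n, n_positive = npos, n_negative = nneg, p_value = p),
            class = "eod_sign_test")
}

#' @exportS3Method base::print
print.eod_sign_test <- function(x, ...) {
  cat(sprintf("<eod_sign_test> n = %d (%d+/%d-), two-tailed p = %.4f\n",
              x$n, x$n_positive, x$n_negative, x$p_value))
  invisible(x)
}

#' Minimal sample size for the sign test under a fully concordant outcome
#'
#' The smallest `n` for which `n` concordant signs (all positive or all
#' negative) reach two-tailed significance at level `alpha`:
#' `ceiling(1 - log2(alpha))`. At `alpha = 0.01` this gives 8, the number of
#' fish used per condition.
#'
#' @param alpha two-tailed significance level in (0, 1).
#' @return integer minimal `n`.
#' @export
min_n_for_sign_test <- function(alpha) {
  if (alpha <= 0 || alpha >= 1)
    eod_stop("alpha must be in (0, 1)", "eod_bad_config")
  as.integer(ceiling(1 - log2(alpha)))
}

#' Assemble split-plot model data from per-recording normalized series
#'
#' @param series_list list of data.frames with `t_min`, `y`; names ignored.
#' @param fish,concentration vectors parallel to `series_list`.
#' @param t_grid_min common time grid (t_k = k/2 min, k = 1..360 by default);
#'   each series is matched to the grid by nearest time (within half a step).
#' @return data.frame with `y`, `concentration_ul_l`, `fish`, `k`, `t_min`.
#' @export
mixed_model_data <- function(series_list, fish, concentration,
                             t_grid_min = (1:360) / 2) {
  stopifnot(length(series_list) == length(fish),
            length(fish) == length(concentration))
  fish <- unname(fish)
  concentration <- unname(concentration)
  step <- stats::median(diff(t_grid_min))
  out <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    idx <- vapply(t_grid_min, function(tk) {
      j <- which.min(abs(s$t_min - tk))
      if (abs(s$t_min[j] - tk) <= step / 2) j else NA_integer_
    }, integer(1))
    ok <- !is.na(idx)
    data.frame(y = s$y[idx[ok]], concentration_ul_l = concentration[i],
               fish = fish[i], k = which(ok), t_min = t_grid_min[ok])
  }))
  rownames(out) <- NULL
  out
}

#' Fit the split-plot linear mixed model
#'
#' `Y_ijk = d0 + d1 c_i + b_j(i) + d2 t_k + d12 c_i t_k + e_ijk` with random
#' fish-within-treatment intercepts `b_j(i) ~ N(0, sigma_b^2)` and residuals
#' `e_ijk ~ N(0, sigma_e^2)`. Concentration enters as its numeric value in
#' uL/L (0 for control). Estimated by REML via `lme4::lmer` (use
#' `REML = FALSE` for likelihood-ratio comparisons). When the residual
#' variance degenerates to zero (noise-free data) the mixed fit falls back to
#' ordinary least squares with `sigma_b^2 = 0` and is flagged singular.
#'
#' @param data data.frame with columns `y`, `concentration_ul_l`, `fish`,
#'   `t_min` (see [mixed_model_data()]).
#' @param REML logical; REML (default) or ML estimation.
#' @return list of class `eod_mixed_fit` with `fixed` (named vector `d0`,
#'   `d1`, `d2`, `d12`), `sigma_beta2`, `sigma_eps2`, `logLik`, `singular`,
#'   `converged`, and `model` (the lmer or lm object).
#' @export
fit_mixed_model <- function(data, REML = TRUE) {
  req <- c("y", "concentration_ul_l", "fish", "t_min")
  if (!all(req %in% names(data)))
    eod_stop(paste("data must have columns", paste(req, collapse = ", ")),
             "eod_bad_config")
  data$unit <- interaction(data$concentration_ul_l, data$fish, drop = TRUE)
  per_unit <- table(data$unit)
  if (length(per_unit) < 2)
    eod_stop("need at least two fish-within-treatment units", "eod_bad_config")
  fe_names <- c("d0", "d1", "d2", "d12")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ concentration_ul_l + t_min +
                   concentration_ul_l:t_min + (1 | unit),
                 data = data, REML = REML,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- lme4::VarCorr(fit)
    sigma_beta2 <- as.numeric(vc$unit[1])
    sigma_eps2 <- stats::sigma(fit)^2
    fixed <- lme4::fixef(fit)
    names(fixed) <- fe_names[match(names(fixed),
      c("(Intercept)", "concentration_ul_l", "t_min",
        "concentration_ul_l:t_min"))]
    return(structure(list(fixed = fixed[fe_names],
                          sigma_beta2 = sigma_beta2,
                          sigma_eps2 = sigma_eps2,
                          logLik = as.numeric(stats::logLik(fit)),
                          singular = lme4::isSingular(fit),
                          converged = TRUE, model = fit),
                     class = "eod_mixed_fit"))
  }
  # degenerate (e.g. exactly noise-free) data: mixed fit unavailable,
  # fall back to the fixed-effects least-squares solution
  ls <- stats::lm(y ~ concentration_ul_l + t_min + concentration_ul_l:t_min,
                  data = data)
  fixed <- stats::coef(ls)
  names(fixed) <- fe_names
  structure(list(fixed = fixed, sigma_beta2 = 0,
                 sigma_eps2 = stats::sigma(ls)^2,
                 logLik = as.numeric(stats::logLik(ls)),
                 singular = TRUE, converged = TRUE, model = ls),
            class = "eod_mixed_fit")
}

#' @exportS3Method base::print
print.eod_mixed_fit <- function(x, ...) {
  cat("<eod_mixed_fit>\n  fixed:",
      paste(sprintf("%s = %.4g", names(x$fixed), x$fixed), collapse = ", "),
      sprintf("\n  sigma_beta^2 = %.3g, sigma_eps^2 = %.3g%s\n",
              x$sigma_beta2, x$sigma_eps2,
              if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' Joint test of any concentration effect (2 degrees of freedom)
#'
#' Likelihood-ratio test of `{d1 = 0 and d12 = 0}` in the split-plot model,
#' comparing maximum-likelihood refits of the full model against the model
#' with both concentration terms removed, against a chi-square reference
#' with 2 degrees of freedom. `data` must contain exactly two treatment
#' levels (one concentration plus control).
#'
#' @param data as for [fit_mixed_model()], restricted to two levels.
#' @return list with `statistic`, `df`, `p_value`, `converged`.
#' @export
joint_concentration_test <- function(data) {
  levels_present <- sort(unique(data$concentration_ul_l))
  if (length(levels_present) != 2)
    eod_stop("data must contain exactly two treatment levels",
             "eod_bad_config")
  data$unit <- interaction(data$concentration_ul_l, data$fish, drop = TRUE)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ concentration_ul_l + t_min + concentration_ul_l:t_min +
                 (1 | unit), data = data, REML = FALSE, control = ctrl))),
    error = function(e) NULL)
  red <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ t_min + (1 | unit), data = data, REML = FALSE,
               control = ctrl))),
    error = function(e) NULL)
  if (is.null(full) || is.null(red))
    eod_stop("mixed-model fit did not converge for the joint test",
             "eod_fit_failed")
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(red))))
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       converged = TRUE)
}

#' Sliding-window recovery time with sequential Bonferroni correction
#'
#' For windows `q = 0, 1, ..., q_max`, the split-plot model is fitted on the
#' data restricted to time indices `k in {q+1, ..., q+window_len}` and the
#' joint 2-df concentration test computed. At step `r` (window `q = r - 1`)
#' the raw p-value is Bonferroni-adjusted by the number of windows examined
#' so far (multiplied by `r`); the recovery time `t_r` is the start time
#' `t_{q+1} = r/2` min of the first window whose adjusted test is no longer
#' rejected at `alpha`.
#'
#' With `cumulative = TRUE`, step `r` instead tests the pooled data of
#' windows `1..r` (`k in {2, ..., r + window_len}`), the alternative reading
#' of a joint null over all windows examined so far.
#'
#' @param data as for [fit_mixed_model()]: two treatment levels on the
#'   common `k` grid (column `k` required, `t_min = k/2`).
#' @param window_len window length in samples (default 15, i.e. 7.5 min).
#' @param alpha significance level (default 0.01).
#' @param q_max last window start index; default runs to the end of the
#'   grid. Signals an error if `q_max + window_len` exceeds the grid.
#' @param cumulative use the cumulative pooled-window reading?
#' @return list of class `eod_recovery_time` with `r`, `t_r_min`,
#'   `p_raw`, `p_adjusted` (vectors over examined windows), `alpha`,
#'   `recovered` (FALSE when every window stayed significant).
#' @export
recovery_time <- function(data, window_len = 15, alpha = 0.01, q_max = NULL,
                          cumulative = FALSE) {
  if (!"k" %in% names(data))
    eod_stop("data must carry the time index column k", "eod_bad_config")
  k_max <- max(data$k)
  if (is.null(q_max)) q_max <- k_max - window_len
  if (q_max + window_len > k_max)
    eod_stop("windows exceed the time grid", "eod_bad_config")
  p_raw <- p_adj <- numeric(0)
  for (r in seq_len(q_max + 1L)) {
    q <- r - 1L
    ks <- if (cumulative) seq(2L, q + window_len) else seq(q + 1L, q + window_len)
    sub <- data[data$k %in% ks, , drop = FALSE]
    p <- tryCatch(joint_concentration_test(sub)$p_value,
                  error = function(e) NA_real_)
    if (is.na(p)) {
      warning(sprintf("window q = %d skipped (non-convergent fit)", q))
      p_raw <- c(p_raw, NA_real_); p_adj <- c(p_adj, NA_real_)
      next
    }
    p_raw <- c(p_raw, p)
    p_adj <- c(p_adj, min(1, p * r))
    if (p_adj[length(p_adj)] >= alpha) {
      return(structure(list(r = r, t_r_min = r / 2, p_raw = p_raw,
                            p_adjusted = p_adj, alpha = alpha,
                            recovered = TRUE, cumulative = cumulative),
                       class = "eod_recovery_time"))
    }
  }
  structure(list(r = NA_integer_, t_r_min = NA_real_, p_raw = p_raw,
                 p_adjusted = p_adj, alpha = alpha, recovered = FALSE,
                 cumulative = cumulative),
            class = "eod_recovery_time")
}

#' @exportS3Method base::print
print.eod_recovery_time <- function(x, ...) {
  if (x$recovered) {
    cat(sprintf("<eod_recovery_time> recovered at window r = %d (t_r = %.1f min)\n",
                x$r, x$t_r_min))
  } else {
    cat("<eod_recovery_time> no recovery within the examined windows\n")
  }
  invisible(x)
}
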