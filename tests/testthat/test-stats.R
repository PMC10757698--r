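test_that("exact sign-test p-values match the study's splits", {
  expect_equal(sign_test_exact(rep(-1, 8))$p_value, 0.0078125)
  st <- sign_test_exact(c(rep(1, 6), rep(-1, 2)))
  expect_equal(st$p_value, 74 / 256)          # 0.2891
  expect_equal(st$n_positive, 6)
  expect_equal(sign_test_exact(c(rep(1, 5), rep(-1, 3)))$p_value, 186 / 256)  # 0.7266
})

test_that("sign-test p agrees with brute-force enumeration of all sign patterns", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.1, 5)
    st <- sign_test_exact(d)
    expect_equal(st$p_value,
                 sign_test_enumeration(st$n, min(st$n_positive, st$n_negative)))
  }
})

test_that("ties are dropped and all-tie input is rejected", {
  st <- sign_test_exact(c(2, -3, 0, 0, 1))
  expect_equal(st$n, 3)
  expect_error(sign_test_exact(c(0, 0, 0)), class = "eod_undefined_test")
  # even splits give p = 1
  expect_equal(sign_test_exact(c(1, -1, 2, -2))$p_value, 1)
})

test_that("the minimal-n design rule matches its defining property", {
  expect_identical(min_n_for_sign_test(0.01), 8L)
  expect_identical(min_n_for_sign_test(0.05), 6L)
  for (alpha in c(0.1, 0.05, 0.01, 0.005, 0.001)) {
    n <- min_n_for_sign_test(alpha)
    expect_lt(sign_test_exact(rep(1, n))$p_value, alpha)
    expect_gte(sign_test_exact(rep(1, n - 1))$p_value, alpha)
  }
  expect_error(min_n_for_sign_test(0), class = "eod_bad_config")
})

test_that("the split-plot fit on noise-free data equals ordinary least squares", {
  delta <- c(1, -0.002, 5e-4, 1e-5)
  dat <- simulate_mixed_data(delta, sigma_beta = 0, sigma_eps = 0,
                             ks = 1:20)
  fit <- fit_mixed_model(dat)
  ls <- stats::lm(y ~ concentration_ul_l + t_min + concentration_ul_l:t_min,
                  data = dat)
  expect_equal(unname(fit$fixed), unname(stats::coef(ls)), tolerance = 1e-8)
  expect_equal(unname(fit$fixed), delta, tolerance = 1e-8)
})

test_that("fixed effects are recovered within 3 standard errors in simulation", {
  delta <- c(1, -0.002, 5e-4, 1e-5)
  set.seed(17)
  hits <- replicate(20, {
    dat <- simulate_mixed_data(delta, sigma_beta = 0.02, sigma_eps = 0.01,
                               ks = 1:30)
    fit <- fit_mixed_model(dat)
    se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))
    all(abs(fit$fixed - delta) <= 3 * se)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the fish variance component collapses when fish effects are absent", {
  set.seed(19)
  dat <- simulate_mixed_data(sigma_beta = 0, sigma_eps = 0.01, ks = 1:30)
  fit <- fit_mixed_model(dat)
  expect_lt(fit$sigma_beta2, 0.2 * fit$sigma_eps2)
  expect_equal(fit$sigma_eps2, 1e-4, tolerance = 0.3)
})

test_that("the joint concentration test separates null copies from real effects", {
  set.seed(23)
  base <- simulate_mixed_data(c(1, 0, 5e-4, 0), sigma_beta = 0.01,
                              sigma_eps = 0.01, concs = 0, ks = 1:15)
  copy <- base
  copy$concentration_ul_l <- 60
  p_null <- joint_concentration_test(rbind(base, copy))$p_value
  expect_gt(p_null, 0.5)  # concentration group is an exact copy of control

  strong <- simulate_mixed_data(c(1, 0.3 / 60, 5e-4, 0), sigma_beta = 0.001,
                                sigma_eps = 0.01, ks = 1:15)
  expect_lt(joint_concentration_test(strong)$p_value, 1e-6)
  expect_error(joint_concentration_test(base), class = "eod_bad_config")
})

test_that("recovery time fires at the first window for identical groups", {
  set.seed(29)
  base <- simulate_mixed_data(c(1, 0, 5e-4, 0), sigma_beta = 0.01,
                              sigma_eps = 0.01, concs = 0, ks = 1:60)
  copy <- base
  copy$concentration_ul_l <- 60
  rt <- recovery_time(rbind(base, copy), q_max = 30)
  expect_true(rt$recovered)
  expect_equal(rt$r, 1L)
  expect_equal(rt$t_r_min, 0.5)
})

test_that("Bonferroni-adjusted p-values never undercut raw ones and windows stay on the grid", {
  set.seed(31)
  dat <- simulate_mixed_data(c(1, -0.005, 0, 1e-4), sigma_beta = 0.005,
                             sigma_eps = 0.01, ks = 1:45)
  rt <- recovery_time(dat, q_max = 30)
  ok <- !is.na(rt$p_raw)
  expect_true(all(rt$p_adjusted[ok] >= rt$p_raw[ok]))
  expect_true(all(rt$p_adjusted[ok] <= 1))
  expect_error(recovery_time(dat, q_max = 60), class = "eod_bad_config")
})

test_that("recovery time is invariant to relabeling fish", {
  set.seed(37)
  dat <- simulate_mixed_data(c(1, -0.001, 2e-4, 2e-5), sigma_beta = 0.01,
                             sigma_eps = 0.01, ks = 1:40)
  rt1 <- recovery_time(dat, q_max = 20)
  relabeled <- dat
  perm <- sample(8)
  relabeled$fish <- perm[relabeled$fish]
  rt2 <- recovery_time(relabeled, q_max = 20)
  expect_equal(rt2$r, rt1$r)
  expect_equal(rt2$p_raw, rt1$p_raw, tolerance = 1e-6)
})

test_that("mixed_model_data aligns per-recording series on the k grid", {
  s1 <- data.frame(t_min = (1:10) / 2, y = 1)
  s2 <- data.frame(t_min = (1:10) / 2 + 0.004, y = 2)  # slight stamp offset
  dat <- mixed_model_data(list(s1, s2), fish = c(1, 1),
                          concentration = c(0, 60), t_grid_min = (1:10) / 2)
  expect_equal(nrow(dat), 20)
  expect_equal(dat$k, rep(1:10, 2))
  expect_equal(dat$t_min, rep((1:10) / 2, 2))
})

test_that("more measurement noise shortens the estimated recovery time", {
  # lower power => the sliding-window test stops rejecting earlier
  p60 <- table2_params$`60`
  med_t_r <- vapply(c(0.01, 0.04), function(sd) {
    t_r <- vapply(1:3, function(seed) {
      set.seed(seed)
      grid <- expand.grid(k = 1:360, fish = 1:8,
                          concentration_ul_l = c(0, 60))
      grid$t_min <- grid$k / 2
      mu <- ifelse(grid$concentration_ul_l > 0,
                   evaluate_recovery_model(p60, grid$t_min), 1)
      grid$y <- mu + rnorm(nrow(grid), 0, sd)
      recovery_time(grid)$t_r_min
    }, numeric(1))
    stats::median(t_r)
  }, numeric(1))
  expect_lt(med_t_r[2], med_t_r[1])
})
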