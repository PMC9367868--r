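# Primary growth model: explicit solution, fitting, threshold crossing.

test_that("explicit solution starts at y0, saturates at ymax, never decreases", {
  p <- baranyi_params(y0 = 5.41, ymax = 8.09, mu = 0.224, lag = 8.44)
  expect_identical(baranyi_log_count(0, p), 5.41)
  expect_equal(baranyi_log_count(500, p), 8.09, tolerance = 1e-6)
  tt <- seq(0, 60, by = 0.05)
  y <- baranyi_log_count(tt, p)
  expect_true(all(diff(y) >= -1e-12))
  expect_true(all(y >= 5.41 - 1e-12 & y <= 8.09 + 1e-12))
  # y(0) = y0 exactly across random draws
  withr::with_seed(11, {
    for (i in 1:20) {
      pr <- random_baranyi_params()
      expect_identical(baranyi_log_count(0, pr), pr$y0)
    }
  })
})

test_that("explicit solution agrees with RK4 integration of the differential form", {
  p <- baranyi_params(y0 = 5.41, ymax = 8.09, mu = 0.224, lag = 8.44)
  horizon <- 3 * (p$lag + (p$ymax - p$y0) / p$mu)
  tt <- seq(0, horizon, length.out = 400)
  expect_lt(max(abs(baranyi_log_count(tt, p) - rk4_baranyi(p, tt))), 1e-6)
  # mid-exponential spot value against the RK4 oracle on a fine grid
  fine <- seq(0, 14, length.out = 141)
  expect_equal(baranyi_log_count(14, p), rk4_baranyi(p, fine)[141],
               tolerance = 1e-7)
  expect_gt(baranyi_log_count(14, p), 5.41)
  expect_lt(baranyi_log_count(14, p), 8.09)
  # no-lag variant too
  p0 <- baranyi_params(4.5, 8.5, 0.4, 0)
  tt0 <- seq(0, 30, length.out = 300)
  expect_lt(max(abs(baranyi_log_count(tt0, p0) - rk4_baranyi(p0, tt0))), 1e-6)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(baranyi_params(8, 7, 0.3), class = "ttishelf_error_domain")
  expect_error(baranyi_params(5, 8, -0.1), class = "ttishelf_error_domain")
  expect_error(baranyi_params(5, 8, 0.3, lag = -1),
               class = "ttishelf_error_domain")
  p <- baranyi_params(5, 8, 0.3)
  expect_error(baranyi_log_count(-1, p), class = "ttishelf_error_domain")
})

test_that("time_to_threshold matches the linear-phase closed forms", {
  # huge ymax, no lag: growth linear in log10, crossing at (7-5)/0.5 = 4 d
  p <- baranyi_params(5, 1e6, 0.5, 0)
  expect_equal(time_to_threshold(p, 7), 4, tolerance = 1e-8)
  # a lag shifts the linear phase by ~lag
  p_lag <- baranyi_params(5, 1e6, 0.5, 2)
  expect_equal(time_to_threshold(p_lag, 7), 6, tolerance = 0.02)
  # braking near ymax slows the approach relative to the linear phase
  p_brake <- baranyi_params(5, 7.5, 0.5, 0)
  expect_gt(time_to_threshold(p_brake, 7), 4)
  # crossing time returned is an actual root
  t7 <- time_to_threshold(p_brake, 7)
  expect_equal(baranyi_log_count(t7, p_brake), 7, tolerance = 1e-7)
})

test_that("time_to_threshold is monotone in lag and mu and handles edge cases", {
  base <- function(lag, mu) baranyi_params(5, 9, mu, lag)
  t_by_lag <- vapply(c(0, 1, 3, 6), function(l) {
    time_to_threshold(base(l, 0.5), 7)
  }, numeric(1))
  expect_true(all(diff(t_by_lag) > 0))
  t_by_mu <- vapply(c(0.2, 0.4, 0.8, 1.6), function(m) {
    time_to_threshold(base(2, m), 7)
  }, numeric(1))
  expect_true(all(diff(t_by_mu) < 0))
  p <- base(0, 0.5)
  expect_warning(t0 <- time_to_threshold(p, 4.5),
                 class = "ttishelf_warning_threshold")
  expect_identical(t0, 0)
  expect_error(time_to_threshold(p, 9.5), class = "ttishelf_error_domain")
  expect_identical(time_to_threshold(p, 9), Inf)
})

test_that("fit inverts noiseless model output to high precision", {
  p <- baranyi_params(4.54, 8.48, 0.294, 2.88)
  curve <- gen_growth_curve(p, times = seq(0, 25, length.out = 15),
                            noise_sd = 0, seed = 1)
  fit <- fit_baranyi(curve)
  est <- fit$params
  for (nm in c("y0", "ymax", "mu", "lag")) {
    expect_equal(est[[nm]], p[[nm]], tolerance = 1e-6)
  }
  expect_gt(fit$r_squared, 1 - 1e-10)
  # no-lag truth under auto selection: lag is dropped
  p0 <- baranyi_params(4.5, 8.5, 0.4, 0)
  fit0 <- fit_baranyi(gen_growth_curve(p0, noise_sd = 0, seed = 2))
  expect_identical(fit0$params$lag, 0)
  expect_equal(fit0$params$mu, 0.4, tolerance = 1e-6)
})

test_that("fit recovers truth within uncertainty under plate-count noise", {
  p <- baranyi_params(4.54, 8.48, 0.294, 2.88)
  curve <- gen_growth_curve(p, times = seq(0, 25, length.out = 12),
                            noise_sd = 0.15, seed = 42)
  fit <- fit_baranyi(curve, with_lag = "with")
  td <- tidy(fit)
  truth <- c(y0 = 4.54, ymax = 8.48, mu = 0.294, lag = 2.88)
  for (i in seq_len(nrow(td))) {
    expect_lt(abs(td$estimate[i] - truth[[td$term[i]]]),
              3 * td$std.error[i] + 1e-9)
  }
})

test_that("degenerate inputs raise typed errors", {
  flat <- tibble::tibble(time_d = 0:6, log10_count = rep(5, 7))
  expect_error(fit_baranyi(flat), class = "ttishelf_error_no_growth")
  falling <- tibble::tibble(time_d = 0:6,
                            log10_count = seq(7, 4, length.out = 7))
  expect_error(fit_baranyi(falling), class = "ttishelf_error_no_growth")
  few <- tibble::tibble(time_d = 0:2, log10_count = c(4, 5, 6))
  expect_error(fit_baranyi(few), class = "ttishelf_error_domain")
})

test_that("unobserved plateau pins ymax to max observation plus margin", {
  p <- baranyi_params(4, 12, 0.3, 1)
  # sample only the early exponential phase
  curve <- gen_growth_curve(p, times = seq(0, 10, length.out = 8),
                            noise_sd = 0.05, seed = 7)
  fit <- fit_baranyi(curve, ymax_margin = 0.5)
  expect_true(fit$ymax_fixed)
  expect_equal(fit$params$ymax, max(curve$log10_count) + 0.5)
})
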