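# Non-isothermal prediction and validation.

test_that("effective temperature: identity, Jensen bound and permutation invariance", {
  const <- temperature_profile(10, 4.8)
  expect_equal(effective_temperature(const, Ea = 113100), 4.8,
               tolerance = 1e-12)
  # square wave with equal dwell: above the arithmetic mean, inside the range
  sq <- temperature_profile(rep(1, 10), rep(c(2, 8), 5))
  teff <- effective_temperature(sq, Ea = 113100)
  expect_gt(teff, 5)
  expect_lt(teff, 8)
  expect_gt(teff, 2)
  # matches a direct evaluation of the segment average + inversion
  fac <- exp(-113100 / 8.314 * inv_dev(c(2, 8)))
  inv <- 1 / 277.15 - 8.314 * log(mean(fac)) / 113100
  expect_equal(teff, 1 / inv - 273.15, tolerance = 1e-9)
  # Ea -> 0 limit: duration-weighted arithmetic mean
  wavg <- temperature_profile(c(3, 1), c(2, 10))
  expect_equal(effective_temperature(wavg, Ea = 0), 4, tolerance = 1e-12)
  # permuting equal-duration segments leaves Teff unchanged
  perm <- temperature_profile(rep(1, 10), rep(c(8, 2), 5))
  expect_equal(effective_temperature(perm, 113100), teff, tolerance = 1e-12)
  expect_error(temperature_profile(numeric(0), numeric(0)),
               class = "ttishelf_error_domain")
  expect_error(temperature_profile(c(1, -1), c(2, 8)),
               class = "ttishelf_error_domain")
})

test_that("dynamic prediction reduces to the explicit solution at constant Tref", {
  p <- baranyi_params(5.41, 8.09, 0.224, 8.44)
  fit <- arrhenius_fit(kref = 0.224, Ea = 113100)
  traj <- predict_growth_dynamic(p, fit, temperature_profile(40, 4))
  expect_lt(max(abs(traj$log10_count - baranyi_log_count(traj$time_d, p))),
            1e-6)
  # lag 0: growth starts immediately
  p0 <- baranyi_params(5, 8.5, 0.4, 0)
  traj0 <- predict_growth_dynamic(baranyi_params(5, 8.5, 0.4, 0),
                                  arrhenius_fit(0.4, 1e5),
                                  temperature_profile(10, 4))
  expect_lt(max(abs(traj0$log10_count - baranyi_log_count(traj0$time_d, p0))),
            1e-6)
})

test_that("dynamic prediction matches an independent RK4 oracle on a stepped profile", {
  p <- baranyi_params(5, 8.5, 0.411, 3.36)
  fit <- arrhenius_fit(kref = 0.411, Ea = 113100)
  prof <- temperature_profile(c(4, 4, 4), c(2, 10, 4))
  times <- seq(0, 12, by = 0.25)
  traj <- predict_growth_dynamic(p, fit, prof, times = times)
  mu_at <- function(t) {
    predict_rate(fit, ifelse(t < 4, 2, ifelse(t < 8, 10, 4)))
  }
  oracle <- rk4_baranyi(p, times, mu_at = mu_at, n_sub = 40L)
  expect_lt(max(abs(traj$log10_count - oracle)), 1e-6)
  # trajectories are non-decreasing and bounded by ymax
  expect_true(all(diff(traj$log10_count) >= -1e-12))
  expect_true(all(traj$log10_count <= 8.5 + 1e-9))
})

test_that("apparent growth rate recovers the generating rate", {
  p <- baranyi_params(5, 9, 0.5, 2)
  fit <- arrhenius_fit(kref = 0.5, Ea = 1e5)
  traj <- predict_growth_dynamic(p, fit, temperature_profile(14, 4))
  expect_equal(as.numeric(apparent_growth_rate(traj)), 0.5, tolerance = 1e-4)
  flat <- tibble::tibble(time_d = 0:9, log10_count = rep(5, 10))
  expect_error(apparent_growth_rate(flat), class = "ttishelf_error_no_growth")
})

test_that("relative error reproduces the reported validation percentages", {
  # experimental vs model-predicted rates from the dynamic validation trial
  tab <- seabream_validation_rates()
  re <- relative_error(tab$k_experimental, tab$k_predicted)
  agree <- round(re) == tab$re_percent_reported
  # the TVC rows and most others round to the reported integers; a couple of
  # reported figures differ from the recomputed value by a point or two of
  # rounding, so exact agreement is asserted only where arithmetic gives it
  expect_equal(round(relative_error(0.348, 0.398)), 14)
  expect_equal(round(relative_error(0.551, 0.524)), 5)
  expect_equal(round(relative_error(0.355, 0.244)), 31)
  expect_equal(round(relative_error(0.510, 0.486)), 5)
  expect_equal(round(relative_error(0.276, 0.351)), 27)
  expect_gte(sum(agree), 5)
  expect_identical(relative_error(0.4, 0.4), 0)
  expect_error(relative_error(0, 0.4), class = "ttishelf_error_domain")
})

test_that("validation report applies the 20% applicability limit", {
  rep <- validation_report(seabream_validation_rates())
  expect_equal(rep$pass, rep$re_percent <= 20)
  # magnitudes, not signed errors
  expect_true(all(rep$re_percent >= 0))
  tvc <- dplyr::filter(rep, organism == "TVC")
  expect_true(all(tvc$pass))
})
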