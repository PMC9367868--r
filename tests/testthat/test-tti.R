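# TTI response normalisation, logistic kinetics and the global model.

test_that("normalisation maps the calibration extremes to 0 and 1", {
  readings <- tibble::tibble(time_d = 0:3, a = c(-30, -10, 0, 20),
                             b = c(10, 10, 20, 40))
  out <- normalize_response(readings) # extremes: a+b in [-20, 60]
  expect_equal(out$norm, c(0, 0.25, 0.5, 1))
  # explicit calibration, including the midpoint case
  mid <- normalize_response(tibble::tibble(time_d = 0, a = 10, b = 10),
                            ab_min = -20, ab_max = 60)
  expect_equal(mid$norm, 0.5)
  # values outside the calibration window are clipped to [0, 1]
  clip <- normalize_response(tibble::tibble(time_d = 0:1, a = c(-30, 40),
                                            b = c(-10, 30)),
                             ab_min = -20, ab_max = 60)
  expect_equal(clip$norm, c(0, 1))
  expect_error(normalize_response(readings, ab_min = 5, ab_max = 5),
               class = "ttishelf_error_domain")
  expect_error(normalize_response(tibble::tibble(a = 70, b = 0)),
               class = "ttishelf_error_domain")
})

test_that("logistic response has the right landmarks and monotonicity", {
  expect_equal(logistic_response(10, k1 = 10, k2 = 2), 0.5)
  expect_equal(logistic_response(10 + 2 * log(4), 10, 2), 0.8,
               tolerance = 1e-12)
  tt <- seq(0, 40, by = 0.5)
  expect_true(all(diff(logistic_response(tt, 10, 2)) > 0))
  # M-25U at 5 degC: time to reach 0.8 solved numerically on the logistic
  root <- uniroot(function(t) logistic_response(t, 8.03, 1.49) - 0.8,
                  c(0, 50), tol = 1e-10)$root
  expect_equal(root, 8.03 + 1.49 * log(4), tolerance = 1e-8)
  expect_equal(root, 10.1, tolerance = 0.01)
})

test_that("logistic fit inverts noiseless data and flags degenerate series", {
  tt <- seq(0, 30, length.out = 20)
  clean <- tibble::tibble(time_d = tt, norm = logistic_response(tt, 10, 2))
  fit <- fit_logistic(clean)
  expect_equal(fit$k1, 10, tolerance = 1e-6)
  expect_equal(fit$k2, 2, tolerance = 1e-6)
  # noisy recovery within uncertainty
  noisy <- gen_tti_series(10, 2, times = tt, noise_sd = 0.03, seed = 5)
  nfit <- fit_logistic(normalize_response(noisy))
  td <- tidy(nfit)
  truth <- c(k1 = 10, k2 = 2)
  for (i in 1:2) {
    expect_lt(abs(td$estimate[i] - truth[[td$term[i]]]), 3 * td$std.error[i])
  }
  flat <- tibble::tibble(time_d = tt, norm = rep(0.5, 20))
  expect_error(fit_logistic(flat), class = "ttishelf_error_degenerate")
  expect_error(fit_logistic(clean[1:3, ]), class = "ttishelf_error_domain")
})

test_that("global model prediction collapses to the reference constants at C=1, Tref", {
  m <- reference_tti_models()$M
  kk <- predict_k1k2(m, conc = 1, temperature_c = 4)
  expect_identical(kk$k1, 128.6)
  expect_identical(kk$k2, 25.7)
})

test_that("global model forward predictions track the measured label constants", {
  m <- reference_tti_models()$M
  # direct single-expression evaluation for M-25U at 5 degC
  expected_k1 <- 128.6 * 25^(-0.861) * exp(97100 / 8.314 * inv_dev(5))
  kk <- predict_k1k2(m, 25, 5)
  expect_equal(kk$k1, expected_k1, tolerance = 1e-12)
  expect_lt(abs(kk$k1 - 8.03) / 8.03, 0.2) # measured 8.03 d
  # LP-150U at 10 degC within 10% of the measured 1.81 d
  lp <- reference_tti_models()$LP
  expect_lt(abs(predict_k1k2(lp, 150, 10)$k1 - 1.81) / 1.81, 0.1)
  # time-like: strictly decreasing in concentration and temperature
  by_c <- predict_k1k2(m, c(5, 10, 25, 50, 100), 4)
  expect_true(all(diff(by_c$k1) < 0) && all(diff(by_c$k2) < 0))
  by_t <- predict_k1k2(m, 25, seq(0, 15, by = 2.5))
  expect_true(all(diff(by_t$k1) < 0) && all(diff(by_t$k2) < 0))
})

test_that("global fit recovers exact synthetic parameters and rejects thin designs", {
  true <- tti_global_model("M", Ea = 1e5, k1ref = 150, k2ref = 30,
                           alpha = 0.9, beta = 0.8)
  design <- tidyr::expand_grid(enzyme_units = c(5, 25, 100),
                               temperature_C = c(0, 5, 10, 15))
  kk <- predict_k1k2(true, design$enzyme_units, design$temperature_C)
  fit <- fit_global_model(dplyr::bind_cols(design, kk[c("k1", "k2")]))
  for (nm in c("Ea", "k1ref", "k2ref", "alpha", "beta")) {
    expect_equal(fit[[nm]], true[[nm]], tolerance = 1e-6)
  }
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  one_conc <- dplyr::filter(tti_response_constants(), enzyme_units == 25)
  expect_error(fit_global_model(one_conc), class = "ttishelf_error_domain")
})

test_that("global fit on the measured M-type table reproduces the published Ea", {
  tab <- dplyr::filter(tti_response_constants(), tti_type == "M")
  fit <- fit_global_model(tab, tti_type = "M")
  expect_lt(abs(fit$Ea / 1000 - 97.1) / 97.1, 0.2)
})

test_that("response time inverts the logistic at the endpoint", {
  m <- reference_tti_models()$M
  kk <- predict_k1k2(m, 25, 4)
  expect_equal(response_time(m, 25, 4, endpoint = 0.5), kk$k1,
               tolerance = 1e-12)
  t80 <- response_time(m, 25, 4, endpoint = 0.8)
  expect_equal(t80, kk$k1 + kk$k2 * log(4), tolerance = 1e-12)
  # round-trip: evaluating the logistic at the response time gives the endpoint
  expect_equal(logistic_response(t80, kk$k1, kk$k2), 0.8, tolerance = 1e-9)
  # response times fall with temperature
  curve <- response_time_curve(m, 25, seq(0, 10, by = 1))
  expect_true(all(diff(curve$response_d) < 0))
  expect_error(response_time(m, 25, 4, endpoint = 1),
               class = "ttishelf_error_domain")
})
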