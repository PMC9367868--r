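#' Normalize a TTI colour-response series
#'
#' Enzymatic TTI labels change colour from green to red as their substrate is
#' hydrolysed; the response is tracked as the sum of the CIELab `a` and `b`
#' coordinates, min-max normalised to `[0, 1]`:
#' `norm(a+b) = ((a+b) - (a+b)_min) / ((a+b)_max - (a+b)_min)`.
#' By default the calibration extremes are taken from the series itself;
#' supply `ab_min`/`ab_max` to use an external calibration.
#'
#' @param data Data frame of colour readings.
#' @param a,b Columns (tidy-eval) holding the CIELab coordinates (each within
#'   -60..60). Defaults `a`, `b`.
#' @param ab_min,ab_max Optional calibration extremes for `a + b`.
#' @return The input data with a `norm` column appended (clipped to `[0, 1]`).
#' @export
normalize_response <- function(data, a = a, b = b,
                               ab_min = NULL, ab_max = NULL) {
  av <- rlang::eval_tidy(rlang::enquo(a), data)
  bv <- rlang::eval_tidy(rlang::enquo(b), data)
  if (any(!is.finite(av)) || any(!is.finite(bv))) {
    stop_domain("colour coordinates must be finite.")
  }
  if (any(abs(av) > 60) || any(abs(bv) > 60)) {
    stop_domain("CIELab a and b coordinates must lie within -60..60.")
  }
  ab <- av + bv
  ab_min <- ab_min %||% min(ab)
  ab_max <- ab_max %||% max(ab)
  if (ab_max <= ab_min) {
    stop_domain("calibration error: ab_max must exceed ab_min.")
  }
  norm <- pmin(pmax((ab - ab_min) / (ab_max - ab_min), 0), 1)
  dplyr::mutate(as_tibble(data), norm = norm)
}

#' Logistic TTI response kinetics
#'
#' The normalised TTI response over storage time follows a rising logistic,
#' `norm(t) = 1 / (1 + exp((k1 - t) / k2))`: `k1` (days) is the inflection
#' time and `1/k2` the slope of the exponential colour-change phase.
#'
#' @param t Time, days (vectorised).
#' @param k1,k2 Response rate constants, days (both > 0).
#' @return Response values in (0, 1); equals 0.5 at `t = k1`.
#' @export
logistic_response <- function(t, k1, k2) {
  check_number(k1, "k1")
  check_number(k2, "k2")
  if (k1 <= 0 || k2 <= 0) stop_domain("`k1` and `k2` must be positive.")
  1 / (1 + exp((k1 - t) / k2))
}

#' Fit logistic response kinetics to a normalised TTI series
#'
#' Nonlinear least squares of the rising logistic on the normalised response.
#' The series must span both tails of the sigmoid well enough to identify the
#' inflection time and slope.
#'
#' @param data Data frame of normalised readings.
#' @param time,response Columns (tidy-eval): time in days and normalised
#'   response. Defaults `time_d`, `norm`.
#' @return A `tti_logistic_fit` with elements `k1`, `k2`, `std_errors`,
#'   `r_squared`, `residuals`, `data`. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @export
fit_logistic <- function(data, time = time_d, response = norm) {
  tvals <- rlang::eval_tidy(rlang::enquo(time), data)
  rvals <- rlang::eval_tidy(rlang::enquo(response), data)
  keep <- is.finite(tvals) & is.finite(rvals)
  tvals <- tvals[keep]; rvals <- rvals[keep]
  if (length(tvals) < 5L) {
    stop_domain("need at least 5 points to fit the logistic response.")
  }
  if (sd(rvals) < 1e-3 || all(rvals <= 0.02) || all(rvals >= 0.98)) {
    abort("degenerate response series: no sigmoidal transition to fit.",
          class = "ttishelf_error_degenerate")
  }
  k1_start <- tvals[which.min(abs(rvals - 0.5))]
  r_clip <- pmin(pmax(rvals, 0.02), 0.98)
  logit <- log(r_clip / (1 - r_clip))
  sl <- coef(lm(logit ~ tvals))[2L]
  k2_start <- if (is.finite(sl) && sl > 0) 1 / sl else diff(range(tvals)) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rvals ~ 1 / (1 + exp((k1 - tvals) / k2)),
      start = list(k1 = max(k1_start, 1e-3), k2 = max(k2_start, 1e-3)),
      lower = c(k1 = 1e-6, k2 = 1e-6),
      upper = c(k1 = 10 * max(tvals), k2 = 10 * max(tvals)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-13)
    ),
    error = function(e) stop_fit(paste("logistic fit failed:", conditionMessage(e)))
  )
  co <- coef(fit)
  fitted_vals <- 1 / (1 + exp((co[["k1"]] - tvals) / co[["k2"]]))
  resid_vals <- rvals - fitted_vals
  r2 <- 1 - sum(resid_vals^2) / sum((rvals - mean(rvals))^2)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(k1 = NA_real_, k2 = NA_real_))
  structure(
    list(k1 = co[["k1"]], k2 = co[["k2"]],
         std_errors = c(k1 = unname(se["k1"]), k2 = unname(se["k2"])),
         r_squared = r2, residuals = resid_vals,
         data = tibble(time_d = tvals, norm = rvals)),
    class = "tti_logistic_fit"
  )
}

#' @export
print.tti_logistic_fit <- function(x, ...) {
  cat(sprintf("TTI logistic fit: k1 = %.3g d, k2 = %.3g d, R^2 = %.4f\n",
              x$k1, x$k2, x$r_squared))
  invisible(x)
}

#' Global TTI concentration-temperature model
#'
#' The per-label logistic constants scale with enzyme concentration as a power
#' law and with temperature through an Arrhenius factor:
#' `k1(C, T) = k1ref(C=1U) C^-alpha exp(+Ea/R (1/T - 1/Tref))` and
#' analogously `k2` with exponent `beta`. `k1` and `k2` are time-like, so both
#' shrink (faster response) as concentration or temperature increases.
#'
#' @param tti_type Label chemistry, `"M"` (methyl myristate substrate) or
#'   `"LP"` (trilaurin/tripalmitin).
#' @param Ea Activation energy of the response, J/mol.
#' @param k1ref,k2ref Response constants at 1 enzyme unit and the reference
#'   temperature, days.
#' @param alpha,beta Concentration exponents for `k1` and `k2`.
#' @param tref_c Reference temperature, degrees C.
#' @param r_squared Optional pooled R-squared of the underlying fit.
#' @return A `tti_global_model` object.
#' @export
tti_global_model <- function(tti_type = c("M", "LP"), Ea, k1ref, k2ref,
                             alpha, beta, tref_c = TREF_C_DEFAULT,
                             r_squared = NA_real_) {
  tti_type <- match.arg(tti_type)
  for (nm in c("Ea", "k1ref", "k2ref", "alpha", "beta")) {
    val <- get(nm)
    check_number(val, nm)
    if (val <= 0) stop_domain(sprintf("`%s` must be positive.", nm))
  }
  structure(
    list(tti_type = tti_type, Ea = Ea, k1ref = k1ref, k2ref = k2ref,
         alpha = alpha, beta = beta, tref_c = tref_c, r_squared = r_squared),
    class = "tti_global_model"
  )
}

#' @export
print.tti_global_model <- function(x, ...) {
  cat(sprintf(
    "%s-type TTI global model: Ea = %.1f kJ/mol, k1ref(1U) = %.4g d, k2ref(1U) = %.4g d, alpha = %.3g, beta = %.3g\n",
    x$tti_type, x$Ea / 1000, x$k1ref, x$k2ref, x$alpha, x$beta
  ))
  invisible(x)
}

#' Predict per-label logistic constants from the global model
#'
#' @param model A [tti_global_model()].
#' @param conc Enzyme concentration, units (> 0).
#' @param temperature_c Storage temperature, degrees C.
#' @return A tibble with columns `conc`, `temperature_C`, `k1`, `k2` (days);
#'   inputs are recycled to a common length.
#' @export
predict_k1k2 <- function(model, conc, temperature_c) {
  if (!inherits(model, "tti_global_model")) {
    stop_domain("`model` must be a `tti_global_model`.")
  }
  if (any(conc <= 0)) stop_domain("`conc` must be positive.")
  n <- max(length(conc), length(temperature_c))
  conc <- rep_len(conc, n)
  temperature_c <- rep_len(temperature_c, n)
  arrh <- exp(model$Ea / R_GAS * inv_temp_dev(temperature_c, model$tref_c))
  tibble(
    conc = conc,
    temperature_C = temperature_c,
    k1 = model$k1ref * conc^(-model$alpha) * arrh,
    k2 = model$k2ref * conc^(-model$beta) * arrh
  )
}

#' Fit the global concentration-temperature model to per-label constants
#'
#' Joint log-linear least squares of `ln k1` and `ln k2` on `ln C` and the
#' reciprocal-temperature deviation, with a single shared activation-energy
#' slope and separate intercepts and concentration exponents for the two
#' constants. The shared slope reflects the single-Ea structure of the global
#' response model.
#'
#' @param data Data frame with one row per label x temperature.
#' @param conc,temperature,k1,k2 Columns (tidy-eval): enzyme units, degrees C
#'   and the fitted logistic constants in days. Defaults `enzyme_units`,
#'   `temperature_C`, `k1`, `k2`.
#' @param tti_type Passed through to the resulting model.
#' @param tref_c Reference temperature, degrees C.
#' @return A [tti_global_model()] with pooled `r_squared` (on the log scale).
#' @export
fit_global_model <- function(data, conc = enzyme_units,
                             temperature = temperature_C, k1 = k1, k2 = k2,
                             tti_type = c("M", "LP"),
                             tref_c = TREF_C_DEFAULT) {
  tti_type <- match.arg(tti_type)
  cv <- rlang::eval_tidy(rlang::enquo(conc), data)
  tv <- rlang::eval_tidy(rlang::enquo(temperature), data)
  k1v <- rlang::eval_tidy(rlang::enquo(k1), data)
  k2v <- rlang::eval_tidy(rlang::enquo(k2), data)
  if (any(c(cv, k1v, k2v) <= 0)) {
    stop_domain("concentrations and rate constants must be positive.")
  }
  if (length(unique(cv)) < 3L || length(unique(tv)) < 3L) {
    stop_domain(
      "rank-deficient design: need >= 3 distinct concentrations and >= 3 distinct temperatures."
    )
  }
  long <- tibble(
    lnk = c(log(k1v), log(k2v)),
    lnc = rep(log(cv), 2L),
    x = rep(inv_temp_dev(tv, tref_c), 2L),
    which = rep(c("k1", "k2"), each = length(cv))
  )
  ols <- lm(lnk ~ 0 + which + which:lnc + x, data = long)
  co <- coef(ols)
  r2 <- 1 - sum(ols$residuals^2) / sum((long$lnk - mean(long$lnk))^2)
  tti_global_model(
    tti_type = tti_type,
    Ea = R_GAS * co[["x"]],
    k1ref = exp(co[["whichk1"]]),
    k2ref = exp(co[["whichk2"]]),
    alpha = -co[["whichk1:lnc"]],
    beta = -co[["whichk2:lnc"]],
    tref_c = tref_c,
    r_squared = r2
  )
}

#' Time for a TTI label to reach its visual endpoint
#'
#' Inverts the logistic response at the endpoint:
#' `t = k1 + k2 ln(endpoint / (1 - endpoint))`, with `(k1, k2)` from
#' [predict_k1k2()]. The manufacturer's visual endpoint (orange-red) sits at
#' a normalised response of 0.8.
#'
#' @param model A [tti_global_model()].
#' @param conc Enzyme concentration, units.
#' @param temperature_c Storage temperature(s), degrees C.
#' @param endpoint Normalised response defining label expiry, in (0, 1).
#' @return Response time(s), days.
#' @export
response_time <- function(model, conc, temperature_c, endpoint = 0.8) {
  check_number(endpoint, "endpoint")
  if (endpoint <= 0 || endpoint >= 1) {
    stop_domain("`endpoint` must lie strictly inside (0, 1).")
  }
  kk <- predict_k1k2(model, conc, temperature_c)
  kk$k1 + kk$k2 * log(endpoint / (1 - endpoint))
}

#' TTI response time as a function of storage temperature
#'
#' @inheritParams response_time
#' @param temperatures_c Temperature grid, degrees C.
#' @return A tibble with columns `temperature_C` and `response_d`.
#' @export
response_time_curve <- function(model, conc, temperatures_c, endpoint = 0.8) {
  tibble(
    temperature_C = temperatures_c,
    response_d = response_time(model, conc, temperatures_c, endpoint)
  )
}
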