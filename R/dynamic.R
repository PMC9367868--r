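#' Piecewise-constant temperature profile
#'
#' Represents a cold-chain temperature history as contiguous constant-
#' temperature segments starting at time 0, the natural form of logger data
#' and of programmed validation scenarios.
#'
#' @param durations_d Segment durations, days (all > 0).
#' @param temperatures_c Segment temperatures, degrees C (within -5..25).
#' @return A `temperature_profile` object: a tibble of segments
#'   (`start_d`, `end_d`, `temperature_C`) with a `total_duration_d`
#'   attribute.
#' @examples
#' pr <- temperature_profile(c(2, 1, 2), c(2, 8, 4))
#' effective_temperature(pr, Ea = 113100)
#' @export
temperature_profile <- function(durations_d, temperatures_c) {
  if (length(durations_d) != length(temperatures_c) ||
      length(durations_d) == 0L) {
    stop_domain("durations and temperatures must be equal-length, non-empty.")
  }
  if (any(!is.finite(durations_d)) || any(durations_d <= 0)) {
    stop_domain("segment durations must be positive.")
  }
  if (any(temperatures_c < -5 | temperatures_c > 25)) {
    stop_domain("segment temperatures must lie within -5..25 degC.")
  }
  ends <- cumsum(durations_d)
  structure(
    tibble(
      start_d = c(0, ends[-length(ends)]),
      end_d = ends,
      temperature_C = temperatures_c
    ),
    total_duration_d = ends[length(ends)],
    class = c("temperature_profile", "tbl_df", "tbl", "data.frame")
  )
}

profile_duration <- function(profile) attr(profile, "total_duration_d")

#' Temperature at given times along a profile
#'
#' @param profile A [temperature_profile()].
#' @param time_d Times, days, within `[0, total duration]`.
#' @return Temperatures, degrees C (right-continuous step function).
#' @export
profile_temperature <- function(profile, time_d) {
  idx <- findInterval(time_d, profile$start_d, rightmost.closed = FALSE)
  idx[time_d >= profile_duration(profile)] <- nrow(profile)
  profile$temperature_C[pmax(idx, 1L)]
}

#' Effective temperature of a dynamic profile
#'
#' The effective temperature is the constant temperature that produces the
#' same integrated Arrhenius effect as the variable profile over the same
#' duration: it solves
#' `exp(-Ea/R (1/Teff - 1/Tref)) = (1/D) sum_i d_i exp(-Ea/R (1/T_i - 1/Tref))`
#' and is inverted in closed form. By Jensen's inequality it is at least the
#' duration-weighted arithmetic mean temperature (for `Ea > 0`); in the
#' `Ea -> 0` limit the inversion degenerates and the weighted arithmetic mean
#' is returned.
#'
#' @param profile A [temperature_profile()].
#' @param Ea Activation energy of the process being integrated, J/mol.
#' @param tref_c Reference temperature, degrees C (cancels out of the
#'   result; kept for interface symmetry).
#' @return Effective temperature, degrees C.
#' @export
effective_temperature <- function(profile, Ea, tref_c = TREF_C_DEFAULT) {
  if (!inherits(profile, "temperature_profile")) {
    stop_domain("`profile` must be a `temperature_profile`.")
  }
  check_number(Ea, "Ea", lower = 0)
  dur <- profile$end_d - profile$start_d
  total <- sum(dur)
  if (total <= 0) stop_domain("profile has zero total duration.")
  w <- dur / total
  if (Ea < 1e-9) {
    return(sum(w * profile$temperature_C))
  }
  factor <- exp(-Ea / R_GAS * inv_temp_dev(profile$temperature_C, tref_c))
  avg <- sum(w * factor)
  inv_teff <- 1 / celsius_to_kelvin(tref_c) - R_GAS * log(avg) / Ea
  kelvin_to_celsius(1 / inv_teff)
}

#' Predict microbial growth under a dynamic temperature profile
#'
#' Integrates the differential (physiological-state) form of the Baranyi
#' model under a time-varying temperature: `dq/dt = mu(T(t)) q` and
#' `dy/dt = mu(T(t)) q/(1+q) (1 - exp(y - ymax))` in natural-log
#' concentration units, with `mu(T)` supplied by the Arrhenius rate model.
#' The initial physiological state is set from the reference-temperature lag,
#' `q0 = 1 / (exp(mu(Tref) lag) - 1)`; with `lag = 0` the culture starts
#' fully adapted (`q0` large, growth immediate).
#'
#' @param params [baranyi_params()] at the reference temperature of
#'   `rate_model` (`y0`, `ymax`, and the reference lag; `mu` is ignored in
#'   favour of `rate_model`'s `kref`).
#' @param rate_model A rate-like [arrhenius_fit()] giving `mu(T)` in
#'   log10 CFU/g per day.
#' @param profile A [temperature_profile()].
#' @param times Output times, days (default: a 201-point grid over the
#'   profile, plus segment boundaries).
#' @return A tibble with columns `time_d`, `temperature_C`, `log10_count`.
#' @export
predict_growth_dynamic <- function(params, rate_model, profile, times = NULL) {
  if (!inherits(params, "baranyi_params")) {
    stop_domain("`params` must be a `baranyi_params` object.")
  }
  if (!inherits(rate_model, "arrhenius_fit") || rate_model$direction != "rate") {
    stop_domain("`rate_model` must be a rate-like `arrhenius_fit`.")
  }
  if (!inherits(profile, "temperature_profile")) {
    stop_domain("`profile` must be a `temperature_profile`.")
  }
  total <- profile_duration(profile)
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, total, length.out = 201L), profile$end_d)))
  }
  if (any(times < 0 | times > total + 1e-9)) {
    stop_domain("output times must lie within the profile duration.")
  }
  ln10 <- log(10)
  y0n <- params$y0 * ln10
  ymaxn <- params$ymax * ln10
  mu_ref_n <- predict_rate(rate_model, rate_model$tref_c) * ln10
  lnq0 <- if (params$lag > 0) {
    -log(expm1(mu_ref_n * params$lag))
  } else {
    log(1e9) # fully adapted: adjustment factor q/(1+q) is 1 to ~1e-9
  }
  state <- c(lnq = lnq0, y = y0n)
  out_t <- numeric(0)
  out_y <- numeric(0)
  for (i in seq_len(nrow(profile))) {
    seg_times <- times[times >= profile$start_d[i] - 1e-12 &
                         times <= profile$end_d[i] + 1e-12]
    span <- sort(unique(c(profile$start_d[i], seg_times, profile$end_d[i])))
    mu_n <- predict_rate(rate_model, profile$temperature_C[i]) * ln10
    rhs <- function(t, s, p) {
      adj <- 1 / (1 + exp(-s[1L])) # s = (ln q, y)
      brake <- 1 - exp(s[2L] - ymaxn)
      list(c(mu_n, mu_n * adj * brake))
    }
    sol <- deSolve::ode(
      y = state, times = span, func = rhs, parms = NULL,
      method = "lsoda", rtol = 1e-10, atol = 1e-10
    )
    if (attr(sol, "istate")[1L] < 0) {
      stop_fit(sprintf("ODE integration failed in segment %d.", i))
    }
    keep <- sol[, "time"] %in% seg_times
    out_t <- c(out_t, sol[keep, "time"])
    out_y <- c(out_y, sol[keep, "y"])
    state <- c(lnq = unname(sol[nrow(sol), "lnq"]),
               y = unname(sol[nrow(sol), "y"]))
  }
  ord <- !duplicated(out_t)
  tibble(
    time_d = out_t[ord],
    temperature_C = profile_temperature(profile, out_t[ord]),
    log10_count = out_y[ord] / ln10
  )
}

#' Apparent growth rate of a trajectory or observed curve
#'
#' Fits the Baranyi model to a (possibly model-generated) log-count
#' trajectory and returns its maximum growth rate — the quantity compared
#' between experiment and prediction in non-isothermal validation.
#'
#' @inheritParams fit_baranyi
#' @param ... Passed on to [fit_baranyi()].
#' @return The fitted growth rate (log10 CFU/g per day) with the full
#'   `baranyi_fit` attached as attribute `"fit"`.
#' @export
apparent_growth_rate <- function(data, time = time_d, count = log10_count,
                                 ...) {
  fit <- fit_baranyi(data, time = {{ time }}, count = {{ count }}, ...)
  structure(fit$params$mu, fit = fit)
}

#' Relative error between experimental and predicted rates
#'
#' `RE% = |(k_experimental - k_predicted) / k_experimental| * 100`, the
#' validation metric for non-isothermal predictions; models are considered
#' applicable when the relative error does not exceed 20%.
#'
#' @param k_experimental,k_predicted Growth rates (experimental must be > 0).
#'   Vectorised.
#' @return Relative error in percent (magnitude, full precision).
#' @seealso [validation_report()] for the tabulated pass/fail form.
#' @export
relative_error <- function(k_experimental, k_predicted) {
  if (any(!is.finite(k_experimental)) || any(k_experimental <= 0)) {
    stop_domain("`k_experimental` must be positive.")
  }
  abs((k_experimental - k_predicted) / k_experimental) * 100
}

#' Tabulated validation of predicted against experimental rates
#'
#' @param data Data frame with experimental and predicted rates.
#' @param k_experimental,k_predicted Columns (tidy-eval). Defaults to those
#'   names.
#' @param limit Applicability limit on RE, percent (default 20).
#' @return The input tibble with `re_percent` (magnitude, full precision),
#'   `re_rounded` (nearest integer percent, the conventional reporting form)
#'   and `pass` columns appended.
#' @export
validation_report <- function(data, k_experimental = k_experimental,
                              k_predicted = k_predicted, limit = 20) {
  ke <- rlang::eval_tidy(rlang::enquo(k_experimental), data)
  kp <- rlang::eval_tidy(rlang::enquo(k_predicted), data)
  re <- relative_error(ke, kp)
  dplyr::mutate(
    as_tibble(data),
    re_percent = re,
    re_rounded = round(re),
    pass = re <= limit
  )
}
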