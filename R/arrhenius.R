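#' Construct an Arrhenius secondary model
#'
#' Describes the temperature dependence of a kinetic quantity through
#' `ln k = ln kref -/+ Ea/R (1/T - 1/Tref)`. Rate-like quantities (growth
#' rates, reaction rates) increase with temperature and carry the minus sign;
#' time-like quantities (lag phases, response-time constants) lengthen as
#' temperature drops and carry the plus sign.
#'
#' @param kref Value of the quantity at the reference temperature (> 0).
#' @param Ea Activation energy, J/mol (>= 0).
#' @param tref_c Reference temperature, degrees C (default 4).
#' @param direction `"rate"` or `"time"`.
#' @param r_squared Optional coefficient of determination of the underlying
#'   regression.
#' @param std_errors Optional named numeric vector (`ln_kref`, `Ea`).
#' @return An `arrhenius_fit` object.
#' @export
arrhenius_fit <- function(kref, Ea, tref_c = TREF_C_DEFAULT,
                          direction = c("rate", "time"),
                          r_squared = NA_real_, std_errors = NULL) {
  direction <- match.arg(direction)
  check_number(kref, "kref")
  check_number(Ea, "Ea")
  check_number(tref_c, "tref_c", lower = -273.15)
  if (kref <= 0) stop_domain("`kref` must be positive.")
  structure(
    list(kref = kref, Ea = Ea, tref_c = tref_c, direction = direction,
         r_squared = r_squared, std_errors = std_errors),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius model (%s-like): kref = %.4g at %g degC, Ea = %.1f kJ/mol",
    x$direction, x$kref, x$tref_c, x$Ea / 1000
  ))
  if (is.finite(x$r_squared)) cat(sprintf(", R^2 = %.3f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Fit the Arrhenius equation to rates or lag times across temperatures
#'
#' Ordinary least squares of `ln(value)` on the reciprocal-temperature
#' deviation `1/T - 1/Tref`. The slope `s` gives the activation energy:
#' `Ea = -R s` for rate-like quantities, `Ea = +R s` for time-like ones; the
#' intercept gives `ln kref`. Inverse-variance weighting is applied when a
#' `std_error` column is supplied and `weighted = TRUE`.
#'
#' @param data Data frame with one row per temperature.
#' @param temperature,value Columns (tidy-eval) holding temperature in degrees
#'   C and the positive kinetic quantity. Defaults `temperature_C`, `value`.
#' @param direction `"rate"` (e.g. growth rates) or `"time"` (e.g. lag).
#' @param tref_c Reference temperature, degrees C.
#' @param weighted Use inverse-variance weights from a `std_error` column.
#' @return An [arrhenius_fit()] object; supports [tidy()] and [glance()].
#' @examples
#' rates <- tibble::tibble(temperature_C = c(0, 2.5, 5, 10),
#'                         value = c(0.224, 0.294, 0.51, 1.07))
#' fit <- fit_arrhenius(rates)
#' fit$Ea / 1000 # kJ/mol
#' @export
fit_arrhenius <- function(data, temperature = temperature_C, value = value,
                          direction = c("rate", "time"),
                          tref_c = TREF_C_DEFAULT, weighted = FALSE) {
  direction <- match.arg(direction)
  temps <- rlang::eval_tidy(rlang::enquo(temperature), data)
  vals <- rlang::eval_tidy(rlang::enquo(value), data)
  if (any(!is.finite(temps)) || any(!is.finite(vals))) {
    stop_domain("temperatures and values must be finite.")
  }
  if (length(unique(temps)) < 3L) {
    stop_domain("need values at >= 3 distinct temperatures for an Arrhenius fit.")
  }
  if (any(vals <= 0)) {
    stop_domain("all values must be positive (the model is fitted on ln(value)).")
  }
  x <- inv_temp_dev(temps, tref_c)
  w <- NULL
  if (weighted && "std_error" %in% names(data)) {
    se <- data$std_error
    # delta-method variance of ln(value)
    w <- (vals / se)^2
  }
  ols <- lm(log(vals) ~ x, weights = w)
  slope <- coef(ols)[[2L]]
  ea <- if (direction == "rate") -R_GAS * slope else R_GAS * slope
  if (ea < 0) {
    warn(sprintf(
      "fitted Ea is negative (%.3g kJ/mol): values trend the wrong way for a %s-like quantity.",
      ea / 1000, direction
    ), class = "ttishelf_warning_ea_negative")
  }
  # summary.lm warns on noiseless (zero-residual) input; that case is exact
  smry <- withCallingHandlers(
    summary(ols),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  se_tab <- smry$coefficients[, "Std. Error"]
  arrhenius_fit(
    kref = exp(coef(ols)[[1L]]),
    Ea = ea,
    tref_c = tref_c,
    direction = direction,
    r_squared = smry$r.squared,
    std_errors = c(ln_kref = unname(se_tab[1L]), Ea = R_GAS * unname(se_tab[2L]))
  )
}

#' Predict a kinetic quantity at a new temperature
#'
#' @param fit An [arrhenius_fit()] object.
#' @param temperature_c Temperature(s), degrees C.
#' @return Predicted value(s), same units as `kref`.
#' @export
predict_rate <- function(fit, temperature_c) {
  if (!inherits(fit, "arrhenius_fit")) {
    stop_domain("`fit` must be an `arrhenius_fit` object.")
  }
  x <- inv_temp_dev(temperature_c, fit$tref_c)
  sgn <- if (fit$direction == "rate") -1 else 1
  fit$kref * exp(sgn * fit$Ea / R_GAS * x)
}

#' Reference lag phase under a shared activation energy
#'
#' Estimates the lag phase at the reference temperature assuming the lag
#' shares the activation energy of the matching growth-rate model (the
#' single-Ea structure of the shelf-life equation) and lengthens as
#' temperature drops. The estimator is the geometric mean of the
#' temperature-standardised lags:
#' `lambda_ref = exp(mean(ln(lag_i) - Ea/R (1/T_i - 1/Tref)))`.
#'
#' @param data Data frame of observed lags.
#' @param temperature,lag Columns (tidy-eval): temperature in degrees C and
#'   lag in days. Defaults `temperature_C`, `lag_d`. Non-positive or missing
#'   lags are dropped.
#' @param Ea Shared activation energy, J/mol.
#' @param tref_c Reference temperature, degrees C.
#' @return Reference lag in days; `0` (with a warning) when no positive lags
#'   are available.
#' @export
fit_lag_reference <- function(data, temperature = temperature_C, lag = lag_d,
                              Ea, tref_c = TREF_C_DEFAULT) {
  temps <- rlang::eval_tidy(rlang::enquo(temperature), data)
  lags <- rlang::eval_tidy(rlang::enquo(lag), data)
  check_number(Ea, "Ea", lower = 0)
  keep <- is.finite(lags) & lags > 0
  if (!any(keep)) {
    warn("no positive lag values; reference lag set to 0.",
         class = "ttishelf_warning_no_lag")
    return(0)
  }
  x <- inv_temp_dev(temps[keep], tref_c)
  exp(mean(log(lags[keep]) - (Ea / R_GAS) * x))
}
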