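#' Shelf-life specification for a chilled product
#'
#' Collects everything needed to predict microbial shelf-life at an arbitrary
#' storage temperature: the initial and limiting population levels, an
#' Arrhenius model for the growth rate, and a reference lag phase sharing the
#' same activation energy. Shelf-life is the time for the population to climb
#' from `log_n0` to the acceptability limit `log_n1` at the
#' temperature-adjusted rate, plus the temperature-adjusted lag:
#' `t_SL(T) = (log_n1 - log_n0) / k(T) + lag(T)` with
#' `k(T) = kref exp(-Ea/R (1/T - 1/Tref))` and
#' `lag(T) = lambda_ref exp(+Ea/R (1/T - 1/Tref))`.
#'
#' @param log_n0 Initial population, log10 CFU/g.
#' @param log_n1 Acceptability limit, log10 CFU/g (default 7, the usual
#'   total-viable-count rejection level for fresh fish).
#' @param rate_model An [arrhenius_fit()] with `direction = "rate"`; supplies
#'   `kref`, `Ea` and `tref_c` unless given explicitly.
#' @param kref,Ea,tref_c Explicit alternatives to `rate_model`: rate at the
#'   reference temperature (log10 CFU/g per day), activation energy (J/mol),
#'   reference temperature (degrees C).
#' @param lambda_ref Lag phase at the reference temperature, days.
#' @return A `shelf_life_spec` object.
#' @examples
#' spec <- shelf_life_spec(log_n0 = 5, kref = 0.4, Ea = 113100, lambda_ref = 3)
#' estimate_shelf_life(spec, c(0, 4, 10))
#' @export
shelf_life_spec <- function(log_n0, log_n1 = 7, rate_model = NULL,
                            kref = NULL, Ea = NULL, tref_c = NULL,
                            lambda_ref = 0) {
  if (!is.null(rate_model)) {
    if (!inherits(rate_model, "arrhenius_fit") ||
        rate_model$direction != "rate") {
      stop_domain("`rate_model` must be a rate-like `arrhenius_fit`.")
    }
    kref <- kref %||% rate_model$kref
    Ea <- Ea %||% rate_model$Ea
    tref_c <- tref_c %||% rate_model$tref_c
  }
  tref_c <- tref_c %||% TREF_C_DEFAULT
  check_number(log_n0, "log_n0")
  check_number(log_n1, "log_n1")
  check_number(kref, "kref")
  check_number(Ea, "Ea", lower = 0)
  check_number(lambda_ref, "lambda_ref", lower = 0)
  if (log_n1 <= log_n0) stop_domain("`log_n1` must exceed `log_n0`.")
  if (kref <= 0) stop_domain("`kref` must be positive.")
  structure(
    list(log_n0 = log_n0, log_n1 = log_n1, kref = kref, Ea = Ea,
         tref_c = tref_c, lambda_ref = lambda_ref),
    class = "shelf_life_spec"
  )
}

#' @export
print.shelf_life_spec <- function(x, ...) {
  cat(sprintf(
    "Shelf-life spec: %.3g -> %.3g log10 CFU/g, kref = %.3g /d at %g degC, Ea = %.1f kJ/mol, lag_ref = %.3g d\n",
    x$log_n0, x$log_n1, x$kref, x$tref_c, x$Ea / 1000, x$lambda_ref
  ))
  invisible(x)
}

#' Estimate shelf-life at given storage temperatures
#'
#' @param spec A [shelf_life_spec()].
#' @param temperature_c Storage temperature(s), degrees C. Temperatures
#'   outside the 0-10 degC calibration range trigger an extrapolation
#'   warning; temperatures outside -5 to 25 degC are an error.
#' @return Shelf-life in days (vectorised over `temperature_c`), strictly
#'   decreasing in temperature.
#' @export
estimate_shelf_life <- function(spec, temperature_c) {
  if (!inherits(spec, "shelf_life_spec")) {
    stop_domain("`spec` must be a `shelf_life_spec` object.")
  }
  if (any(!is.finite(temperature_c))) stop_domain("temperatures must be finite.")
  if (any(temperature_c < -5 | temperature_c > 25)) {
    stop_domain("temperature far outside the modelled range (-5 to 25 degC).")
  }
  if (any(temperature_c < 0 | temperature_c > 10)) {
    warn("temperature outside the 0-10 degC calibration range; extrapolating.",
         class = "ttishelf_warning_extrapolation")
  }
  x <- inv_temp_dev(temperature_c, spec$tref_c)
  k_t <- spec$kref * exp(-spec$Ea / R_GAS * x)
  lag_t <- spec$lambda_ref * exp(spec$Ea / R_GAS * x)
  (spec$log_n1 - spec$log_n0) / k_t + lag_t
}

#' Shelf-life as a function of storage temperature
#'
#' Vectorised [estimate_shelf_life()] over a temperature grid, returned as a
#' tibble suitable for plotting against a TTI response curve.
#'
#' @param spec A [shelf_life_spec()].
#' @param temperatures_c Non-empty numeric vector of temperatures, degrees C.
#' @return A tibble with columns `temperature_C` and `shelf_life_d`,
#'   preserving the grid order.
#' @export
shelf_life_curve <- function(spec, temperatures_c) {
  if (length(temperatures_c) == 0L) stop_domain("temperature grid is empty.")
  tibble(
    temperature_C = temperatures_c,
    shelf_life_d = estimate_shelf_life(spec, temperatures_c)
  )
}
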