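# Bundled reference kinetic tables for gilthead seabream fillets stored under
# modified atmosphere packaging (MAP), with or without a CO2-emitting pad
# (MAP-PAD), at 0-10 degC, and for the enzymatic FreshTag TTI labels (M- and
# LP-type) at 0-15 degC. These are the published study constants the package's
# worked examples and validation checks run against.

#' Reference Baranyi growth parameters for seabream fillets
#'
#' Growth rate (log10 CFU/g per day), lag phase (days) and maximum population
#' for four spoilage groups (total viable count, Pseudomonas,
#' Enterobacteriaceae, H2S-producing bacteria) under MAP and MAP-PAD at
#' 0-10 degC. `lag_d` is `NA` where the no-lag model variant applied.
#'
#' @return A tibble with columns `organism`, `packaging`, `temperature_C`,
#'   `rate`, `rate_se`, `lag_d`, `lag_se`, `nmax`, `r_squared`.
#' @export
seabream_growth_params <- function() {
  temps <- c(0, 2.5, 5, 10)
  row <- function(org, pack, rate, rate_se, lag, lag_se, nmax, r2) {
    tibble(
      organism = org, packaging = pack, temperature_C = temps,
      rate = rate, rate_se = rate_se, lag_d = lag, lag_se = lag_se,
      nmax = nmax, r_squared = r2
    )
  }
  dplyr::bind_rows(
    row("TVC", "MAP_PAD", c(0.224, 0.294, 0.51, 1.07),
        c(0.027, 0.020, 0.14, 0.23), c(8.44, 2.88, 3.65, 1.16),
        c(0.97, 0.37, 0.58, 0.45), c(8.09, 8.48, 8.48, 8.73),
        c(0.992, 0.982, 0.960, 0.963)),
    row("TVC", "MAP", c(0.186, 0.298, 0.838, 1.26),
        c(0.031, 0.052, 0.19, 0.187), c(6.36, 1.52, 3.88, 1.55),
        c(1.52, 0.78, 0.56, 0.25), c(8.14, 7.92, 8.61, 8.71),
        c(0.953, 0.903, 0.982, 0.989)),
    row("Pseudomonas", "MAP_PAD", c(0.130, 0.257, 0.427, 0.629),
        c(0.016, 0.0247, 0.037, 0.035), c(8.76, 5.11, 4.63, 1.09),
        c(0.13, 0.99, 0.18, 0.03), c(6.83, 5.71, 6.62, 6.86),
        c(0.957, 0.771, 0.985, 0.947)),
    row("Pseudomonas", "MAP", c(0.143, 0.215, 0.416, 0.645),
        c(0.032, 0.1232, 0.088, 0.221), c(6.43, 5.20, 5.94, 0.87),
        c(1.84, 0.34, 0.35, 0.03), c(7.04, 6.35, 6.85, 7.50),
        c(0.914, 0.843, 0.929, 0.916)),
    row("Enterobacteriaceae", "MAP_PAD", c(0.251, 0.421, 0.543, 0.894),
        c(0.073, 0.007, 0.377, 0.034), c(12.68, 7.12, 5.82, 1.34),
        c(2.68, 0.80, 0.76, 0.08), c(6.78, 4.74, 7.23, 7.53),
        c(0.866, 0.999, 0.982, 0.999)),
    row("Enterobacteriaceae", "MAP", c(0.324, 0.433, 0.672, 1.050),
        c(0.072, 0.033, 0.086, 0.090), c(11.58, 4.76, 4.06, NA),
        c(1.68, 0.74, 0.9, NA), c(6.95, 4.75, 6.81, 7.60),
        c(0.933, 0.980, 0.984, 0.812)),
    row("H2S_producers", "MAP_PAD", c(0.183, 0.219, 0.339, 1.050),
        c(0.041, 0.029, 0.130, 0.130), c(1.33, NA, NA, NA),
        c(0.04, NA, NA, NA), c(7.95, 6.94, 7.53, 7.78),
        c(0.888, 0.967, 0.798, 0.969)),
    row("H2S_producers", "MAP", c(0.209, 0.295, 0.695, 1.150),
        c(0.032, 0.043, 0.169, 0.160), c(NA, NA, NA, NA),
        c(NA, NA, NA, NA), c(8.42, 6.69, 7.43, 8.13),
        c(0.922, 0.931, 0.908, 0.964))
  )
}

#' Reference activation energies for seabream spoilage rates
#'
#' Published Arrhenius activation energies (kJ/mol) of the growth rates of the
#' four spoilage groups under the two packaging conditions, fitted over
#' 0-10 degC.
#'
#' @return A tibble with columns `organism`, `packaging`, `ea_kj_mol`,
#'   `r_squared`.
#' @export
seabream_activation_energy <- function() {
  tibble(
    organism = rep(c("TVC", "Pseudomonas", "Enterobacteriaceae",
                     "H2S_producers"), each = 2L),
    packaging = rep(c("MAP_PAD", "MAP"), 4L),
    ea_kj_mol = c(113.1, 133.9, 93.7, 100.5, 81.4, 90.3, 116.2, 120.4),
    r_squared = c(0.887, 0.883, 0.918, 0.952, 0.969, 0.982, 0.961, 0.943)
  )
}

#' Observed shelf-life of seabream fillets at isothermal storage
#'
#' Days for the total viable count to reach the 7 log10 CFU/g acceptability
#' limit, as observed in the storage trials.
#'
#' @return A tibble with columns `packaging`, `temperature_C`,
#'   `shelf_life_d`.
#' @export
seabream_shelf_life_observed <- function() {
  tibble(
    packaging = rep(c("MAP_PAD", "MAP"), each = 4L),
    temperature_C = rep(c(0, 2.5, 5, 10), 2L),
    shelf_life_d = c(17, 13, 8, 3, 16, 11, 6, 3)
  )
}

#' Reference per-label TTI logistic constants
#'
#' Measured logistic response constants `k1` and `k2` (days) for the M-type
#' labels (5-100 enzyme units) and LP-type labels (100-500 units) at
#' 0-15 degC.
#'
#' @return A tibble with columns `tti_type`, `enzyme_units`,
#'   `temperature_C`, `k1`, `k1_se`, `k2`, `k2_se`.
#' @export
tti_response_constants <- function() {
  temps <- c(0, 2.5, 5, 10, 15)
  row <- function(type, units, k1, k1_se, k2, k2_se) {
    tibble(tti_type = type, enzyme_units = units, temperature_C = temps,
           k1 = k1, k1_se = k1_se, k2 = k2, k2_se = k2_se)
  }
  dplyr::bind_rows(
    row("M", 5, c(50.4, 37.2, 29.2, 10.2, 6.90), c(1.91, 1.24, 0.43, 0.32, 0.02),
        c(7.83, 4.07, 3.20, 1.48, 1.24), c(1.60, 0.94, 0.31, 0.26, 0.02)),
    row("M", 10, c(31.3, 23.1, 14.0, 6.85, 3.97), c(0.36, 0.10, 0.37, 0.02, 0.04),
        c(6.18, 2.37, 3.65, 0.57, 0.59), c(0.44, 0.09, 0.35, 0.02, 0.04)),
    row("M", 15, c(22.3, 18.1, 12.3, 5.57, 3.11), c(0.36, 0.18, 0.25, 0.10, 0.02),
        c(4.79, 2.76, 2.25, 1.06, 0.48), c(0.26, 0.16, 0.24, 0.08, 0.01)),
    row("M", 20, c(19.2, 14.9, 11.9, 3.69, 2.47), c(0.36, 0.18, 0.25, 0.10, 0.02),
        c(4.95, 2.02, 1.68, 0.64, 0.50), c(0.26, 0.16, 0.24, 0.08, 0.01)),
    row("M", 25, c(15.5, 12.5, 8.03, 2.96, 1.63), c(0.34, 0.49, 0.13, 0.03, 0.02),
        c(2.99, 2.57, 1.49, 0.60, 0.21), c(0.28, 0.33, 0.12, 0.03, 0.02)),
    row("M", 50, c(8.11, 5.47, 3.77, 1.79, 0.93), c(0.07, 0.17, 0.03, 0.03, 0.01),
        c(1.39, 1.24, 0.47, 0.34, 0.16), c(0.08, 0.10, 0.02, 0.02, 0.01)),
    row("M", 75, c(6.03, 3.99, 2.73, 0.97, 0.68), c(0.03, 0.04, 0.02, 0.02, 0.01),
        c(0.86, 0.65, 0.27, 0.17, 0.15), c(0.03, 0.03, 0.02, 0.01, 0.01)),
    row("M", 100, c(4.26, 3.12, 2.06, 0.97, 0.46), c(0.03, 0.07, 0.02, 0.02, 0.01),
        c(0.58, 0.53, 0.31, 0.09, 0.08), c(0.03, 0.07, 0.01, 0.01, 0.01)),
    row("LP", 100, c(33.1, 14.0, 7.90, 3.15, 1.15), c(0.33, 0.42, 0.13, 0.06, 0.02),
        c(10.9, 4.26, 1.84, 0.79, 0.27), c(0.25, 0.31, 0.12, 0.06, 0.02)),
    row("LP", 150, c(21.4, 12.1, 8.77, 1.81, 0.77), c(0.80, 0.16, 0.15, 0.04, 0.03),
        c(8.60, 2.09, 2.52, 0.57, 0.18), c(0.79, 0.14, 0.13, 0.03, 0.03)),
    row("LP", 300, c(11.3, 3.49, 1.38, 0.85, 0.30), c(0.40, 0.14, 0.04, 0.02, 0.03),
        c(3.49, 0.86, 0.38, 0.23, 0.06), c(0.36, 0.14, 0.04, 0.01, 0.03)),
    row("LP", 500, c(9.87, 4.03, 1.75, 0.49, 0.20), c(0.10, 0.06, 0.03, 0.01, 0.01),
        c(2.25, 1.01, 0.41, 0.14, 0.05), c(0.09, 0.06, 0.02, 0.01, 0.01))
  )
}

#' Reference global TTI model parameters
#'
#' Published parameters of the global concentration-temperature response
#' model for the two label chemistries.
#'
#' @return A tibble with columns `tti_type`, `ea_kj_mol`, `k1ref`, `k2ref`,
#'   `alpha`, `beta`, `r_squared`.
#' @export
tti_global_constants <- function() {
  tibble(
    tti_type = c("M", "LP"),
    ea_kj_mol = c(97.1, 148.0),
    k1ref = c(128.6, 1822.4),
    k2ref = c(25.7, 298.1),
    alpha = c(0.861, 1.10),
    beta = c(0.861, 0.970),
    r_squared = c(0.970, 0.967)
  )
}

#' Build the reference global TTI models
#'
#' @return A named list of [tti_global_model()] objects (`M`, `LP`) built
#'   from [tti_global_constants()].
#' @export
reference_tti_models <- function() {
  tab <- tti_global_constants()
  models <- purrr::pmap(tab, function(tti_type, ea_kj_mol, k1ref, k2ref,
                                      alpha, beta, r_squared) {
    tti_global_model(tti_type, Ea = ea_kj_mol * 1000, k1ref = k1ref,
                     k2ref = k2ref, alpha = alpha, beta = beta,
                     r_squared = r_squared)
  })
  setNames(models, tab$tti_type)
}

#' Experimental and predicted growth rates under the dynamic validation
#'
#' Apparent growth rates fitted to the non-isothermal validation trial
#' (effective temperature 4.8 degC) alongside the rates predicted by the
#' Arrhenius models, with the conventionally reported (integer-rounded)
#' relative errors.
#'
#' @return A tibble with columns `organism`, `packaging`, `k_experimental`,
#'   `k_experimental_se`, `k_predicted`, `k_predicted_se`,
#'   `re_percent_reported`.
#' @export
seabream_validation_rates <- function() {
  tibble(
    organism = rep(c("TVC", "Pseudomonas", "Enterobacteriaceae",
                     "H2S_producers"), each = 2L),
    packaging = rep(c("MAP_PAD", "MAP"), 4L),
    k_experimental = c(0.348, 0.551, 0.355, 0.367, 0.493, 0.510, 0.276, 0.467),
    k_experimental_se = c(0.015, 0.073, 0.041, 0.049, 0.0282, 0.025,
                          0.043, 0.047),
    k_predicted = c(0.398, 0.524, 0.244, 0.321, 0.401, 0.486, 0.351, 0.447),
    k_predicted_se = c(0.024, 0.046, 0.012, 0.009, 0.015, 0.023,
                       0.025, 0.0017),
    re_percent_reported = c(14, 5, 31, 12, 18, 5, 27, 2)
  )
}

#' Assemble the reference shelf-life spec for a packaging condition
#'
#' Builds a total-viable-count shelf-life specification from the bundled
#' reference tables: the published activation energy for the packaging
#' condition, a reference rate and reference lag aligned to the measured
#' per-temperature rates and lags by the shared-Ea geometric-mean estimator,
#' an initial load of 5 log10 CFU/g (the typical initial total viable count
#' of fresh fillets) and the 7 log10 CFU/g acceptability limit.
#'
#' @param packaging `"MAP_PAD"` or `"MAP"`.
#' @param log_n0,log_n1 Initial load and acceptability limit, log10 CFU/g.
#' @param tref_c Reference temperature, degrees C.
#' @return A [shelf_life_spec()].
#' @export
seabream_shelf_life_spec <- function(packaging = c("MAP_PAD", "MAP"),
                                     log_n0 = 5, log_n1 = 7,
                                     tref_c = TREF_C_DEFAULT) {
  packaging <- match.arg(packaging)
  growth <- dplyr::filter(seabream_growth_params(),
                          .data$organism == "TVC",
                          .data$packaging == !!packaging)
  ea <- dplyr::filter(seabream_activation_energy(),
                      .data$organism == "TVC",
                      .data$packaging == !!packaging)$ea_kj_mol * 1000
  x <- inv_temp_dev(growth$temperature_C, tref_c)
  kref <- exp(mean(log(growth$rate) + (ea / R_GAS) * x))
  lambda_ref <- fit_lag_reference(growth, lag = lag_d, Ea = ea, tref_c = tref_c)
  shelf_life_spec(log_n0 = log_n0, log_n1 = log_n1, kref = kref, Ea = ea,
                  tref_c = tref_c, lambda_ref = lambda_ref)
}
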