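#' Generate a synthetic microbial growth curve
#'
#' Draws a log10 count series from the Baranyi-Roberts model with additive
#' Gaussian noise on the log10 scale — the standard error structure of plate
#' counts at these population levels. Output follows the package's count
#' table schema so it can feed straight into [fit_baranyi()].
#'
#' @param params A [baranyi_params()] object.
#' @param times Sampling times, days (default: 12 points over 0-25 d,
#'   mirroring a typical chilled-storage sampling design).
#' @param noise_sd Noise standard deviation, log10 CFU/g (>= 0).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @param organism,packaging,temperature_c Metadata columns for the output.
#' @param replicate Replicate label.
#' @return A tibble with columns `organism`, `packaging`, `temperature_C`,
#'   `time_d`, `log10_count`, `replicate`.
#' @export
gen_growth_curve <- function(params, times = seq(0, 25, length.out = 12),
                             noise_sd = 0.15, seed = 1L,
                             organism = "TVC", packaging = "MAP",
                             temperature_c = NA_real_, replicate = 1L) {
  if (!inherits(params, "baranyi_params")) {
    stop_domain("`params` must be a `baranyi_params` object.")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  clean <- baranyi_log_count(times, params)
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(length(times), 0, noise_sd))
  tibble(
    organism = organism,
    packaging = packaging,
    temperature_C = temperature_c,
    time_d = times,
    log10_count = clean + noise,
    replicate = replicate
  )
}

#' Generate a synthetic TTI colour-reading series
#'
#' Simulates raw CIELab readings consistent with the normalisation and the
#' logistic response: the noiseless normalised response is mapped back to an
#' `a + b` sum between the calibration extremes (split evenly between the two
#' coordinates), after adding Gaussian noise on the normalised scale.
#'
#' @param k1,k2 Logistic response constants, days.
#' @param ab_min,ab_max Calibration extremes of `a + b`.
#' @param times Reading times, days.
#' @param noise_sd Noise standard deviation on the normalised response.
#' @param seed Integer seed.
#' @param tti_type,enzyme_units,temperature_c,replicate Metadata columns.
#' @return A tibble with columns `tti_type`, `enzyme_units`, `temperature_C`,
#'   `time_d`, `a`, `b`, `replicate` (the colour table schema).
#' @export
gen_tti_series <- function(k1, k2, ab_min = -20, ab_max = 60,
                           times = seq(0, 30, length.out = 20),
                           noise_sd = 0.03, seed = 1L,
                           tti_type = "M", enzyme_units = 25,
                           temperature_c = NA_real_, replicate = 1L) {
  check_number(noise_sd, "noise_sd", lower = 0)
  if (ab_max <= ab_min) stop_domain("`ab_max` must exceed `ab_min`.")
  norm <- logistic_response(times, k1, k2)
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(length(times), 0, noise_sd))
  norm_noisy <- pmin(pmax(norm + noise, 0), 1)
  ab <- ab_min + norm_noisy * (ab_max - ab_min)
  tibble(
    tti_type = tti_type,
    enzyme_units = enzyme_units,
    temperature_C = temperature_c,
    time_d = times,
    a = ab / 2,
    b = ab / 2,
    replicate = replicate
  )
}

#' Generate a cold-chain temperature profile
#'
#' Builds a piecewise-constant logger-style profile. When `target_teff_c` is
#' given, the dwell fractions are adjusted by bisection so that the profile's
#' effective temperature (for the supplied activation energy) hits the target
#' to within 0.01 degC — emulating programmed validation scenarios such as a
#' 2-10 degC history with an effective temperature of 4.8 degC.
#'
#' @param kind `"constant"`, `"square_wave"` or `"staircase"`.
#' @param levels_c Temperature levels, degrees C: one value for `constant`,
#'   low/high for `square_wave`, any number (cycled) for `staircase`.
#' @param duration_d Total profile duration, days.
#' @param period_d Cycle period for the alternating kinds, days.
#' @param target_teff_c Optional effective-temperature target, degrees C.
#' @param Ea Activation energy used in the effective-temperature calculation,
#'   J/mol (required with `target_teff_c`).
#' @return A [temperature_profile()].
#' @examples
#' pr <- gen_temperature_profile("square_wave", levels_c = c(2, 10),
#'                               duration_d = 16, period_d = 2,
#'                               target_teff_c = 4.8, Ea = 113100)
#' effective_temperature(pr, Ea = 113100)
#' @export
gen_temperature_profile <- function(kind = c("constant", "square_wave", "staircase"),
                                    levels_c, duration_d = 16,
                                    period_d = 2, target_teff_c = NULL,
                                    Ea = NULL) {
  kind <- match.arg(kind)
  check_number(duration_d, "duration_d")
  if (duration_d <= 0) stop_domain("`duration_d` must be positive.")
  if (kind == "constant") {
    if (length(levels_c) != 1L) stop_domain("`constant` takes a single level.")
    if (!is.null(target_teff_c) && abs(target_teff_c - levels_c) > 0.01) {
      abort("infeasible target: a constant profile has Teff equal to its level.",
            class = "ttishelf_error_feasibility")
    }
    return(temperature_profile(duration_d, levels_c))
  }
  if (length(levels_c) < 2L) {
    stop_domain("alternating profiles need at least two levels.")
  }
  n_cycles <- max(1L, round(duration_d / period_d))
  build <- function(frac_hot) {
    # one cycle dwells `frac_hot` of the period at the hottest level and
    # spreads the rest over the remaining levels (staircase) or the low
    # level (square wave)
    hot <- which.max(levels_c)
    others <- setdiff(seq_along(levels_c), hot)
    dwell <- numeric(length(levels_c))
    dwell[hot] <- frac_hot * period_d
    dwell[others] <- (1 - frac_hot) * period_d / length(others)
    keep <- dwell > 1e-9
    temps <- rep(levels_c[keep], n_cycles)
    durs <- rep(dwell[keep], n_cycles)
    temperature_profile(durs * duration_d / sum(durs), temps)
  }
  if (is.null(target_teff_c)) {
    return(build(1 / length(levels_c)))
  }
  if (is.null(Ea)) stop_domain("`Ea` is required when targeting a Teff.")
  if (target_teff_c < min(levels_c) - 1e-9 ||
      target_teff_c > max(levels_c) + 1e-9) {
    abort(sprintf(
      "infeasible target: Teff = %g degC lies outside the level range [%g, %g].",
      target_teff_c, min(levels_c), max(levels_c)
    ), class = "ttishelf_error_feasibility")
  }
  obj <- function(frac) {
    effective_temperature(build(frac), Ea) - target_teff_c
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  if (obj(lo) > 0 || obj(hi) < 0) {
    abort("infeasible target: unreachable by adjusting the hot dwell fraction.",
          class = "ttishelf_error_feasibility")
  }
  frac <- uniroot(obj, c(lo, hi), tol = 1e-10)$root
  build(frac)
}
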