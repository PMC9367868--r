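# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Baranyi growth-model fit
#'
#' @param x A `baranyi_fit` from [fit_baranyi()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy baranyi_fit
#' @export
tidy.baranyi_fit <- function(x, ...) {
  terms <- c("y0", "ymax", "mu", "lag")
  est <- c(x$params$y0, x$params$ymax, x$params$mu, x$params$lag)
  tibble(
    term = terms,
    estimate = est,
    std.error = unname(x$std_errors[terms])
  )
}

#' Glance at a Baranyi growth-model fit
#'
#' @inheritParams tidy.baranyi_fit
#' @return A one-row tibble: `r.squared`, `sigma`, `nobs`, `lag_dropped`,
#'   `ymax_fixed`.
#' @method glance baranyi_fit
#' @export
glance.baranyi_fit <- function(x, ...) {
  p <- 3L + as.integer(x$params$lag > 0)
  tibble(
    r.squared = x$r_squared,
    sigma = sqrt(sum(x$residuals^2) / max(x$n - p, 1L)),
    nobs = x$n,
    lag_dropped = x$lag_dropped,
    ymax_fixed = x$ymax_fixed
  )
}

#' Tidy an Arrhenius secondary-model fit
#'
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @return Rows for `kref` and `Ea` with standard errors where available
#'   (the `kref` standard error is delta-method from `ln kref`).
#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  se <- x$std_errors
  tibble(
    term = c("kref", "Ea"),
    estimate = c(x$kref, x$Ea),
    std.error = c(
      if (!is.null(se)) x$kref * unname(se["ln_kref"]) else NA_real_,
      if (!is.null(se)) unname(se["Ea"]) else NA_real_
    )
  )
}

#' Glance at an Arrhenius secondary-model fit
#'
#' @inheritParams tidy.arrhenius_fit
#' @return A one-row tibble: `r.squared`, `tref_c`, `direction`.
#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, tref_c = x$tref_c, direction = x$direction)
}

#' Tidy a TTI logistic fit
#'
#' @param x A `tti_logistic_fit`.
#' @param ... Unused.
#' @return Rows for `k1` and `k2`.
#' @method tidy tti_logistic_fit
#' @export
tidy.tti_logistic_fit <- function(x, ...) {
  tibble(
    term = c("k1", "k2"),
    estimate = c(x$k1, x$k2),
    std.error = unname(x$std_errors[c("k1", "k2")])
  )
}

#' Glance at a TTI logistic fit
#'
#' @inheritParams tidy.tti_logistic_fit
#' @return A one-row tibble: `r.squared`, `nobs`.
#' @method glance tti_logistic_fit
#' @export
glance.tti_logistic_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = nrow(x$data))
}

#' Tidy a global TTI model
#'
#' @param x A `tti_global_model`.
#' @param ... Unused.
#' @return One row per parameter (`Ea`, `k1ref`, `k2ref`, `alpha`, `beta`).
#' @method tidy tti_global_model
#' @export
tidy.tti_global_model <- function(x, ...) {
  tibble(
    term = c("Ea", "k1ref", "k2ref", "alpha", "beta"),
    estimate = c(x$Ea, x$k1ref, x$k2ref, x$alpha, x$beta)
  )
}

#' Glance at a global TTI model
#'
#' @inheritParams tidy.tti_global_model
#' @return A one-row tibble: `tti_type`, `r.squared`, `tref_c`.
#' @method glance tti_global_model
#' @export
glance.tti_global_model <- function(x, ...) {
  tibble(tti_type = x$tti_type, r.squared = x$r_squared, tref_c = x$tref_c)
}
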