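#' Baranyi-Roberts growth-model parameters
#'
#' Bundles the four parameters of the Baranyi-Roberts primary growth model in
#' the units used throughout the package: populations as log10 CFU/g, time in
#' days. The maximum specific growth rate `mu` is expressed in log10 CFU/g per
#' day (the slope of the exponential phase on a log10 count plot); the lag
#' phase `lag` enters through the physiological-state adjustment function, so
#' `lag = 0` gives the no-lag model variant.
#'
#' @param y0 Initial population, log10 CFU/g.
#' @param ymax Maximum (stationary-phase) population, log10 CFU/g. Must exceed
#'   `y0`.
#' @param mu Maximum growth rate, log10 CFU/g per day. Must be positive.
#' @param lag Lag phase, days (>= 0). Default 0 (no lag).
#' @return An object of class `baranyi_params`.
#' @examples
#' p <- baranyi_params(y0 = 5.41, ymax = 8.09, mu = 0.224, lag = 8.44)
#' baranyi_log_count(c(0, 10, 20), p)
#' @export
baranyi_params <- function(y0, ymax, mu, lag = 0) {
  check_number(y0, "y0")
  check_number(ymax, "ymax")
  check_number(mu, "mu")
  check_number(lag, "lag", lower = 0)
  if (y0 >= ymax) {
    stop_domain(sprintf("`y0` (%g) must be strictly below `ymax` (%g).", y0, ymax))
  }
  if (mu <= 0) stop_domain("`mu` must be strictly positive.")
  structure(
    list(y0 = y0, ymax = ymax, mu = mu, lag = lag),
    class = "baranyi_params"
  )
}

#' @export
print.baranyi_params <- function(x, ...) {
  cat("Baranyi-Roberts parameters\n")
  cat(sprintf("  y0   = %.4g log10 CFU/g\n", x$y0))
  cat(sprintf("  ymax = %.4g log10 CFU/g\n", x$ymax))
  cat(sprintf("  mu   = %.4g log10 CFU/g / d\n", x$mu))
  cat(sprintf("  lag  = %.4g d\n", x$lag))
  invisible(x)
}

# Explicit Baranyi-Roberts solution evaluated in natural-log concentration.
# Inputs already converted: y0n/ymaxn natural-log counts, mun = mu * ln 10.
baranyi_natural <- function(t, y0n, ymaxn, mun, lag) {
  h0 <- mun * lag
  # adjustment function A(t); all exp() arguments are <= 0 so no overflow
  a_t <- t + log(exp(-mun * t) + exp(-h0) - exp(-mun * t - h0)) / mun
  b <- mun * a_t
  d <- ymaxn - y0n
  # ln(1 + (e^b - 1) e^-d), computed via a shifted log-sum-exp so large b is safe
  m <- pmax(0, b - d)
  brake <- m + log(exp(-m) + exp(b - d - m) - exp(-d - m))
  y0n + b - brake
}

#' Evaluate the Baranyi-Roberts growth curve
#'
#' Explicit solution of the Baranyi-Roberts model (curvature parameter m = 1,
#' nu = mu_max), evaluated on the log10 CFU/g scale. The curve starts exactly
#' at `y0`, rises sigmoidally after the lag phase and approaches `ymax`.
#'
#' @param t Time, days (vectorised, each >= 0).
#' @param params A [baranyi_params()] object.
#' @return Numeric vector of log10 CFU/g values, one per element of `t`.
#' @export
baranyi_log_count <- function(t, params) {
  if (!inherits(params, "baranyi_params")) {
    stop_domain("`params` must be a `baranyi_params` object.")
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_domain("`t` must be finite and non-negative.")
  }
  ln10 <- log(10)
  baranyi_natural(t, params$y0 * ln10, params$ymax * ln10,
                  params$mu * ln10, params$lag) / ln10
}

#' Time for a growth curve to reach a threshold population
#'
#' Solves `baranyi_log_count(t) = threshold` for `t` by root bracketing. The
#' solution is unique because the curve is strictly increasing between `y0`
#' and `ymax`.
#'
#' @param params A [baranyi_params()] object.
#' @param threshold Target population, log10 CFU/g.
#' @param tol Absolute tolerance on the returned time, days.
#' @return Crossing time in days. Returns `0` (with a warning) when the
#'   threshold is at or below `y0`, and `Inf` when it equals `ymax`.
#' @examples
#' p <- baranyi_params(y0 = 5, ymax = 9, mu = 0.5, lag = 0)
#' time_to_threshold(p, 7)
#' @export
time_to_threshold <- function(params, threshold, tol = 1e-9) {
  if (!inherits(params, "baranyi_params")) {
    stop_domain("`params` must be a `baranyi_params` object.")
  }
  check_number(threshold, "threshold")
  if (threshold > params$ymax) {
    stop_domain(sprintf(
      "threshold %g log10 CFU/g exceeds ymax = %g and is never reached.",
      threshold, params$ymax
    ))
  }
  if (threshold <= params$y0) {
    warn("threshold is at or below the initial population; returning 0 days.",
         class = "ttishelf_warning_threshold")
    return(0)
  }
  if (threshold == params$ymax) return(Inf)
  f <- function(t) baranyi_log_count(t, params) - threshold
  upper <- params$lag + (threshold - params$y0) / params$mu + 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = tol)$root
}

# Starting values for the Baranyi fit, per the initialization rules used by
# standard growth-curve fitting programs.
baranyi_start <- function(time, count, with_lag) {
  y0 <- count[1L]
  ymax <- max(count)
  slopes <- diff(count) / diff(time)
  mu <- max(slopes[is.finite(slopes)], 1e-3)
  lag <- 0
  if (with_lag) {
    above <- which(count > y0 + 0.2)
    lag <- if (length(above) > 0L) time[above[1L]] else 0
  }
  list(y0 = y0, ymax = ymax, mu = min(mu, 10), lag = lag)
}

baranyi_nls <- function(time, count, with_lag, start, maxt) {
  obs_max <- max(count)
  lower <- c(y0 = min(count) - 2, ymax = obs_max - 0.2, mu = 1e-6)
  upper <- c(y0 = obs_max, ymax = obs_max + 2, mu = 10)
  if (with_lag) {
    lower <- c(lower, lag = 0)
    upper <- c(upper, lag = maxt)
    form <- count ~ baranyi_log_count(time, baranyi_params(y0, ymax, mu, lag))
    start <- start[c("y0", "ymax", "mu", "lag")]
  } else {
    form <- count ~ baranyi_log_count(time, baranyi_params(y0, ymax, mu, 0))
    start <- start[c("y0", "ymax", "mu")]
  }
  start <- as.list(pmin(pmax(unlist(start), lower + 1e-8), upper - 1e-8))
  minpack.lm::nlsLM(
    form,
    data = data.frame(time = time, count = count),
    start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-13
    )
  )
}

# Fit with a few jittered restarts; returns the converged nls object or
# raises a fitting error carrying the best incumbent.
baranyi_nls_restarts <- function(time, count, with_lag, n_restarts = 3L) {
  start <- baranyi_start(time, count, with_lag)
  maxt <- max(time)
  best <- NULL
  for (i in 0:n_restarts) {
    st <- start
    if (i > 0L) {
      st$mu <- start$mu * exp((i - 2) * 0.5)
      if (with_lag) st$lag <- max(0, start$lag + (i - 2) * maxt / 10)
    }
    fit <- tryCatch(baranyi_nls(time, count, with_lag, st, maxt),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
      if (deviance(fit) < Inf) return(best)
    }
  }
  if (is.null(best)) {
    stop_fit("Baranyi fit failed to converge after restarts.")
  }
  best
}

#' Fit the Baranyi-Roberts model to a microbial count curve
#'
#' Least-squares fit of the primary growth model to log10 counts over time.
#' With `with_lag = "auto"` both the lag and no-lag variants are fitted and an
#' F-test at `alpha = 0.05` decides whether the lag phase is retained —
#' mirroring the behaviour of standard growth-curve fitting tools, which drop
#' a non-significant lag. When the data do not constrain the upper plateau the
#' fitted `ymax` runs into its bound and is instead fixed to the maximum
#' observation plus `ymax_margin` (flagged in the result).
#'
#' @param data Data frame with the observed curve.
#' @param time,count Column names (tidy-eval) holding time in days and
#'   log10 CFU/g counts. Defaults `time_d` and `log10_count`.
#' @param with_lag `"auto"` (F-test), `"with"` or `"without"`.
#' @param alpha Significance level of the lag F-test under `"auto"`.
#' @param ymax_margin Margin (log10 CFU/g) added to the maximum observation
#'   when `ymax` is unidentified.
#' @return A `baranyi_fit` object with elements `params`
#'   ([baranyi_params()]), `std_errors`, `r_squared`, `residuals`, `fitted`,
#'   `data`, and flags `lag_dropped`, `ymax_fixed`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' p <- baranyi_params(4.5, 8.5, 0.3, 2.9)
#' curve <- gen_growth_curve(p, times = seq(0, 25, length.out = 12),
#'                           noise_sd = 0.1, seed = 1)
#' fit <- fit_baranyi(curve)
#' glance(fit)
#' @export
fit_baranyi <- function(data, time = time_d, count = log10_count,
                        with_lag = c("auto", "with", "without"),
                        alpha = 0.05, ymax_margin = 0.5) {
  with_lag <- match.arg(with_lag)
  tq <- rlang::enquo(time)
  cq <- rlang::enquo(count)
  tvals <- rlang::eval_tidy(tq, data)
  cvals <- rlang::eval_tidy(cq, data)
  if (is.null(tvals) || is.null(cvals)) {
    stop_format("`data` must contain the time and count columns.")
  }
  keep <- is.finite(tvals) & is.finite(cvals)
  tvals <- tvals[keep]; cvals <- cvals[keep]
  ord <- order(tvals)
  tvals <- tvals[ord]; cvals <- cvals[ord]
  if (any(tvals < 0)) stop_domain("times must be non-negative.")
  n_distinct_t <- length(unique(tvals))
  need <- if (with_lag == "without") 3L else 4L
  if (n_distinct_t < need) {
    stop_domain(sprintf(
      "need at least %d distinct time points (got %d).", need, n_distinct_t
    ))
  }
  # degenerate / no-growth screen
  trend <- coef(lm(cvals ~ tvals))[2L]
  if (diff(range(cvals)) < 0.25 || trend <= 0) {
    abort("no growth detected: counts are flat or decreasing over time.",
          class = "ttishelf_error_no_growth")
  }

  fit_nolag <- baranyi_nls_restarts(tvals, cvals, with_lag = FALSE)
  fit_lag <- NULL
  lag_dropped <- FALSE
  use_lag <- FALSE
  if (with_lag != "without") {
    fit_lag <- tryCatch(baranyi_nls_restarts(tvals, cvals, with_lag = TRUE),
                        error = function(e) NULL)
    if (!is.null(fit_lag)) {
      lag_est <- coef(fit_lag)[["lag"]]
      if (with_lag == "with") {
        use_lag <- TRUE
        if (lag_est <= 1e-8) {
          lag_dropped <- TRUE
          use_lag <- FALSE
        }
      } else {
        n <- length(cvals)
        sse1 <- deviance(fit_lag)
        sse0 <- deviance(fit_nolag)
        f_stat <- (sse0 - sse1) / (sse1 / (n - 4L))
        p_val <- pf(max(f_stat, 0), 1L, n - 4L, lower.tail = FALSE)
        use_lag <- is.finite(p_val) && p_val < alpha && lag_est > 1e-8
        lag_dropped <- !use_lag
      }
    } else if (with_lag == "with") {
      stop_fit("Baranyi fit with lag failed to converge.")
    }
  }
  fit <- if (use_lag) fit_lag else fit_nolag

  co <- coef(fit)
  ymax_fixed <- FALSE
  obs_max <- max(cvals)
  y_at_end <- baranyi_log_count(max(tvals), baranyi_params(
    co[["y0"]], co[["ymax"]], co[["mu"]], if (use_lag) co[["lag"]] else 0))
  if (co[["ymax"]] >= obs_max + 2 - 1e-6 || y_at_end < co[["ymax"]] - 0.3) {
    # the fitted curve never approaches its own plateau, so ymax is
    # unidentified: pin it to the maximum observation plus the margin and
    # refit the remaining parameters
    ymax_fixed <- TRUE
    ymax_val <- obs_max + ymax_margin
    refit <- function(lag_on) {
      st <- baranyi_start(tvals, cvals, lag_on)
      env <- environment()
      form <- if (lag_on) {
        count ~ baranyi_log_count(time, baranyi_params(y0, ymax_val, mu, lag))
      } else {
        count ~ baranyi_log_count(time, baranyi_params(y0, ymax_val, mu, 0))
      }
      environment(form) <- env
      start <- if (lag_on) st[c("y0", "mu", "lag")] else st[c("y0", "mu")]
      lower <- c(y0 = min(cvals) - 2, mu = 1e-6)
      upper <- c(y0 = obs_max, mu = 10)
      if (lag_on) {
        lower <- c(lower, lag = 0); upper <- c(upper, lag = max(tvals))
      }
      minpack.lm::nlsLM(
        form,
        data = data.frame(time = tvals, count = cvals),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15)
      )
    }
    fit <- refit(use_lag)
    co <- coef(fit)
    co[["ymax"]] <- ymax_val
  }

  params <- baranyi_params(
    y0 = co[["y0"]], ymax = co[["ymax"]], mu = co[["mu"]],
    lag = if (use_lag) co[["lag"]] else 0
  )
  fitted_vals <- baranyi_log_count(tvals, params)
  resid_vals <- cvals - fitted_vals
  sstot <- sum((cvals - mean(cvals))^2)
  r2 <- 1 - sum(resid_vals^2) / sstot
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(co)), names(co)))
  std_errors <- c(
    y0 = unname(se["y0"]),
    ymax = if (ymax_fixed) NA_real_ else unname(se["ymax"]),
    mu = unname(se["mu"]),
    lag = if (use_lag) unname(se["lag"]) else NA_real_
  )

  structure(
    list(
      params = params,
      std_errors = std_errors,
      r_squared = r2,
      residuals = resid_vals,
      fitted = fitted_vals,
      data = tibble(time_d = tvals, log10_count = cvals),
      lag_dropped = lag_dropped,
      ymax_fixed = ymax_fixed,
      n = length(cvals)
    ),
    class = "baranyi_fit"
  )
}

#' @export
print.baranyi_fit <- function(x, ...) {
  cat("Baranyi-Roberts fit (", x$n, " observations)\n", sep = "")
  print(x$params)
  cat(sprintf("  R^2 = %.4f", x$r_squared))
  if (x$lag_dropped) cat("  [lag dropped: not significant]")
  if (x$ymax_fixed) cat("  [ymax fixed: plateau not observed]")
  cat("\n")
  invisible(x)
}
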