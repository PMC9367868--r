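# Independent oracles used across the suite. These deliberately avoid the
# package's explicit-solution and solver code paths: the growth oracle is a
# hand-stepped fixed-step RK4 on the differential (physiological-state) form
# of the Baranyi model, and the regression oracle is the closed-form
# simple-linear-regression slope.

# RK4 integration of dq/dt = mu_n q, dy/dt = mu_n q/(1+q) (1 - e^(y - ymax_n))
# in natural-log units; mu_at(t) gives the rate in log10/d at time t (constant
# for isothermal use; for stepped profiles it is sampled at substep midpoints,
# so substeps must not straddle a temperature switch). Returns log10 counts at
# `times`.
rk4_baranyi <- function(params, times, mu_at = NULL, n_sub = 8L) {
  ln10 <- log(10)
  ymaxn <- params$ymax * ln10
  mu_ref_n <- params$mu * ln10
  if (is.null(mu_at)) mu_at <- function(t) params$mu
  has_lag <- params$lag > 0
  q <- if (has_lag) 1 / expm1(mu_ref_n * params$lag) else Inf
  y <- params$y0 * ln10
  deriv <- function(mu_n, q, y) {
    adj <- if (is.infinite(q)) 1 else q / (1 + q)
    c(mu_n * q, mu_n * adj * (1 - exp(y - ymaxn)))
  }
  out <- numeric(length(times))
  stopifnot(times[1] == 0)
  out[1] <- y / ln10
  for (i in seq_along(times)[-1]) {
    h <- (times[i] - times[i - 1]) / n_sub
    t <- times[i - 1]
    for (s in seq_len(n_sub)) {
      mu_n <- mu_at(t + h / 2) * ln10
      k1 <- deriv(mu_n, q, y)
      k2 <- deriv(mu_n, q + h / 2 * k1[1], y + h / 2 * k1[2])
      k3 <- deriv(mu_n, q + h / 2 * k2[1], y + h / 2 * k2[2])
      k4 <- deriv(mu_n, q + h * k3[1], y + h * k3[2])
      if (!is.infinite(q)) q <- q + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      y <- y + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      t <- t + h
    }
    out[i] <- y / ln10
  }
  out
}

# Closed-form OLS slope and intercept, Sxy/Sxx.
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Random valid Baranyi parameter draws (uses the caller's RNG state).
random_baranyi_params <- function() {
  y0 <- runif(1, 2, 6)
  baranyi_params(
    y0 = y0,
    ymax = y0 + runif(1, 1.5, 4.5),
    mu = runif(1, 0.1, 1.2),
    lag = runif(1, 0, 8)
  )
}

ref_tref_c <- 4
r_gas <- 8.314

inv_dev <- function(temp_c, tref_c = ref_tref_c) {
  1 / (temp_c + 273.15) - 1 / (tref_c + 273.15)
}
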