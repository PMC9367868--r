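# Internal helpers shared across modules.

# Universal gas constant, J / (mol K)
R_GAS <- 8.314

# Reference temperature default, degrees C (middle of the 0-10 C chill range)
TREF_C_DEFAULT <- 4

celsius_to_kelvin <- function(temp_c) temp_c + 273.15

kelvin_to_celsius <- function(temp_k) temp_k - 273.15

# Reciprocal-temperature deviation from the reference, the Arrhenius regressor:
# 1/T - 1/Tref, both in K. Positive below Tref.
inv_temp_dev <- function(temp_c, tref_c) {
  1 / celsius_to_kelvin(temp_c) - 1 / celsius_to_kelvin(tref_c)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "ttishelf_error_domain", ...)
}

stop_fit <- function(msg, ...) {
  abort(msg, class = "ttishelf_error_fit", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "ttishelf_error_format", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_domain(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_format(sprintf(
      "%s is missing required column%s: %s.",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ), missing_columns = missing)
  }
  invisible(data)
}
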