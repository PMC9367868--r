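# Readers and writers for the package's delimited table formats. All files
# carry temperatures in degrees C, times in days, and use the decimal point
# (not comma); conversion to Kelvin happens inside the kinetics functions.

count_schema <- c("organism", "packaging", "temperature_C", "time_d",
                  "log10_count", "replicate")
color_schema <- c("tti_type", "enzyme_units", "temperature_C", "time_d",
                  "a", "b", "replicate")
profile_schema <- c("time_d", "temperature_C")

read_table_checked <- function(path, schema, numeric_cols, what) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, schema, sprintf("%s file '%s'", what, path))
  for (col in numeric_cols) {
    vals <- raw[[col]]
    if (is.character(vals)) {
      bad <- which(!grepl("^\\s*-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?\\s*$",
                          vals))
      hint <- if (any(grepl(",", vals))) {
        " (values contain commas: use the decimal point, not the comma)"
      } else {
        ""
      }
      stop_format(sprintf(
        "column `%s` of %s is not numeric at line%s %s%s.",
        col, path, if (length(bad) > 1L) "s" else "",
        paste(utils::head(bad + 1L, 5L), collapse = ", "), hint
      ))
    }
    if (any(!is.finite(vals))) {
      stop_format(sprintf("column `%s` of %s contains missing values at line%s %s.",
                          col, path, "", paste(which(!is.finite(vals)) + 1L,
                                               collapse = ", ")))
    }
  }
  raw
}

#' Read a microbial count table
#'
#' CSV with columns `organism`, `packaging`, `temperature_C`, `time_d`,
#' `log10_count`, `replicate` (header required; decimal point).
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_counts <- function(path) {
  out <- read_table_checked(path, count_schema,
                            c("temperature_C", "time_d", "log10_count"),
                            "count table")
  if (any(out$time_d < 0)) stop_format("negative times in count table.")
  out
}

#' Read a TTI colour-reading table
#'
#' CSV with columns `tti_type`, `enzyme_units`, `temperature_C`, `time_d`,
#' `a`, `b`, `replicate`.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_colors <- function(path) {
  out <- read_table_checked(path, color_schema,
                            c("enzyme_units", "temperature_C", "time_d",
                              "a", "b"),
                            "colour table")
  if (any(abs(out$a) > 60) || any(abs(out$b) > 60)) {
    stop_format("CIELab coordinates outside -60..60 in colour table.")
  }
  out
}

#' Read a temperature-logger profile
#'
#' CSV with columns `time_d`, `temperature_C`: each row gives the temperature
#' holding from that time until the next row (logger convention); the final
#' row closes the profile.
#'
#' @param path File path.
#' @return A [temperature_profile()].
#' @export
read_profile <- function(path) {
  raw <- read_table_checked(path, profile_schema,
                            c("time_d", "temperature_C"), "profile")
  if (nrow(raw) < 2L) stop_format("profile needs at least two rows.")
  if (is.unsorted(raw$time_d, strictly = TRUE)) {
    stop_format("profile times must be strictly increasing.")
  }
  if (abs(raw$time_d[1L]) > 1e-9) stop_format("profile must start at time 0.")
  durations <- diff(raw$time_d)
  temperature_profile(durations, raw$temperature_C[-nrow(raw)])
}

#' Write package tables to CSV
#'
#' Writers matching [read_counts()], [read_colors()] and [read_profile()];
#' write-then-read round-trips are identities.
#'
#' @param data Table to write (for `write_profile`, a
#'   [temperature_profile()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path) {
  check_columns(data, count_schema, "count table")
  readr::write_csv(data[count_schema], path)
  invisible(path)
}

#' @rdname write_counts
#' @export
write_colors <- function(data, path) {
  check_columns(data, color_schema, "colour table")
  readr::write_csv(data[color_schema], path)
  invisible(path)
}

#' @rdname write_counts
#' @export
write_profile <- function(data, path) {
  if (!inherits(data, "temperature_profile")) {
    stop_domain("`data` must be a `temperature_profile`.")
  }
  out <- tibble(
    time_d = c(data$start_d, profile_duration(data)),
    temperature_C = c(data$temperature_C,
                      data$temperature_C[nrow(data)])
  )
  readr::write_csv(out, path)
  invisible(path)
}
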