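#' Activation-energy compatibility of a TTI with a product
#'
#' A TTI can integrate a product's thermal history faithfully only if its
#' response has a similar temperature sensitivity; the standard criterion
#' requires the label's activation energy to lie within +/- 20 kJ/mol of the
#' activation energy of the product's quality-deterioration rate.
#'
#' @param ea_product,ea_tti Activation energies, J/mol (both > 0).
#' @param window Half-width of the acceptance window, J/mol (default 20000).
#' @return `TRUE` when `|ea_product - ea_tti| <= window`.
#' @export
ea_compatible <- function(ea_product, ea_tti, window = 20000) {
  if (any(ea_product <= 0) || any(ea_tti <= 0)) {
    stop_domain("activation energies must be positive.")
  }
  abs(ea_product - ea_tti) <= window
}

#' Score the match between a shelf-life curve and a TTI response curve
#'
#' Compares product shelf-life and label response time over a common
#' temperature grid. The selection statistic is the maximum absolute relative
#' deviation `(response - shelf_life) / shelf_life` over the grid; a label is
#' conservative at abuse when it expires at or before the product at every
#' grid temperature above the abuse threshold.
#'
#' @param shelf_curve Tibble from [shelf_life_curve()] (`temperature_C`,
#'   `shelf_life_d`).
#' @param tti_curve Tibble from [response_time_curve()] (`temperature_C`,
#'   `response_d`).
#' @param abuse_threshold_c Temperature above which under-prediction by the
#'   label is unacceptable, degrees C (default 6).
#' @return A `tti_match` object: per-temperature table plus
#'   `max_abs_relative_deviation` and `conservative_at_abuse`.
#' @export
match_score <- function(shelf_curve, tti_curve, abuse_threshold_c = 6) {
  check_columns(shelf_curve, c("temperature_C", "shelf_life_d"), "`shelf_curve`")
  check_columns(tti_curve, c("temperature_C", "response_d"), "`tti_curve`")
  if (nrow(shelf_curve) != nrow(tti_curve) ||
      any(abs(shelf_curve$temperature_C - tti_curve$temperature_C) > 1e-9)) {
    stop_format("curves are on different temperature grids.")
  }
  table <- tibble(
    temperature_C = shelf_curve$temperature_C,
    shelf_life_d = shelf_curve$shelf_life_d,
    tti_response_d = tti_curve$response_d,
    relative_deviation =
      (tti_curve$response_d - shelf_curve$shelf_life_d) / shelf_curve$shelf_life_d
  )
  abuse <- table$temperature_C > abuse_threshold_c
  conservative <- !any(abuse) ||
    all(table$tti_response_d[abuse] <= table$shelf_life_d[abuse] + 1e-12)
  structure(
    list(
      table = table,
      max_abs_relative_deviation = max(abs(table$relative_deviation)),
      conservative_at_abuse = conservative,
      abuse_threshold_c = abuse_threshold_c
    ),
    class = "tti_match"
  )
}

#' @export
print.tti_match <- function(x, ...) {
  cat(sprintf(
    "TTI match: max |relative deviation| = %.3f, conservative above %g degC: %s\n",
    x$max_abs_relative_deviation, x$abuse_threshold_c, x$conservative_at_abuse
  ))
  invisible(x)
}

#' Rank candidate TTI labels against a product shelf-life spec
#'
#' Filters candidates by activation-energy compatibility, then ranks the
#' admissible labels by ascending maximum absolute relative deviation between
#' the label's response-time curve and the product's shelf-life curve over
#' the temperature grid; ties favour labels that are conservative at abuse
#' temperatures.
#'
#' @param spec A [shelf_life_spec()] for the product.
#' @param ea_product Activation energy of the product's deterioration rate,
#'   J/mol. Defaults to `spec$Ea`.
#' @param candidates Tibble with one row per candidate: a `model` list-column
#'   of [tti_global_model()] objects and a numeric `conc` column (enzyme
#'   units). An optional `label` column names the candidates; otherwise
#'   labels are built as `<type>-<conc>U`.
#' @param temperatures_c Temperature grid, degrees C (default 0-10 by 0.5).
#' @param abuse_threshold_c Abuse threshold for the conservativeness flag.
#' @param endpoint TTI visual endpoint (normalised response).
#' @param ea_window Compatibility window, J/mol.
#' @return A tibble ranked best-first with columns `rank`, `label`, `conc`,
#'   `ea_tti`, `ea_compatible`, `max_abs_relative_deviation`,
#'   `conservative_at_abuse`, and a `match` list-column of `tti_match`
#'   objects. Incompatible candidates are retained at the bottom with
#'   `rank = NA`. An empty compatible set triggers a diagnostic warning.
#' @export
select_tti <- function(spec, candidates, ea_product = NULL,
                       temperatures_c = seq(0, 10, by = 0.5),
                       abuse_threshold_c = 6, endpoint = 0.8,
                       ea_window = 20000) {
  if (!inherits(spec, "shelf_life_spec")) {
    stop_domain("`spec` must be a `shelf_life_spec`.")
  }
  check_columns(candidates, c("model", "conc"), "`candidates`")
  if (nrow(candidates) == 0L) stop_domain("need at least one candidate.")
  ea_product <- ea_product %||% spec$Ea
  shelf <- shelf_life_curve(spec, temperatures_c)
  rows <- purrr::pmap(
    list(candidates$model, candidates$conc, seq_len(nrow(candidates))),
    function(model, conc, i) {
      label <- if ("label" %in% names(candidates)) {
        candidates$label[[i]]
      } else {
        sprintf("%s-%gU", model$tti_type, conc)
      }
      tti <- response_time_curve(model, conc, temperatures_c, endpoint)
      m <- match_score(shelf, tti, abuse_threshold_c)
      tibble(
        label = label,
        conc = conc,
        ea_tti = model$Ea,
        ea_compatible = ea_compatible(ea_product, model$Ea, ea_window),
        max_abs_relative_deviation = m$max_abs_relative_deviation,
        conservative_at_abuse = m$conservative_at_abuse,
        match = list(m)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(
    out,
    !.data$ea_compatible,
    .data$max_abs_relative_deviation,
    !.data$conservative_at_abuse,
    .data$label
  )
  n_ok <- sum(out$ea_compatible)
  if (n_ok == 0L) {
    warn(sprintf(
      "no candidate within +/- %.1f kJ/mol of the product Ea (%.1f kJ/mol).",
      ea_window / 1000, ea_product / 1000
    ), class = "ttishelf_warning_no_compatible_tti")
  }
  out$rank <- c(seq_len(n_ok), rep(NA_integer_, nrow(out) - n_ok))
  dplyr::relocate(out, "rank")
}
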