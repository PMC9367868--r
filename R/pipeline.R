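#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Table arguments may
#' be data frames (as produced by the generators or readers) or file paths.
#'
#' @param counts Microbial count table or CSV path (may be `NULL`).
#' @param colors TTI colour table or CSV path (may be `NULL`).
#' @param profile [temperature_profile()] or logger CSV path (may be `NULL`).
#' @param dynamic_rates Optional data frame of experimental apparent rates
#'   under the profile (`organism`, `packaging`, `k_experimental`) for the
#'   validation stage.
#' @param tref_c Reference temperature, degrees C.
#' @param log_n0,log_n1 Initial load and acceptability limit, log10 CFU/g.
#' @param endpoint TTI visual endpoint (normalised response).
#' @param ea_window_kj Activation-energy compatibility window, kJ/mol.
#' @param abuse_threshold_c Abuse temperature threshold, degrees C.
#' @param seed Integer seed recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, colors = NULL, profile = NULL,
                            dynamic_rates = NULL,
                            tref_c = TREF_C_DEFAULT, log_n0 = 5, log_n1 = 7,
                            endpoint = 0.8, ea_window_kj = 20,
                            abuse_threshold_c = 6, seed = 1L) {
  check_number(tref_c, "tref_c", lower = -5, upper = 25)
  check_number(log_n1, "log_n1")
  check_number(endpoint, "endpoint", lower = 1e-9, upper = 1 - 1e-9)
  check_number(ea_window_kj, "ea_window_kj", lower = 0)
  if (ea_window_kj <= 0) stop_domain("`ea_window_kj` must be positive.")
  structure(
    list(counts = counts, colors = colors, profile = profile,
         dynamic_rates = dynamic_rates, tref_c = tref_c, log_n0 = log_n0,
         log_n1 = log_n1, endpoint = endpoint, ea_window_kj = ea_window_kj,
         abuse_threshold_c = abuse_threshold_c, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

resolve_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(reader(x))
  x
}

pipeline_stage <- function(name, expr) {
  tryCatch(
    list(status = "ok", result = expr),
    error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "ttishelf_error_pipeline", parent = e)
    }
  )
}

#' Run the full shelf-life / TTI analysis pipeline
#'
#' Orchestrates the end-to-end analysis: primary growth fits per
#' organism/packaging/temperature, Arrhenius secondary models, shelf-life
#' specs and curves for the total viable count, per-label TTI logistic fits
#' and global models, TTI selection per packaging, and (when a profile is
#' supplied) effective temperature and dynamic growth prediction with
#' relative-error validation against experimental rates. Stages whose inputs
#' are missing are marked `"skipped"` rather than failing the run.
#'
#' @param config A [pipeline_config()].
#' @return A `ttishelf_report` list with elements `growth`, `arrhenius`,
#'   `shelf_life`, `tti`, `matching`, `validation` (each `list(status,
#'   result)`) and `provenance` (seed, timestamp-free config echo).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_domain("`config` must come from `pipeline_config()`.")
  }
  counts <- resolve_table(config$counts, read_counts)
  colors <- resolve_table(config$colors, read_colors)
  profile <- if (is.character(config$profile)) {
    read_profile(config$profile)
  } else {
    config$profile
  }
  skipped <- list(status = "skipped", result = NULL)
  report <- list(growth = skipped, arrhenius = skipped, shelf_life = skipped,
                 tti = skipped, matching = skipped, validation = skipped)

  if (!is.null(counts)) {
    report$growth <- pipeline_stage("growth", {
      counts %>%
        dplyr::group_by(.data$organism, .data$packaging, .data$temperature_C) %>%
        tidyr::nest() %>%
        dplyr::ungroup() %>%
        dplyr::mutate(fit = purrr::map(data, fit_baranyi)) %>%
        dplyr::mutate(
          rate = purrr::map_dbl(.data$fit, ~ .x$params$mu),
          lag_d = purrr::map_dbl(.data$fit, ~ if (.x$params$lag > 0) .x$params$lag else NA_real_),
          nmax = purrr::map_dbl(.data$fit, ~ .x$params$ymax),
          r_squared = purrr::map_dbl(.data$fit, ~ .x$r_squared)
        ) %>%
        dplyr::select(-"data")
    })
    report$arrhenius <- pipeline_stage("arrhenius", {
      report$growth$result %>%
        dplyr::group_by(.data$organism, .data$packaging) %>%
        tidyr::nest() %>%
        dplyr::ungroup() %>%
        dplyr::mutate(
          rate_fit = purrr::map(data, fit_arrhenius, value = rate,
                                tref_c = config$tref_c),
          ea_kj_mol = purrr::map_dbl(.data$rate_fit, ~ .x$Ea / 1000),
          kref = purrr::map_dbl(.data$rate_fit, ~ .x$kref),
          lambda_ref = purrr::map2_dbl(
            data, .data$rate_fit,
            ~ suppressWarnings(fit_lag_reference(.x, Ea = .y$Ea,
                                                 tref_c = config$tref_c))
          ),
          r_squared = purrr::map_dbl(.data$rate_fit, ~ .x$r_squared)
        ) %>%
        dplyr::select(-"data")
    })
    report$shelf_life <- pipeline_stage("shelf_life", {
      tvc <- dplyr::filter(report$arrhenius$result, .data$organism == "TVC")
      specs <- purrr::pmap(
        list(tvc$packaging, tvc$kref, tvc$ea_kj_mol, tvc$lambda_ref),
        function(pack, kref, ea, lref) {
          spec <- shelf_life_spec(log_n0 = config$log_n0,
                                  log_n1 = config$log_n1,
                                  kref = kref, Ea = ea * 1000,
                                  tref_c = config$tref_c, lambda_ref = lref)
          list(packaging = pack, spec = spec,
               curve = shelf_life_curve(spec, seq(0, 10, by = 0.5)))
        }
      )
      setNames(specs, tvc$packaging)
    })
  }

  if (!is.null(colors)) {
    report$tti <- pipeline_stage("tti", {
      per_label <- colors %>%
        dplyr::group_by(.data$tti_type, .data$enzyme_units,
                        .data$temperature_C) %>%
        tidyr::nest() %>%
        dplyr::ungroup() %>%
        dplyr::mutate(
          fit = purrr::map(data, ~ fit_logistic(normalize_response(.x))),
          k1 = purrr::map_dbl(.data$fit, "k1"),
          k2 = purrr::map_dbl(.data$fit, "k2"),
          r_squared = purrr::map_dbl(.data$fit, "r_squared")
        ) %>%
        dplyr::select(-"data")
      globals <- per_label %>%
        dplyr::group_by(.data$tti_type) %>%
        tidyr::nest() %>%
        dplyr::ungroup() %>%
        dplyr::mutate(model = purrr::map2(
          data, .data$tti_type,
          ~ fit_global_model(.x, tti_type = .y, tref_c = config$tref_c)
        )) %>%
        dplyr::select(-"data")
      list(per_label = per_label, global = globals)
    })
  }

  if (!is.null(counts) && !is.null(colors) &&
      report$shelf_life$status == "ok" && report$tti$status == "ok") {
    report$matching <- pipeline_stage("matching", {
      globals <- report$tti$result$global
      concs <- report$tti$result$per_label %>%
        dplyr::distinct(.data$tti_type, .data$enzyme_units)
      candidates <- concs %>%
        dplyr::left_join(globals, by = "tti_type") %>%
        dplyr::transmute(model = .data$model, conc = .data$enzyme_units)
      purrr::map(report$shelf_life$result, function(sl) {
        select_tti(sl$spec, candidates,
                   abuse_threshold_c = config$abuse_threshold_c,
                   endpoint = config$endpoint,
                   ea_window = config$ea_window_kj * 1000)
      })
    })
  }

  if (!is.null(profile) && !is.null(counts) &&
      report$arrhenius$status == "ok") {
    report$validation <- pipeline_stage("validation", {
      arr <- report$arrhenius$result
      teff <- purrr::map_dbl(arr$rate_fit, ~ effective_temperature(
        profile, Ea = .x$Ea, tref_c = config$tref_c))
      preds <- tibble(
        organism = arr$organism,
        packaging = arr$packaging,
        teff_c = teff,
        k_predicted = purrr::map2_dbl(arr$rate_fit, teff, predict_rate)
      )
      out <- list(predicted = preds)
      if (!is.null(config$dynamic_rates)) {
        joined <- dplyr::inner_join(
          config$dynamic_rates, preds, by = c("organism", "packaging"))
        out$report <- validation_report(joined)
      }
      out
    })
  }

  report$provenance <- list(
    seed = config$seed,
    tref_c = config$tref_c,
    log_n1 = config$log_n1,
    endpoint = config$endpoint,
    ea_window_kj = config$ea_window_kj,
    abuse_threshold_c = config$abuse_threshold_c
  )
  structure(report, class = "ttishelf_report")
}

#' @export
print.ttishelf_report <- function(x, ...) {
  cat("ttishelf pipeline report\n")
  for (stage in c("growth", "arrhenius", "shelf_life", "tti", "matching",
                  "validation")) {
    cat(sprintf("  %-11s %s\n", stage, x[[stage]]$status))
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serialises the tabular parts of a [run_pipeline()] report (fit summaries,
#' shelf-life curves, rankings, validation table) plus provenance to a JSON
#' file. Model objects are reduced to their parameters.
#'
#' @param report A `ttishelf_report`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "ttishelf_report")) {
    stop_domain("`report` must come from `run_pipeline()`.")
  }
  strip <- function(x) {
    if (inherits(x, c("arrhenius_fit", "tti_global_model",
                      "shelf_life_spec"))) {
      return(unclass(x))
    }
    if (inherits(x, "baranyi_fit")) {
      return(list(params = unclass(x$params), r_squared = x$r_squared))
    }
    if (inherits(x, "tti_match")) {
      return(list(max_abs_relative_deviation = x$max_abs_relative_deviation,
                  conservative_at_abuse = x$conservative_at_abuse))
    }
    if (inherits(x, "tti_logistic_fit")) {
      return(list(k1 = x$k1, k2 = x$k2, r_squared = x$r_squared))
    }
    if (inherits(x, "baranyi_params")) return(unclass(x))
    if (is.data.frame(x)) {
      # column orientation; list-columns are stripped element-wise
      return(purrr::map(as.list(x), function(col) {
        if (is.list(col)) purrr::map(col, strip) else col
      }))
    }
    if (is.list(x)) return(purrr::map(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
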