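#' Pipeline run configuration
#'
#' Validates and bundles every tunable parameter of the analysis pipeline.
#' The configuration is echoed verbatim into the run manifest so any run
#' can be reproduced.
#'
#' @param od_epsilon Minimum corrected OD for a valid F/OD point
#'   (absorbance units).
#' @param n_interior Interior knot count for the synthesis-rate spline, or
#'   `NULL` for the data-driven default.
#' @param margin_min Boundary margin excluded from synthesis-rate
#'   evaluation, minutes.
#' @param t_treat Treatment time for the induction analysis, minutes, or
#'   `NULL` to skip it.
#' @param window Induction response window, minutes.
#' @param clamp_f Floor negative corrected fluorescence at zero?
#' @param dialect Plate CSV dialect when reading from a path.
#' @param seed Seed recorded for simulation-derived inputs (metadata only).
#' @return A validated `run_config` list.
#' @export
run_config <- function(od_epsilon = 0.01, n_interior = NULL, margin_min = 30,
                       t_treat = NULL, window = 40, clamp_f = TRUE,
                       dialect = c("long", "wide"), seed = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(od_epsilon > 0, margin_min >= 0, window > 0)
  if (!is.null(n_interior)) stopifnot(n_interior >= 0)
  if (!is.null(t_treat)) stopifnot(t_treat >= 0)
  structure(list(od_epsilon = od_epsilon, n_interior = n_interior,
                 margin_min = margin_min, t_treat = t_treat, window = window,
                 clamp_f = clamp_f, dialect = dialect, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline on one plate
#'
#' Composes the analysis stages in measurement order: correction (blank OD,
#' background fluorescence, F/OD), discrete promoter activity, spline-based
#' synthesis rate, and — when `t_treat` is configured — the induction
#' response with within-background fractional normalization. Any stage
#' failure aborts with the stage name attached.
#'
#' @param wells Well table, an `nf_plate` from [render_plate()], or a path
#'   to a plate CSV.
#' @param layout Layout tibble or path to a layout TSV; taken from the
#'   plate when `wells` is an `nf_plate`.
#' @param config A [run_config()].
#' @return An `nf_run` list: `expression`, `activity`, `synthesis`,
#'   `response` (or `NULL`), `layout`, `manifest`.
#' @examples
#' plate <- render_plate(plate_scenarios()$wt_dps)
#' run <- run_pipeline(plate, config = run_config(t_treat = 170))
#' run$response
#' @export
run_pipeline <- function(wells, layout = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(wells, "nf_plate")) {
    if (is.null(layout)) layout <- wells$layout
    if (is.null(config$seed)) config$seed <- wells$config$seed
    wells <- wells$wells
  }
  if (is.character(wells)) wells <- read_plate(wells, dialect = config$dialect)
  if (is.character(layout)) layout <- read_layout(layout)
  if (is.null(layout)) abort("A plate layout is required")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  expression <- stage("correction",
                      correct_plate(wells, layout,
                                    od_epsilon = config$od_epsilon,
                                    clamp_f = config$clamp_f))
  activity <- stage("activity", promoter_activity(expression))
  synthesis <- stage("synthesis",
                     synthesis_rate(expression,
                                    n_interior = config$n_interior,
                                    margin_min = config$margin_min,
                                    od_epsilon = config$od_epsilon))
  response <- NULL
  if (!is.null(config$t_treat)) {
    response <- stage("induction", {
      induction_response(expression, t_treat = config$t_treat,
                         window = config$window) %>%
        left_join(select(layout, "well_id", "genotype", "position",
                         "replicate"),
                  by = "well_id") %>%
        fractional_response()
    })
  }
  n_masked <- sum(!expression$mask)
  n_floored <- if (is.null(response)) 0L else sum(response$floored)
  manifest <- list(
    parameters = unclass(config),
    n_wells = dplyr::n_distinct(expression$well_id),
    n_time_points = dplyr::n_distinct(expression$time_min),
    warnings = list(masked_points = n_masked, floored_responses = n_floored),
    seed = config$seed,
    version = as.character(utils::packageVersion("nucleoflux")))
  structure(list(expression = expression, activity = activity,
                 synthesis = synthesis, response = response,
                 layout = layout, manifest = manifest),
            class = "nf_run")
}

#' @export
print.nf_run <- function(x, ...) {
  cat("Promoter-activity pipeline run\n")
  cat("  wells: ", x$manifest$n_wells, "; time points: ",
      x$manifest$n_time_points, "\n", sep = "")
  cat("  masked expression points: ",
      x$manifest$warnings$masked_points, "\n", sep = "")
  if (!is.null(x$response)) {
    cat("  induction responses: ", nrow(x$response), " wells\n", sep = "")
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x `nf_run` object.
#' @param ... Unused.
#' @return Tibble with well and point counts and flag totals.
#' @export
glance.nf_run <- function(x, ...) {
  tibble(n_wells = x$manifest$n_wells,
         n_time_points = x$manifest$n_time_points,
         n_masked_points = x$manifest$warnings$masked_points,
         n_floored_responses = x$manifest$warnings$floored_responses,
         has_response = !is.null(x$response))
}

#' Per-well summary of a pipeline run
#'
#' @param x `nf_run` object.
#' @param endpoint_window Minutes of final unmasked data averaged for the
#'   end-point F/OD (default 60).
#' @param ... Unused.
#' @return Tibble with one row per sample well: layout metadata, end-point
#'   F/OD, peak discrete activity, peak synthesis rate and, if computed,
#'   the induction response and fraction.
#' @export
tidy.nf_run <- function(x, endpoint_window = 60, ...) {
  out <- endpoint_fod(x$expression, window_min = endpoint_window) %>%
    left_join(select(x$layout, "well_id", "genotype", "module", "position",
                     "medium", "replicate"),
              by = "well_id") %>%
    left_join(x$activity %>%
                filter(.data$mask) %>%
                group_by(.data$well_id) %>%
                summarise(peak_activity = max(.data$d_fod_clipped),
                          .groups = "drop"),
              by = "well_id") %>%
    left_join(x$synthesis %>%
                group_by(.data$well_id) %>%
                summarise(peak_q = max(.data$q), .groups = "drop"),
              by = "well_id")
  if (!is.null(x$response)) {
    out <- left_join(out,
                     select(x$response, "well_id", "delta_fod",
                            "fraction_pct"),
                     by = "well_id")
  }
  out
}

#' Stationary-phase end-point expression
#'
#' Mean F/OD over the final `window_min` minutes of unmasked data of each
#' well — the operational "final reporter amount" used for cross-condition
#' comparisons.
#'
#' @param expr Expression tibble.
#' @param window_min Averaging window, minutes (default 60).
#' @return Tibble `well_id`, `endpoint_fod`, `n_points`.
#' @export
endpoint_fod <- function(expr, window_min = 60) {
  expr %>%
    filter(.data$mask) %>%
    group_by(.data$well_id) %>%
    filter(.data$time_min >= max(.data$time_min) - window_min) %>%
    summarise(endpoint_fod = mean(.data$fod), n_points = dplyr::n(),
              .groups = "drop")
}

#' Exponential-phase mean expression
#'
#' Mean F/OD over the exponential window of each well, defined
#' operationally as the unmasked points where the corrected OD lies between
#' `od_frac[1]` and `od_frac[2]` of the well's maximum corrected OD. The
#' default window (10-60% of the maximum) covers mid-exponential growth
#' while excluding the noisy low-density start.
#'
#' @param expr Expression tibble.
#' @param od_frac Length-2 fractions of the maximum corrected OD bounding
#'   the window.
#' @return Tibble `well_id`, `expo_fod`, `n_points`.
#' @export
exponential_mean_fod <- function(expr, od_frac = c(0.1, 0.6)) {
  expr %>%
    filter(.data$mask) %>%
    group_by(.data$well_id) %>%
    filter(.data$od_corr >= od_frac[1] * max(.data$od_corr),
           .data$od_corr <= od_frac[2] * max(.data$od_corr)) %>%
    summarise(expo_fod = mean(.data$fod), n_points = dplyr::n(),
              .groups = "drop")
}

#' Compare pipeline runs across experimental groups
#'
#' Tabular analogue of the study's cross-condition figures: per group, the
#' mean and standard deviation of the stationary-phase end-point F/OD and
#' (when induction responses were computed) of the fractional response.
#'
#' @param runs An `nf_run` or a list of them.
#' @param by Layout columns defining the groups, e.g. `"position"`,
#'   `c("genotype", "medium")`.
#' @param endpoint_window Passed to [endpoint_fod()].
#' @return Tibble with one row per group: `n_wells`, `mean_endpoint_fod`,
#'   `sd_endpoint_fod`, and `mean_fraction_pct` / `sd_fraction_pct` when
#'   available.
#' @export
compare_groups <- function(runs, by = "position", endpoint_window = 60) {
  if (inherits(runs, "nf_run")) runs <- list(runs)
  if (length(runs) == 0) abort("Need at least one pipeline run")
  if (length(by) == 0) abort("Need at least one grouping column")
  per_well <- purrr::imap(runs, function(run, i) {
    tidy(run, endpoint_window = endpoint_window) %>%
      mutate(run_id = as.character(i))
  }) %>% bind_rows()
  bad <- setdiff(by, names(per_well))
  if (length(bad) > 0) {
    abort(paste0("Unknown grouping column(s): ", paste(bad, collapse = ", ")))
  }
  grouped <- per_well %>%
    group_by(across(dplyr::all_of(by))) %>%
    summarise(n_wells = dplyr::n(),
              mean_endpoint_fod = mean(.data$endpoint_fod),
              sd_endpoint_fod = ifelse(dplyr::n() > 1, sd(.data$endpoint_fod),
                                       0),
              mean_fraction_pct = if ("fraction_pct" %in% names(per_well)) {
                mean(.data$fraction_pct)
              } else NA_real_,
              sd_fraction_pct = if ("fraction_pct" %in% names(per_well)) {
                ifelse(dplyr::n() > 1, sd(.data$fraction_pct), 0)
              } else NA_real_,
              .groups = "drop")
  grouped
}
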