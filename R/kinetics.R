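#' Discrete promoter activity d(F/OD)
#'
#' The standard discrete proxy for promoter output: the first
#' difference of consecutive F/OD values,
#' \eqn{[d(F/OD)]_n = (F/OD)_n - (F/OD)_{n-1}}. Signed differences are kept
#' in `d_fod_raw`; `d_fod_clipped` sets negative values to zero, which is
#' the form used for graphical display. A masked expression point
#' invalidates both adjacent differences.
#'
#' @param expr Expression tibble from [correct_plate()] /[compute_fod()]
#'   (may hold many wells).
#' @return Activity tibble: `well_id`, `time_min` (from the second point of
#'   each well onward), `d_fod_raw`, `d_fod_clipped`, `mask`.
#' @export
promoter_activity <- function(expr) {
  expr <- as_tibble(expr)
  out <- expr %>%
    group_by(.data$well_id) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    mutate(d_fod_raw = .data$fod - dplyr::lag(.data$fod),
           mask_pair = .data$mask & dplyr::lag(.data$mask)) %>%
    filter(dplyr::row_number() > 1) %>%
    ungroup() %>%
    mutate(d_fod_raw = ifelse(.data$mask_pair, .data$d_fod_raw, NA_real_),
           d_fod_clipped = pmax(.data$d_fod_raw, 0)) %>%
    select("well_id", "time_min", "d_fod_raw", "d_fod_clipped",
           mask = "mask_pair")
  empty <- out %>%
    group_by(.data$well_id) %>%
    summarise(all_masked = !any(.data$mask), .groups = "drop") %>%
    filter(.data$all_masked)
  if (nrow(empty) > 0) {
    warn(paste0("No unmasked consecutive points for well(s): ",
                paste(empty$well_id, collapse = ", ")))
  }
  out
}

#' Spline-based reporter synthesis rate
#'
#' Estimates the instantaneous per-biomass reporter synthesis rate
#' \eqn{q(t) = F'(t) / OD(t)} for each well: corrected fluorescence and
#' corrected OD are each smoothed with a least-squares cubic B-spline
#' (Schoenberg-Whitney knot selection, see [select_knots()]), the
#' fluorescence spline is differentiated analytically, and the ratio is
#' evaluated on the interior of the time grid. The margins are excluded
#' because cubic-spline derivatives are unreliable near the boundaries.
#'
#' @param expr Expression tibble (may hold many wells); only unmasked points
#'   are fitted.
#' @param n_interior Number of interior knots; default
#'   `max(4, floor(N / 12))` for N unmasked points, trading smoothness for
#'   simplicity and speed.
#' @param margin_min Minutes excluded at each end of the unmasked span
#'   (default 30).
#' @param od_epsilon Floor applied to the OD spline in the denominator.
#' @return Synthesis tibble: `well_id`, `time_min` (interior evaluation
#'   grid), `q` (fluorescence units per minute per absorbance unit). The
#'   knot vectors used are stored in the `"knots"` attribute, keyed by well.
#' @examples
#' plate <- render_plate(plate_scenarios()$wt_hns)
#' expr <- correct_plate(plate$wells, plate$layout)
#' synth <- synthesis_rate(expr)
#' head(synth)
#' @export
synthesis_rate <- function(expr, n_interior = NULL, margin_min = 30,
                           od_epsilon = 0.01) {
  expr <- as_tibble(expr)
  pieces <- list()
  knot_sets <- list()
  for (id in unique(expr$well_id)) {
    w <- expr %>%
      filter(.data$well_id == id, .data$mask) %>%
      arrange(.data$time_min)
    if (nrow(w) < 10) {
      abort(paste0("Well ", id, ": need >= 10 unmasked points for the ",
                   "synthesis-rate spline fit; got ", nrow(w)))
    }
    if (all(w$od_corr <= 0)) {
      abort(paste0("Well ", id, ": corrected OD non-positive throughout"))
    }
    n_int <- if (is.null(n_interior)) max(4L, floor(nrow(w) / 12)) else n_interior
    knots <- select_knots(w$time_min, n_int)
    f_fit <- fit_lsq_cubic_spline(w$time_min, w$f_corr, knots)
    od_fit <- fit_lsq_cubic_spline(w$time_min, w$od_corr, knots)
    lo <- min(w$time_min) + margin_min
    hi <- max(w$time_min) - margin_min
    eval_t <- w$time_min[w$time_min >= lo & w$time_min <= hi]
    if (length(eval_t) == 0) {
      abort(paste0("Well ", id, ": margin_min leaves no interior ",
                   "evaluation points"))
    }
    q <- predict(f_fit, eval_t, deriv = 1L) /
      pmax(predict(od_fit, eval_t), od_epsilon)
    pieces[[id]] <- tibble(well_id = id, time_min = eval_t, q = q)
    knot_sets[[id]] <- knots
  }
  out <- bind_rows(pieces)
  attr(out, "knots") <- knot_sets
  out
}
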