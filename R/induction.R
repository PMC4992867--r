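#' Induction response: F/OD increase over a treatment window
#'
#' Quantifies the response of a reporter to an inducing treatment (in the
#' reference protocol: sub-lethal hydrogen peroxide added after 170 min of
#' growth) as the total increase in F/OD after `window` minutes of
#' treatment compared to the pre-treatment value:
#' `delta_fod = fod(t_treat + window) - fod(t_treat)`. Endpoints are
#' evaluated at the nearest grid point, matching a 10-min measurement
#' cadence; negative responses are floored at zero with the flooring
#' recorded in `floored`.
#'
#' @param expr Expression tibble (may hold many wells).
#' @param t_treat Treatment time in minutes (default 170).
#' @param window Response window in minutes (default 40, the span over
#'   which the oxidative-stress response is essentially complete).
#' @return Tibble with one row per well: `well_id`, `t_treat`, `t_end`
#'   (grid times actually used), `delta_fod_raw` (signed), `delta_fod`
#'   (floored at 0), `floored`.
#' @export
induction_response <- function(expr, t_treat = 170, window = 40) {
  expr <- as_tibble(expr)
  one <- function(w) {
    w <- arrange(w, .data$time_min)
    grid <- w$time_min
    if (t_treat < min(grid) || t_treat + window > max(grid)) {
      abort(paste0("Treatment window [", t_treat, ", ", t_treat + window,
                   "] min extends beyond the measured span [", min(grid),
                   ", ", max(grid), "] for well ", w$well_id[1]))
    }
    i1 <- which.min(abs(grid - t_treat))
    i2 <- which.min(abs(grid - (t_treat + window)))
    for (i in c(i1, i2)) {
      if (!w$mask[i]) {
        abort(paste0("Well ", w$well_id[1], ": F/OD masked at t = ",
                     grid[i], " min; cannot evaluate the induction response"))
      }
    }
    d <- w$fod[i2] - w$fod[i1]
    tibble(well_id = w$well_id[1], t_treat = grid[i1], t_end = grid[i2],
           delta_fod_raw = d, delta_fod = max(d, 0), floored = d < 0)
  }
  expr %>%
    split(expr$well_id) %>%
    purrr::map(one) %>%
    bind_rows() %>%
    arrange(.data$well_id)
}

#' Fractional induction response within a background
#'
#' Normalizes per-position induction responses to the total response of all
#' positions within the same genetic background (and, if present, the same
#' replicate/experiment): `fraction_pct = 100 * delta_fod / sum(delta_fod)`.
#' With k positions contributing equally each fraction is 100/k; for the
#' six-position design this reference value is 100/6, approximately 17%.
#' Groups whose total response is zero get `NA` fractions and a
#' `zero_total` flag.
#'
#' @param responses Tibble with a `delta_fod` column plus grouping columns.
#' @param group_cols Columns defining a normalization group; defaults to
#'   `"genotype"` plus `"replicate"` when present.
#' @return The input with `fraction_pct` and `zero_total` columns added.
#' @examples
#' fractional_response(
#'   tibble::tibble(genotype = "wildtype",
#'                  position = c("OL", "OR", "ML", "MR", "TL", "TR"),
#'                  delta_fod = rep(60, 6)))
#' @export
fractional_response <- function(responses, group_cols = NULL) {
  responses <- as_tibble(responses)
  if (!"delta_fod" %in% names(responses)) {
    abort("responses must contain a delta_fod column")
  }
  if (is.null(group_cols)) {
    group_cols <- intersect(c("genotype", "replicate"), names(responses))
  }
  grouped <- if (length(group_cols) > 0) {
    group_by(responses, across(dplyr::all_of(group_cols)))
  } else {
    group_by(responses)
  }
  sizes <- dplyr::group_size(grouped)
  if (any(sizes < 2)) {
    abort("Each normalization group needs >= 2 positions")
  }
  grouped %>%
    mutate(total = sum(pmax(.data$delta_fod, 0)),
           zero_total = .data$total == 0,
           fraction_pct = ifelse(.data$zero_total, NA_real_,
                                 100 * pmax(.data$delta_fod, 0) / .data$total)) %>%
    ungroup() %>%
    select(-"total")
}

#' Between-replicate dispersion of fractional responses
#'
#' Summarizes how strongly the fractional response of each position
#' fluctuates between independent experiments: per genotype and position,
#' the minimum, maximum and standard deviation of `fraction_pct` across
#' replicates. Strong fluctuation is the signature of a perturbed
#' background (e.g. cells lacking HU), whereas wild-type fractions are
#' stable.
#'
#' @param fractions Tibble from [fractional_response()] with `genotype`,
#'   `position`, `replicate` and `fraction_pct` columns.
#' @return Tibble with one row per genotype and position: `n_replicates`,
#'   `min_pct`, `max_pct`, `range_pct`, `sd_pct`.
#' @export
replicate_dispersion <- function(fractions) {
  fractions <- as_tibble(fractions)
  need <- c("genotype", "position", "replicate", "fraction_pct")
  missing_cols <- setdiff(need, names(fractions))
  if (length(missing_cols) > 0) {
    abort(paste0("fractions lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n_exp <- fractions %>%
    group_by(.data$genotype) %>%
    summarise(n = dplyr::n_distinct(.data$replicate), .groups = "drop")
  if (any(n_exp$n < 2)) {
    abort(paste0("Need >= 2 experiments per genotype to measure dispersion; ",
                 "got a single experiment for: ",
                 paste(n_exp$genotype[n_exp$n < 2], collapse = ", ")))
  }
  fractions %>%
    group_by(.data$genotype, .data$position) %>%
    summarise(n_replicates = dplyr::n(),
              min_pct = min(.data$fraction_pct),
              max_pct = max(.data$fraction_pct),
              range_pct = max(.data$fraction_pct) - min(.data$fraction_pct),
              sd_pct = sd(.data$fraction_pct),
              .groups = "drop")
}
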