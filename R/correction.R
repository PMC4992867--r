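#' Blank-correct optical density
#'
#' Subtracts the time-matched mean optical density of the blank wells
#' (medium only, no cells) from a sample well's raw OD. The result may be
#' slightly negative in early lag; such points are masked later by the
#' F/OD step rather than clamped here.
#'
#' @param sample One well as a tibble with `time_min` and `od_raw`.
#' @param blanks Well table of blank wells (`well_id`, `time_min`, `od_raw`).
#' @return `sample` with an `od_corr` column added.
#' @export
blank_correct_od <- function(sample, blanks) {
  ref <- reference_mean(blanks, sample$time_min, "od_raw", "blank")
  mutate(as_tibble(sample), od_corr = .data$od_raw - ref)
}

#' Background-correct fluorescence
#'
#' Subtracts the time-matched mean fluorescence of the background wells —
#' the non-fluorescent reference strain, which grows and autofluoresces but
#' carries no reporter — from a sample well's raw fluorescence.
#'
#' @param sample One well as a tibble with `time_min` and `fluor_raw`.
#' @param backgrounds Well table of background wells.
#' @return `sample` with an `f_corr` column added.
#' @export
background_correct_f <- function(sample, backgrounds) {
  ref <- reference_mean(backgrounds, sample$time_min, "fluor_raw", "background")
  mutate(as_tibble(sample), f_corr = .data$fluor_raw - ref)
}

# Time-matched mean of a reference group; errors on empty group or grid
# mismatch.
reference_mean <- function(ref_wells, time_min, col, what) {
  if (is.null(ref_wells) || nrow(ref_wells) == 0) {
    abort(paste0("No ", what, " wells available; add at least one well with ",
                 "role '", what, "' to the plate layout"))
  }
  ref <- ref_wells %>%
    group_by(.data$time_min) %>%
    summarise(ref = mean(.data[[col]]), .groups = "drop") %>%
    arrange(.data$time_min)
  if (length(ref$time_min) != length(time_min) ||
      any(ref$time_min != time_min)) {
    abort(paste0("Time grid of ", what, " wells does not match the sample"))
  }
  ref$ref
}

#' Compute per-biomass expression (F/OD)
#'
#' Divides background-corrected fluorescence by blank-corrected optical
#' density at each time point. Points where the corrected OD falls below
#' `od_epsilon` are masked (`mask = FALSE`, `fod = NA`) rather than
#' producing unstable ratios; gaps (`NA` readings) are masked too. Negative
#' corrected fluorescence is clamped to zero before division by default,
#' since negative reporter signal is physically meaningless.
#'
#' @param corrected Tibble with `od_corr` and `f_corr` columns (output of the
#'   two correction steps, or [correct_plate()] internals).
#' @param od_epsilon Minimum corrected OD (absorbance units) for a valid
#'   ratio; default 0.01.
#' @param clamp_f If `TRUE` (default), floor `f_corr` at 0 before dividing.
#' @return The input with `fod` and logical `mask` columns added.
#' @export
compute_fod <- function(corrected, od_epsilon = 0.01, clamp_f = TRUE) {
  stopifnot(od_epsilon > 0)
  df <- as_tibble(corrected)
  f <- df$f_corr
  if (clamp_f) f <- pmax(f, 0)
  mask <- !is.na(df$od_corr) & !is.na(f) & df$od_corr >= od_epsilon
  fod <- ifelse(mask, f / df$od_corr, NA_real_)
  mutate(df, fod = fod, mask = mask)
}

#' Correct a whole plate and compute F/OD
#'
#' Applies blank correction (OD), background correction (fluorescence) and
#' the F/OD ratio to every sample well of a plate, using the roles in the
#' layout to find the reference wells.
#'
#' @param wells Well table from [read_plate()] or [render_plate()].
#' @param layout Layout tibble from [read_layout()].
#' @param od_epsilon Passed to [compute_fod()].
#' @param clamp_f Passed to [compute_fod()].
#' @param roles Which roles to correct; by default only `"sample"` wells.
#' @return Expression tibble: `well_id`, `time_min`, `od_corr`, `f_corr`,
#'   `fod`, `mask`, one row per well and time point.
#' @examples
#' plate <- render_plate(plate_scenarios()$wt_dps)
#' expr <- correct_plate(plate$wells, plate$layout)
#' dplyr::filter(expr, mask) |> head()
#' @export
correct_plate <- function(wells, layout, od_epsilon = 0.01, clamp_f = TRUE,
                          roles = "sample") {
  wells <- validate_wells(wells)
  layout <- validate_layout(layout)
  unknown <- setdiff(unique(wells$well_id), layout$well_id)
  if (length(unknown) > 0) {
    abort(paste0("Wells absent from layout: ", paste(unknown, collapse = ", ")))
  }
  ids_of <- function(role) layout$well_id[layout$role == role]
  blanks <- filter(wells, .data$well_id %in% ids_of("blank"))
  backgrounds <- filter(wells, .data$well_id %in% ids_of("background"))
  if (nrow(blanks) == 0) {
    abort("No blank wells in layout; cannot blank-correct OD")
  }
  if (nrow(backgrounds) == 0) {
    abort("No background wells in layout; cannot background-correct ",
          "fluorescence")
  }
  targets <- layout$well_id[layout$role %in% roles]
  grid <- sort(unique(wells$time_min))
  blank_ref <- reference_mean(blanks, grid, "od_raw", "blank")
  bg_ref <- reference_mean(backgrounds, grid, "fluor_raw", "background")
  wells %>%
    filter(.data$well_id %in% targets) %>%
    group_by(.data$well_id) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    mutate(od_corr = .data$od_raw - blank_ref,
           f_corr = .data$fluor_raw - bg_ref) %>%
    ungroup() %>%
    select("well_id", "time_min", "od_corr", "f_corr") %>%
    compute_fod(od_epsilon = od_epsilon, clamp_f = clamp_f)
}
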