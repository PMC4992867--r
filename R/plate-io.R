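#' Read a plate-reader export
#'
#' Parses a CSV export of a microplate time course into a long well table
#' with one row per well and time point. Two dialects are supported:
#'
#' * `"long"`: columns `well_id`, `time_min`, `channel` (`"OD"` or `"F"`),
#'   `value`.
#' * `"wide"`: one `time_min` column plus a `<well>_OD` and `<well>_F`
#'   column per well (e.g. `B3_OD`, `B3_F`).
#'
#' Optical density is the 595 nm absorbance; fluorescence is the 485/535 nm
#' reporter channel. Units are passed through unchanged. Missing single
#' readings may be encoded as `NA`; they are kept as gaps and masked by
#' downstream steps, never interpolated.
#'
#' @param path Path to the CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param time_unit `"min"` (default) or `"sec"`; seconds are converted to
#'   minutes on read.
#' @return A tibble with columns `well_id`, `time_min`, `od_raw`,
#'   `fluor_raw`, sorted by well and time. The time grid is validated to be
#'   strictly increasing and identical across wells.
#' @examples
#' plate <- render_plate(plate_scenarios()$wt_dps)
#' f <- tempfile(fileext = ".csv")
#' write_plate(plate$wells, f)
#' wells <- read_plate(f)
#' head(wells)
#' @export
read_plate <- function(path, dialect = c("long", "wide"),
                       time_unit = c("min", "sec")) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) {
    abort(paste0("Plate file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  wells <- if (dialect == "long") parse_long_plate(raw) else parse_wide_plate(raw)
  if (time_unit == "sec") {
    wells$time_min <- wells$time_min / 60
  }
  validate_wells(wells)
}

parse_long_plate <- function(raw) {
  need <- c("well_id", "time_min", "channel", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Long plate file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(raw$channel), c("OD", "F"))
  if (length(bad) > 0) {
    abort(paste0("Unknown channel token(s): ", paste(bad, collapse = ", "),
                 "; expected OD or F"))
  }
  dup <- raw %>%
    dplyr::count(.data$well_id, .data$time_min, .data$channel) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Time grid not strictly increasing (duplicate readings) ",
                 "for well(s): ", paste(unique(dup$well_id), collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(raw, id_cols = c("well_id", "time_min"),
                             names_from = "channel", values_from = "value")
  for (ch in c("OD", "F")) {
    if (!ch %in% names(wide)) {
      abort(paste0("No ", ch, " readings present in file"))
    }
  }
  miss <- wide %>%
    group_by(.data$well_id) %>%
    summarise(no_od = all(is.na(.data$OD)), no_f = all(is.na(.data$F)),
              .groups = "drop") %>%
    filter(.data$no_od | .data$no_f)
  if (nrow(miss) > 0) {
    abort(paste0("Missing channel for well(s): ",
                 paste(miss$well_id, collapse = ", ")))
  }
  wide %>%
    rename(od_raw = "OD", fluor_raw = "F") %>%
    arrange(.data$well_id, .data$time_min)
}

parse_wide_plate <- function(raw) {
  if (!"time_min" %in% names(raw)) {
    abort("Wide plate file lacks a time_min column")
  }
  value_cols <- setdiff(names(raw), "time_min")
  m <- regmatches(value_cols, regexec("^(.*)_(OD|F)$", value_cols))
  ok <- lengths(m) == 3
  if (any(!ok)) {
    abort(paste0("Wide columns must be named <well>_OD / <well>_F; offending: ",
                 paste(value_cols[!ok], collapse = ", ")))
  }
  ids <- vapply(m, `[`, character(1), 2)
  chans <- vapply(m, `[`, character(1), 3)
  for (id in unique(ids)) {
    have <- chans[ids == id]
    if (!all(c("OD", "F") %in% have)) {
      abort(paste0("Missing channel for well: ", id))
    }
  }
  long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(value_cols),
                              names_to = c("well_id", "channel"),
                              names_pattern = "^(.*)_(OD|F)$",
                              values_to = "value")
  parse_long_plate(dplyr::rename(long, time_min = "time_min"))
}

#' Validate a well table
#'
#' Checks the invariants of the raw well container: strictly increasing time
#' within each well, a shared time grid across wells, and no negative raw
#' readings (gaps encoded as `NA` are allowed).
#'
#' @param wells Tibble with `well_id`, `time_min`, `od_raw`, `fluor_raw`.
#' @return The validated tibble, invisibly ordered by well and time.
#' @export
validate_wells <- function(wells) {
  need <- c("well_id", "time_min", "od_raw", "fluor_raw")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols) > 0) {
    abort(paste0("Well table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  wells <- as_tibble(wells) %>% arrange(.data$well_id, .data$time_min)
  grids <- split(wells$time_min, wells$well_id)
  for (id in names(grids)) {
    if (any(diff(grids[[id]]) <= 0)) {
      abort(paste0("Time grid not strictly increasing for well ", id))
    }
  }
  ref <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(ref) && all(g == ref),
                 logical(1))
  if (!all(same)) {
    abort(paste0("Wells measured on different time grids: ",
                 paste(names(grids)[!same], collapse = ", ")))
  }
  neg <- wells$od_raw < 0 | wells$fluor_raw < 0
  if (any(neg, na.rm = TRUE)) {
    abort("Negative raw readings found; raw OD and fluorescence must be >= 0")
  }
  wells
}

#' Read a plate layout
#'
#' Reads the tab-separated layout assigning each well a role and metadata.
#' Expected header: `well_id`, `role`, `genotype`, `module`, `position`,
#' `medium`, `replicate`. Roles are `blank` (medium only), `background`
#' (non-fluorescent reference strain) and `sample` (reporter strain).
#'
#' @param path Path to the TSV layout.
#' @return A validated layout tibble.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Layout file not found: ", path))
  }
  lay <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_layout(lay)
}

#' Validate a plate layout
#'
#' @param layout Layout tibble (see [read_layout()] for columns).
#' @return The validated layout tibble.
#' @export
validate_layout <- function(layout) {
  need <- c("well_id", "role", "genotype", "module", "position", "medium",
            "replicate")
  missing_cols <- setdiff(need, names(layout))
  if (length(missing_cols) > 0) {
    abort(paste0("Layout lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  layout <- as_tibble(layout)
  if (anyDuplicated(layout$well_id) > 0) {
    dup <- unique(layout$well_id[duplicated(layout$well_id)])
    abort(paste0("Duplicate well_id in layout: ", paste(dup, collapse = ", ")))
  }
  check_enum <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad) > 0) {
      abort(paste0("Unknown ", what, " token(s): ",
                   paste(bad, collapse = ", "), "; allowed: ",
                   paste(allowed, collapse = ", ")))
    }
  }
  check_enum(layout$role, nf_roles, "role")
  check_enum(layout$genotype, nf_genotypes, "genotype")
  check_enum(layout$module, nf_modules, "module")
  check_enum(layout$position, nf_positions, "position")
  bad_sample <- layout$role == "sample" & layout$module == "none"
  if (any(bad_sample)) {
    abort(paste0("Sample well(s) without a promoter module: ",
                 paste(layout$well_id[bad_sample], collapse = ", ")))
  }
  if (any(!is.finite(layout$replicate) | layout$replicate < 1)) {
    abort("replicate must be an integer >= 1")
  }
  layout
}

#' Write a plate to CSV
#'
#' Writes a well table in either dialect understood by [read_plate()].
#'
#' @param wells Well tibble (`well_id`, `time_min`, `od_raw`, `fluor_raw`).
#' @param path Output CSV path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_plate <- function(wells, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  long <- wells %>%
    tidyr::pivot_longer(cols = c("od_raw", "fluor_raw"), names_to = "channel",
                        values_to = "value") %>%
    mutate(channel = ifelse(.data$channel == "od_raw", "OD", "F")) %>%
    select("well_id", "time_min", "channel", "value")
  out <- if (dialect == "long") {
    long
  } else {
    long %>%
      tidyr::pivot_wider(id_cols = "time_min",
                         names_from = c("well_id", "channel"),
                         names_sep = "_", values_from = "value")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a plate layout to TSV
#'
#' @param layout Layout tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(layout, path, progress = FALSE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Writes one TSV per result kind present in a pipeline run (`expression`,
#' `activity`, `synthesis`, `response`) plus a JSON run manifest echoing
#' inputs, parameters, seed and package version. Empty tables produce a
#' header-only file.
#'
#' @param run A `nf_run` object from [run_pipeline()], or a named list of
#'   data frames.
#' @param out_dir Output directory, created if absent.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(run, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort(paste0("Cannot write to directory: ", out_dir))
  }
  kinds <- intersect(c("expression", "activity", "synthesis", "response"),
                     names(run))
  written <- character(0)
  for (kind in kinds) {
    tab <- run[[kind]]
    if (is.null(tab)) next
    path <- file.path(out_dir, paste0(kind, ".tsv"))
    readr::write_tsv(tab, path, progress = FALSE)
    written <- c(written, path)
  }
  manifest <- run$manifest
  if (is.null(manifest)) {
    manifest <- list(version = as.character(utils::packageVersion("nucleoflux")))
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(written, mpath))
}
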