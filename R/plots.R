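#' Plot a simulated plate
#'
#' Raw OD and fluorescence time courses of every well, coloured by layout
#' role.
#'
#' @param object `nf_plate` from [render_plate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nf_plate <- function(object, ...) {
  df <- object$wells %>%
    left_join(select(object$layout, "well_id", "role"), by = "well_id") %>%
    tidyr::pivot_longer(cols = c("od_raw", "fluor_raw"), names_to = "channel",
                        values_to = "value") %>%
    mutate(channel = ifelse(.data$channel == "od_raw",
                            "optical density (595 nm)",
                            "fluorescence (485/535 nm)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value,
                                   group = .data$well_id,
                                   colour = .data$role)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = paste0("Simulated plate: ", object$config$name)) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' @param object `nf_run` from [run_pipeline()].
#' @param type Which result to plot: per-biomass expression (`F/OD`),
#'   discrete promoter activity, spline synthesis rate, or the fractional
#'   induction response.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nf_run <- function(object,
                            type = c("expression", "activity", "synthesis",
                                     "response"), ...) {
  type <- match.arg(type)
  switch(type,
         expression = plot_expression(object$expression, object$layout),
         activity = plot_activity(object$activity, object$layout),
         synthesis = plot_synthesis(object$synthesis, object$layout),
         response = plot_response(object$response))
}

join_position <- function(df, layout) {
  if (is.null(layout)) return(mutate(df, position = "well"))
  left_join(df, select(layout, "well_id", "position"), by = "well_id")
}

#' Plot per-biomass expression (F/OD) curves
#'
#' @param expr Expression tibble.
#' @param layout Optional layout tibble used to colour wells by position.
#' @return A ggplot object.
#' @export
plot_expression <- function(expr, layout = NULL) {
  df <- join_position(filter(expr, .data$mask), layout)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$fod,
                                   group = .data$well_id,
                                   colour = .data$position)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "F/OD",
                  colour = "position") +
    ggplot2::theme_minimal()
}

#' Plot discrete promoter activity profiles
#'
#' @param activity Activity tibble from [promoter_activity()].
#' @param layout Optional layout tibble.
#' @return A ggplot object.
#' @export
plot_activity <- function(activity, layout = NULL) {
  df <- join_position(filter(activity, .data$mask), layout)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                   y = .data$d_fod_clipped,
                                   group = .data$well_id,
                                   colour = .data$position)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "promoter activity d(F/OD)",
                  colour = "position") +
    ggplot2::theme_minimal()
}

#' Plot spline-based synthesis-rate profiles
#'
#' @param synthesis Synthesis tibble from [synthesis_rate()].
#' @param layout Optional layout tibble.
#' @return A ggplot object.
#' @export
plot_synthesis <- function(synthesis, layout = NULL) {
  df <- join_position(synthesis, layout)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$q,
                                   group = .data$well_id,
                                   colour = .data$position)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = "synthesis rate q(t) = F'(t)/OD(t)",
                  colour = "position") +
    ggplot2::theme_minimal()
}

#' Plot fractional induction responses per position
#'
#' The dashed reference line marks the equal-contribution expectation
#' 100/k for k positions in a background.
#'
#' @param response Response tibble from [run_pipeline()] (with `genotype`,
#'   `position`, `fraction_pct`).
#' @return A ggplot object.
#' @export
plot_response <- function(response) {
  if (is.null(response)) abort("No induction response table to plot")
  k <- response %>%
    group_by(.data$genotype) %>%
    summarise(k = dplyr::n_distinct(.data$position), .groups = "drop")
  ggplot2::ggplot(response, ggplot2::aes(x = .data$position,
                                         y = .data$fraction_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(data = k,
                        ggplot2::aes(yintercept = 100 / .data$k),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "chromosomal position",
                  y = "fraction of total response (%)") +
    ggplot2::theme_minimal()
}
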