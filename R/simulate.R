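#' Growth-model parameters
#'
#' Parameterizes the deterministic growth model used by the simulator:
#' logistic growth after an initial lag, an optional intermediate lag in
#' which growth pauses at a given density (as seen after a rich-medium
#' starter culture is switched to minimal medium), and a constant blank
#' offset added to every absorbance reading. The inoculum is fixed at
#' 1:200 of the carrying capacity, matching the dilution used for plate
#' inoculation.
#'
#' @param lag_min Initial lag duration, minutes.
#' @param mu_max Maximal specific growth rate, per minute.
#' @param od_capacity Carrying capacity, absorbance units.
#' @param intermediate_lag `NULL`, or `list(start_od=, duration_min=)`:
#'   growth pauses for `duration_min` once the culture reaches `start_od`.
#' @param od_blank_offset Absorbance added to all wells (medium + plate).
#' @return A `growth_params` list.
#' @export
growth_params <- function(lag_min = 40, mu_max = 0.028, od_capacity = 0.55,
                          intermediate_lag = NULL, od_blank_offset = 0.04) {
  stopifnot(lag_min >= 0, mu_max >= 0, od_capacity > 0, od_blank_offset >= 0)
  if (!is.null(intermediate_lag)) {
    stopifnot(is.list(intermediate_lag),
              intermediate_lag$start_od > 0,
              intermediate_lag$start_od < od_capacity,
              intermediate_lag$duration_min >= 0)
  }
  structure(list(lag_min = lag_min, mu_max = mu_max,
                 od_capacity = od_capacity,
                 intermediate_lag = intermediate_lag,
                 od_blank_offset = od_blank_offset),
            class = "growth_params")
}

#' Simulate a growth curve
#'
#' Closed-form piecewise logistic growth: the culture holds at the inoculum
#' density (`od_capacity / 200`) during the lag, grows logistically
#' afterwards, and optionally pauses for the configured intermediate lag.
#' The specific growth rate `mu(t) = d log OD / dt` is returned alongside;
#' it is `mu_max * (1 - OD/K)` while growing and 0 during lags.
#'
#' @param growth A [growth_params()] object.
#' @param time_min Time grid, minutes.
#' @return Tibble `time_min`, `od_true`, `mu`, `in_intermediate_lag`, with
#'   attribute `"mu_max"`.
#' @export
simulate_growth <- function(growth, time_min) {
  stopifnot(inherits(growth, "growth_params"))
  t <- as.numeric(time_min)
  K <- growth$od_capacity
  od0 <- K / 200
  mu <- growth$mu_max
  logistic <- function(tau) K / (1 + (K / od0 - 1) * exp(-mu * tau))
  # Effective growth time: clock time minus lag phases elapsed so far.
  tau <- pmax(t - growth$lag_min, 0)
  in_ilag <- rep(FALSE, length(t))
  il <- growth$intermediate_lag
  if (!is.null(il) && mu > 0 && il$start_od > od0) {
    # Growth time at which the pause density is reached.
    tau_pause <- log((il$start_od / (K - il$start_od)) * ((K - od0) / od0)) / mu
    t_pause <- growth$lag_min + tau_pause
    in_ilag <- t >= t_pause & t < t_pause + il$duration_min
    after <- t >= t_pause + il$duration_min
    tau[in_ilag] <- tau_pause
    tau[after] <- tau[after] - il$duration_min
  }
  od <- logistic(tau)
  growing <- t >= growth$lag_min & !in_ilag & mu > 0
  mu_t <- ifelse(growing, mu * (1 - od / K), 0)
  out <- tibble(time_min = t, od_true = od, mu = mu_t,
                in_intermediate_lag = in_ilag)
  attr(out, "mu_max") <- mu
  out
}

#' Promoter-program parameters
#'
#' Encodes one of the growth-phase expression archetypes of the nucleoid
#' proteins as a per-biomass synthesis-rate program
#' \eqn{a(t) = base\_rate \times gain(t)} with
#' `gain(t) = growth * mu(t)/mu_max + const + stationary * (1 - mu(t)/mu_max)
#'  + lag * I(intermediate lag) + pulse * I(treatment window)`:
#'
#' * `"fis"`: growth-rate-coupled — sharply on at the onset of exponential
#'   growth, off towards stationary phase (`growth = 1`).
#' * `"hns"`: constitutive with a slight rise towards stationary phase
#'   (`const = 1`, `stationary = 0.3`).
#' * `"dps"`: induced on transition to stationary phase (`stationary = 1`),
#'   weakly active in exponential phase (`const = 0.15`), transiently
#'   activated during an intermediate lag (`lag = 0.6`), and inducible by
#'   oxidative stress with a pulse that terminates `pulse_duration` minutes
#'   after treatment (`pulse = 4`).
#' * `"custom"`: all gains 0; set them via `gains`.
#'
#' @param archetype `"fis"`, `"hns"`, `"dps"` or `"custom"`.
#' @param base_rate Per-biomass synthesis rate (fluorescence units per
#'   minute per absorbance unit); archetype defaults are fis 25, hns 8,
#'   dps 30.
#' @param gains Named list overriding any of `growth`, `const`,
#'   `stationary`, `lag`, `pulse`.
#' @param pulse_duration Minutes the treatment pulse stays on (default 40).
#' @return A `promoter_program` list.
#' @export
promoter_program <- function(archetype = c("fis", "hns", "dps", "custom"),
                             base_rate = NULL, gains = NULL,
                             pulse_duration = 40) {
  archetype <- match.arg(archetype)
  defaults <- switch(archetype,
    fis = list(rate = 25, g = list(growth = 1, const = 0, stationary = 0,
                                   lag = 0, pulse = 0)),
    hns = list(rate = 8, g = list(growth = 0, const = 1, stationary = 0.3,
                                  lag = 0, pulse = 0)),
    dps = list(rate = 30, g = list(growth = 0, const = 0.15, stationary = 1,
                                   lag = 0.6, pulse = 4)),
    custom = list(rate = 1, g = list(growth = 0, const = 0, stationary = 0,
                                     lag = 0, pulse = 0)))
  g <- defaults$g
  if (!is.null(gains)) {
    bad <- setdiff(names(gains), names(g))
    if (length(bad) > 0) {
      abort(paste0("Unknown gain(s): ", paste(bad, collapse = ", ")))
    }
    g[names(gains)] <- gains
  }
  if (any(unlist(g) < 0)) abort("Gains must be >= 0")
  rate <- if (is.null(base_rate)) defaults$rate else base_rate
  stopifnot(rate >= 0, pulse_duration >= 0)
  structure(list(archetype = archetype, base_rate = rate, gains = g,
                 pulse_duration = pulse_duration),
            class = "promoter_program")
}

#' Chromosomal position-effect parameters
#'
#' Describes how a module's chromosomal context scales its expression:
#'
#' * replication-associated gene dosage: copy-number multiplier
#'   `2^(dosage_coeff * (1 - rel_position) * mu(t)/mu_max)`, so
#'   origin-proximal modules (`rel_position` near 0) gain up to
#'   `2^dosage_coeff`-fold during fast growth and all dosage effects vanish
#'   in stationary phase;
#' * a constant genotype- and position-specific multiplier (1 in wild
#'   type);
#' * a lognormal between-replicate fluctuation with coefficient of
#'   variation `replicate_cv` (0 in wild type), drawn once per well;
#' * an `upstream_coupling` factor applied while a configured upstream
#'   operon is transcribing (1 = no coupling).
#'
#' @param rel_position Position on the origin-terminus axis, 0 at the
#'   replication origin, 1 at the terminus.
#' @param dosage_coeff Dosage exponent coefficient (>= 0).
#' @param genotype_multiplier Constant expression multiplier (> 0).
#' @param replicate_cv Lognormal CV of the per-replicate fluctuation (>= 0).
#' @param upstream_coupling Multiplier while upstream transcription is
#'   active (> 0).
#' @return A `position_effect` list.
#' @export
position_effect <- function(rel_position, dosage_coeff = 1,
                            genotype_multiplier = 1, replicate_cv = 0,
                            upstream_coupling = 1) {
  stopifnot(rel_position >= 0, rel_position <= 1, dosage_coeff >= 0,
            genotype_multiplier > 0, replicate_cv >= 0, upstream_coupling > 0)
  structure(list(rel_position = rel_position, dosage_coeff = dosage_coeff,
                 genotype_multiplier = genotype_multiplier,
                 replicate_cv = replicate_cv,
                 upstream_coupling = upstream_coupling),
            class = "position_effect")
}

#' Simulate true reporter accumulation in one well
#'
#' Integrates the accumulation model `dF/dt = a(t) * OD(t)` for a stable,
#' non-degrading fluorescent reporter, where the per-biomass activity
#' `a(t)` combines the promoter program, the gene-dosage multiplier, the
#' genotype multiplier, an optional per-replicate fluctuation draw and
#' optional upstream-transcription coupling.
#'
#' @param curve Growth curve from [simulate_growth()].
#' @param program A [promoter_program()].
#' @param effect A [position_effect()].
#' @param events Optional list: `treat_time` (minutes; turns the pulse gain
#'   on for `program$pulse_duration` minutes) and `upstream_active`
#'   (logical; applies `effect$upstream_coupling`).
#' @param replicate_draw Per-replicate multiplier (default 1; drawn by
#'   [render_plate()] when `replicate_cv > 0`).
#' @return `curve` with `a_true` (per-biomass synthesis rate) and `f_true`
#'   (accumulated reporter, trapezoidal integral of `a * OD`) added.
#' @export
simulate_reporter <- function(curve, program, effect, events = list(),
                              replicate_draw = 1) {
  stopifnot(inherits(program, "promoter_program"),
            inherits(effect, "position_effect"))
  mu_max <- attr(curve, "mu_max")
  if (is.null(mu_max)) abort("curve must come from simulate_growth()")
  t <- curve$time_min
  mu_rel <- if (mu_max > 0) curve$mu / mu_max else rep(0, length(t))
  g <- program$gains
  pulse_on <- rep(FALSE, length(t))
  if (!is.null(events$treat_time)) {
    pulse_on <- t >= events$treat_time &
      t < events$treat_time + program$pulse_duration
  }
  gain <- g$growth * mu_rel + g$const + g$stationary * (1 - mu_rel) +
    g$lag * curve$in_intermediate_lag + g$pulse * pulse_on
  dosage <- 2^(effect$dosage_coeff * (1 - effect$rel_position) * mu_rel)
  coupling <- if (isTRUE(events$upstream_active)) effect$upstream_coupling else 1
  a <- program$base_rate * gain * dosage * effect$genotype_multiplier *
    replicate_draw * coupling
  integrand <- a * curve$od_true
  f_true <- cumtrapz(t, integrand)
  out <- mutate(curve, a_true = a, f_true = f_true)
  attr(out, "mu_max") <- mu_max
  out
}

cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Assemble a plate scenario
#'
#' Bundles growth, wells, noise, gain, seed and grid into a renderable
#' scenario. Each well entry (see [well_entry()]) carries layout metadata
#' plus its promoter program and position effect; blank and background
#' wells carry no program.
#'
#' @param wells List of [well_entry()] objects.
#' @param growth Default [growth_params()] for wells without their own.
#' @param noise List: `od_sd` (absorbance), `f_sd` (fluorescence units),
#'   `autofluor_per_od` (fluorescence units per absorbance unit of live
#'   biomass).
#' @param fluor_gain Fluorescence units per true reporter unit.
#' @param seed Integer seed; identical configs render identical plates.
#' @param grid List: `t_end_min`, `dt_min` (default 10-min cadence).
#' @param treat_time Optional treatment time (minutes) applied to the whole
#'   plate.
#' @param name Scenario name.
#' @param metadata Free-form metadata recorded in the truth record.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(wells, growth = growth_params(),
                            noise = list(od_sd = 0.003, f_sd = 5,
                                         autofluor_per_od = 150),
                            fluor_gain = 1, seed = 1,
                            grid = list(t_end_min = 1380, dt_min = 10),
                            treat_time = NULL, name = "scenario",
                            metadata = list()) {
  stopifnot(length(wells) > 0, fluor_gain > 0,
            grid$t_end_min > 0, grid$dt_min > 0)
  stopifnot(all(c("od_sd", "f_sd", "autofluor_per_od") %in% names(noise)))
  structure(list(name = name, wells = wells, growth = growth, noise = noise,
                 fluor_gain = fluor_gain, seed = as.integer(seed),
                 grid = grid, treat_time = treat_time, metadata = metadata),
            class = "scenario_config")
}

#' One well of a plate scenario
#'
#' @param role `"blank"`, `"background"` or `"sample"`.
#' @param genotype,module,position,medium,replicate Layout metadata.
#' @param program [promoter_program()] (samples only).
#' @param effect [position_effect()] (samples only).
#' @param growth Optional per-well [growth_params()] override.
#' @param upstream_active Logical; is the configured upstream operon
#'   transcribing in this well's medium?
#' @return A `well_entry` list.
#' @export
well_entry <- function(role, genotype = "none", module = "none",
                       position = "none", medium = "M9", replicate = 1,
                       program = NULL, effect = NULL, growth = NULL,
                       upstream_active = FALSE) {
  if (role == "sample" && (is.null(program) || is.null(effect))) {
    abort("Sample wells need a promoter program and a position effect")
  }
  structure(list(role = role, genotype = genotype, module = module,
                 position = position, medium = medium, replicate = replicate,
                 program = program, effect = effect, growth = growth,
                 upstream_active = upstream_active),
            class = "well_entry")
}

#' Render a scenario into a measured plate
#'
#' Simulates every well of a scenario and applies the measurement model:
#'
#' * `od_raw = OD_true + blank offset + N(0, od_sd)`
#' * `fluor_raw = fluor_gain * F_true + autofluor_per_od * OD_true +
#'    N(0, f_sd)`
#'
#' Blank wells contain medium only (offset and noise); background wells
#' grow but carry no reporter (autofluorescence only). Raw readings are
#' truncated at zero, as a plate reader never reports negative counts.
#' Per-replicate lognormal fluctuation draws (mean 1) are taken once per
#' sample well with `replicate_cv > 0`. The full ground truth per well —
#' `od_true`, `f_true`, `a_true` and the replicate draw — is returned for
#' validation.
#'
#' @param cfg A [scenario_config()].
#' @return An `nf_plate` list: `wells` (measured readings), `layout`,
#'   `truth` (per-well, per-time ground truth) and `config`.
#' @examples
#' plate <- render_plate(plate_scenarios()$wt_fis_pair)
#' names(plate)
#' @export
render_plate <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$grid$t_end_min, by = cfg$grid$dt_min)
  ids <- plate_well_ids(length(cfg$wells))
  # One fluctuation draw per insertion locus and experiment: wells of the
  # same position and replicate (e.g. paired media/treatment conditions)
  # share the draw, so paired contrasts are not diluted by it.
  draws <- replicate_draws(cfg$wells)
  wells_out <- vector("list", length(cfg$wells))
  truth_out <- vector("list", length(cfg$wells))
  layout_out <- vector("list", length(cfg$wells))
  for (i in seq_along(cfg$wells)) {
    entry <- cfg$wells[[i]]
    id <- ids[i]
    growth <- if (is.null(entry$growth)) cfg$growth else entry$growth
    offset <- growth$od_blank_offset
    if (entry$role == "blank") {
      od_true <- rep(0, length(t))
      f_true <- rep(0, length(t))
      a_true <- rep(0, length(t))
      draw <- 1
    } else {
      curve <- simulate_growth(growth, t)
      if (entry$role == "background") {
        od_true <- curve$od_true
        f_true <- rep(0, length(t))
        a_true <- rep(0, length(t))
        draw <- 1
      } else {
        draw <- draws[[draw_key(entry)]]
        rep_curve <- simulate_reporter(
          curve, entry$program, entry$effect,
          events = list(treat_time = cfg$treat_time,
                        upstream_active = entry$upstream_active),
          replicate_draw = draw)
        od_true <- rep_curve$od_true
        f_true <- rep_curve$f_true
        a_true <- rep_curve$a_true
      }
    }
    od_raw <- pmax(od_true + offset + rnorm(length(t), 0, cfg$noise$od_sd), 0)
    fluor_raw <- pmax(cfg$fluor_gain * f_true +
                        cfg$noise$autofluor_per_od * od_true +
                        rnorm(length(t), 0, cfg$noise$f_sd), 0)
    wells_out[[i]] <- tibble(well_id = id, time_min = t, od_raw = od_raw,
                             fluor_raw = fluor_raw)
    truth_out[[i]] <- tibble(well_id = id, time_min = t, od_true = od_true,
                             f_true = f_true, a_true = a_true,
                             replicate_draw = draw)
    layout_out[[i]] <- tibble(well_id = id, role = entry$role,
                              genotype = entry$genotype, module = entry$module,
                              position = entry$position, medium = entry$medium,
                              replicate = entry$replicate)
  }
  structure(list(wells = bind_rows(wells_out),
                 layout = validate_layout(bind_rows(layout_out)),
                 truth = bind_rows(truth_out),
                 config = cfg),
            class = "nf_plate")
}

draw_key <- function(entry) {
  paste(entry$genotype, entry$module, entry$position, entry$replicate,
        sep = "|")
}

replicate_draws <- function(entries) {
  keys <- character(0)
  cvs <- numeric(0)
  for (e in entries) {
    if (e$role != "sample") next
    k <- draw_key(e)
    if (!k %in% keys) {
      keys <- c(keys, k)
      cvs <- c(cvs, e$effect$replicate_cv)
    }
  }
  draws <- lapply(cvs, function(cv) {
    if (cv > 0) {
      sdl <- sqrt(log(1 + cv^2))
      rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else 1
  })
  setNames(draws, keys)
}

plate_well_ids <- function(n) {
  if (n > 96) abort("A plate holds at most 96 wells")
  grid <- expand.grid(col = 1:12, row = LETTERS[1:8])
  paste0(grid$row, grid$col)[seq_len(n)]
}

#' @export
print.nf_plate <- function(x, ...) {
  cat("Simulated plate '", x$config$name, "': ",
      dplyr::n_distinct(x$wells$well_id), " wells x ",
      length(unique(x$wells$time_min)), " time points (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}
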