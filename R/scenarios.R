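# Canonical chromosomal coordinates of the insertion positions on the
# origin(0)-terminus(1) axis of a replichore.
rel_position_of <- function(position) {
  map <- c(OL = 0.08, OR = 0.08, ML = 0.5, MR = 0.5, TL = 0.92, TR = 0.92,
           MLup = 0.5, ara = 0.3, native = 0.85, none = 0)
  unname(map[position])
}

# Position-specific constant multipliers in the HU-deficient background:
# some positions express weaker (TR), some stronger (MR); magnitudes are
# free parameters of the simulator.
hup_position_multiplier <- function(position) {
  map <- c(OL = 1, OR = 1, ML = 1, MR = 1.6, TL = 1, TR = 0.5,
           MLup = 1, ara = 1, native = 1)
  m <- map[position]
  ifelse(is.na(m), 1, unname(m))
}

#' Packaged plate scenarios
#'
#' Builds the named set of simulation scenarios that mirror the study
#' conditions the pipeline is designed for:
#'
#' * `wt_dps`, `hup_dps`: oxidative-stress induction plates — the Pdps
#'   module at the six symmetric origin/middle/terminus positions, five
#'   replicates, hydrogen peroxide pulse at 170 min, 340-min run. The
#'   HU-deficient (`hupAB`) variant adds per-well lognormal
#'   between-replicate fluctuation (CV 0.4), reduced gene dosage and
#'   position-specific multipliers.
#' * `wt_hns`, `hup_hns`: growth-phase expression of the Phns module at
#'   the six positions over 23 h.
#' * `wt_fis_pair`, `hup_fis_pair`: the supercoiling-sensitive Pfis module
#'   at ML and MLup (directly upstream of the rrnG ribosomal operon). In
#'   the mutant the MLup module carries a constant 2.5-fold multiplier
#'   (midpoint of the observed 2-3-fold excess); in wild type both
#'   positions are equivalent.
#' * `wt_ara`, `hup_ara`: the Pdps module downstream of the araBAD operon,
#'   grown with and without arabinose. With arabinose the operon
#'   transcribes into the module's neighbourhood; in the mutant this halves
#'   the module's output (`upstream_coupling = 0.5`), in wild type it has
#'   no effect.
#' * `wt_dps_casamino`, `wt_dps_minimal`: media comparison for the Pdps
#'   module, with a 2.5-fold base-rate ratio between casamino-supplemented
#'   and plain minimal medium.
#' * `wt_dps_minimal_dyt`: as `wt_dps_minimal` but inoculated from a rich
#'   starter culture, adding an intermediate lag during which the Pdps
#'   module is transiently activated.
#'
#' @param seed Base seed; each scenario derives its own from it, so the
#'   whole set is reproducible from one integer.
#' @return Named list of [scenario_config()] objects.
#' @export
plate_scenarios <- function(seed = 7) {
  growth_cas <- growth_params(lag_min = 40, mu_max = 0.028, od_capacity = 0.55)
  growth_min <- growth_params(lag_min = 60, mu_max = 0.020, od_capacity = 0.45)
  growth_min_dyt <- growth_params(lag_min = 60, mu_max = 0.020,
                                  od_capacity = 0.45,
                                  intermediate_lag = list(start_od = 0.08,
                                                          duration_min = 200))
  slow <- function(g) {
    growth_params(lag_min = g$lag_min, mu_max = 0.8 * g$mu_max,
                  od_capacity = g$od_capacity,
                  intermediate_lag = g$intermediate_lag,
                  od_blank_offset = g$od_blank_offset)
  }
  six <- c("OL", "OR", "ML", "MR", "TL", "TR")

  refs <- function(genotype, medium) {
    c(lapply(1:3, function(i) well_entry("blank", medium = medium,
                                         replicate = i)),
      lapply(1:3, function(i) well_entry("background", genotype = genotype,
                                         medium = medium, replicate = i)))
  }

  dps_induction <- function(genotype, seed) {
    wt <- genotype == "wildtype"
    samples <- list()
    for (rep in 1:5) {
      for (pos in six) {
        eff <- position_effect(
          rel_position = rel_position_of(pos),
          dosage_coeff = if (wt) 1 else 0.3,
          genotype_multiplier = if (wt) 1 else hup_position_multiplier(pos),
          replicate_cv = if (wt) 0 else 0.4)
        samples <- c(samples, list(well_entry(
          "sample", genotype = genotype, module = "Pdps", position = pos,
          medium = "M9_casamino", replicate = rep,
          program = promoter_program("dps", base_rate = 30), effect = eff)))
      }
    }
    scenario_config(
      wells = c(samples, refs(genotype, "M9_casamino")),
      growth = if (wt) growth_cas else slow(growth_cas),
      seed = seed, grid = list(t_end_min = 340, dt_min = 10),
      treat_time = 170,
      name = paste0(if (wt) "wt" else "hup", "_dps"),
      metadata = list(treatment = "H2O2", dose_ug_ml = 50,
                      detector_gain = 70))
  }

  hns_plate <- function(genotype, seed) {
    wt <- genotype == "wildtype"
    samples <- list()
    for (rep in 1:3) {
      for (pos in six) {
        eff <- position_effect(
          rel_position = rel_position_of(pos),
          dosage_coeff = if (wt) 1 else 0.3,
          genotype_multiplier = if (wt) 1 else hup_position_multiplier(pos),
          replicate_cv = if (wt) 0 else 0.4)
        samples <- c(samples, list(well_entry(
          "sample", genotype = genotype, module = "Phns", position = pos,
          medium = "M9", replicate = rep,
          program = promoter_program("hns"), effect = eff)))
      }
    }
    scenario_config(wells = c(samples, refs(genotype, "M9")),
                    growth = if (wt) growth_min else slow(growth_min),
                    seed = seed,
                    name = paste0(if (wt) "wt" else "hup", "_hns"))
  }

  fis_pair <- function(genotype, seed) {
    wt <- genotype == "wildtype"
    samples <- list()
    for (rep in 1:5) {
      for (pos in c("ML", "MLup")) {
        mlup_mult <- if (!wt && pos == "MLup") 2.5 else 1
        eff <- position_effect(
          rel_position = rel_position_of(pos),
          dosage_coeff = if (wt) 1 else 0.3,
          genotype_multiplier = mlup_mult,
          replicate_cv = if (wt) 0 else 0.4)
        samples <- c(samples, list(well_entry(
          "sample", genotype = genotype, module = "Pfis", position = pos,
          medium = "M9", replicate = rep,
          program = promoter_program("fis"), effect = eff)))
      }
    }
    scenario_config(wells = c(samples, refs(genotype, "M9")),
                    growth = if (wt) growth_min else slow(growth_min),
                    seed = seed,
                    name = paste0(if (wt) "wt" else "hup", "_fis_pair"))
  }

  ara_plate <- function(genotype, seed) {
    wt <- genotype == "wildtype"
    samples <- list()
    for (rep in 1:5) {
      for (medium in c("M9", "M9_ara")) {
        eff <- position_effect(
          rel_position = rel_position_of("ara"),
          dosage_coeff = if (wt) 1 else 0.3,
          genotype_multiplier = 1,
          replicate_cv = if (wt) 0 else 0.4,
          upstream_coupling = if (wt) 1 else 0.5)
        samples <- c(samples, list(well_entry(
          "sample", genotype = genotype, module = "Pdps", position = "ara",
          medium = medium, replicate = rep,
          program = promoter_program("dps", base_rate = 12), effect = eff,
          upstream_active = medium == "M9_ara")))
      }
    }
    scenario_config(wells = c(samples, refs(genotype, "M9")),
                    growth = if (wt) growth_min else slow(growth_min),
                    seed = seed,
                    name = paste0(if (wt) "wt" else "hup", "_ara"))
  }

  media_plate <- function(medium, base_rate, growth, seed, name) {
    samples <- list()
    for (rep in 1:3) {
      for (pos in six) {
        samples <- c(samples, list(well_entry(
          "sample", genotype = "wildtype", module = "Pdps", position = pos,
          medium = medium, replicate = rep,
          program = promoter_program("dps", base_rate = base_rate),
          effect = position_effect(rel_position = rel_position_of(pos)))))
      }
    }
    scenario_config(wells = c(samples, refs("wildtype", medium)),
                    growth = growth, seed = seed, name = name)
  }

  list(
    wt_dps = dps_induction("wildtype", seed),
    hup_dps = dps_induction("hupAB", seed + 101),
    wt_hns = hns_plate("wildtype", seed + 202),
    hup_hns = hns_plate("hupAB", seed + 303),
    wt_fis_pair = fis_pair("wildtype", seed + 404),
    hup_fis_pair = fis_pair("hupAB", seed + 505),
    wt_ara = ara_plate("wildtype", seed + 606),
    hup_ara = ara_plate("hupAB", seed + 707),
    wt_dps_casamino = media_plate("M9_casamino", base_rate = 30,
                                  growth = growth_cas, seed = seed + 808,
                                  name = "wt_dps_casamino"),
    wt_dps_minimal = media_plate("M9", base_rate = 12,
                                 growth = growth_min, seed = seed + 909,
                                 name = "wt_dps_minimal"),
    wt_dps_minimal_dyt = media_plate("M9", base_rate = 12,
                                     growth = growth_min_dyt,
                                     seed = seed + 1010,
                                     name = "wt_dps_minimal_dyt"))
}
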