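# Small in-code fixtures shared across test files.

# A minimal two-well long-format plate as a tibble.
tiny_wells <- function() {
  tibble::tibble(
    well_id = rep(c("A1", "A2"), each = 3),
    time_min = rep(c(0, 10, 20), 2),
    od_raw = c(0.05, 0.10, 0.20, 0.06, 0.12, 0.25),
    fluor_raw = c(10, 40, 90, 12, 50, 110))
}

tiny_layout <- function() {
  tibble::tibble(
    well_id = c("A1", "A2", "A3", "A4"),
    role = c("sample", "sample", "blank", "background"),
    genotype = c("wildtype", "wildtype", "none", "wildtype"),
    module = c("Pdps", "Pdps", "none", "none"),
    position = c("OL", "TR", "none", "none"),
    medium = "M9",
    replicate = 1L)
}

# Noise-free single-well expression series from explicit vectors.
expression_series <- function(time_min, od_corr, f_corr, od_epsilon = 0.01) {
  nucleoflux::compute_fod(
    tibble::tibble(well_id = "W1", time_min = time_min,
                   od_corr = od_corr, f_corr = f_corr),
    od_epsilon = od_epsilon)
}

# A deterministic (zero-noise) scenario with a single constitutive sample
# well, handy for closed-form checks.
zero_noise_config <- function(t_end = 700, dt = 10, program = NULL,
                              effect = NULL, growth = NULL,
                              treat_time = NULL) {
  if (is.null(program)) program <- nucleoflux::promoter_program("hns")
  if (is.null(effect)) {
    effect <- nucleoflux::position_effect(rel_position = 0.5,
                                          dosage_coeff = 0)
  }
  if (is.null(growth)) {
    growth <- nucleoflux::growth_params(lag_min = 40, mu_max = 0.028,
                                        od_capacity = 0.55,
                                        od_blank_offset = 0)
  }
  nucleoflux::scenario_config(
    wells = list(
      nucleoflux::well_entry("sample", genotype = "wildtype",
                             module = "Phns", position = "ML", medium = "M9",
                             replicate = 1, program = program,
                             effect = effect),
      nucleoflux::well_entry("blank", medium = "M9"),
      nucleoflux::well_entry("background", genotype = "wildtype",
                             medium = "M9")),
    growth = growth,
    noise = list(od_sd = 0, f_sd = 0, autofluor_per_od = 0),
    seed = 11, grid = list(t_end_min = t_end, dt_min = dt),
    treat_time = treat_time, name = "zero_noise")
}
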