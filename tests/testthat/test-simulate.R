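test_that("growth model honours lag, capacity and zero-growth limits", {
  t <- seq(0, 2000, by = 10)
  g <- growth_params(lag_min = 60, mu_max = 0.025, od_capacity = 0.5)
  curve <- simulate_growth(g, t)
  od0 <- 0.5 / 200
  expect_equal(curve$od_true[t <= 60], rep(od0, sum(t <= 60)))
  expect_equal(curve$od_true[length(t)], 0.5, tolerance = 1e-6)
  expect_true(all(diff(curve$od_true) >= 0))
  # mu_max = 0 -> constant OD, zero growth rate
  flat <- simulate_growth(growth_params(mu_max = 0, od_capacity = 0.5), t)
  expect_equal(flat$od_true, rep(od0, length(t)))
  expect_equal(flat$mu, rep(0, length(t)))
})

test_that("an intermediate lag delays growth by its duration", {
  t <- seq(0, 3000, by = 1)
  base <- growth_params(lag_min = 60, mu_max = 0.02, od_capacity = 0.45)
  paused <- growth_params(lag_min = 60, mu_max = 0.02, od_capacity = 0.45,
                          intermediate_lag = list(start_od = 0.08,
                                                  duration_min = 200))
  t_half <- function(curve) t[min(which(curve$od_true >= 0.45 / 2))]
  d <- t_half(simulate_growth(paused, t)) - t_half(simulate_growth(base, t))
  expect_lt(abs(d - 200), 1 + 1e-9)
  # growth rate is zero during the pause and OD holds at start_od
  curve <- simulate_growth(paused, t)
  pause <- curve$in_intermediate_lag
  expect_equal(sum(pause), 200)
  expect_equal(curve$mu[pause], rep(0, 200))
  expect_equal(curve$od_true[pause], rep(0.08, 200), tolerance = 1e-9)
})

test_that("reporter accumulation follows closed forms", {
  t <- seq(0, 500, by = 10)
  g <- growth_params(mu_max = 0, od_capacity = 2)  # constant OD 0.01
  curve <- simulate_growth(g, t)
  prog <- promoter_program("custom", base_rate = 5, gains = list(const = 1))
  eff <- position_effect(0.5, dosage_coeff = 0)
  rep_curve <- simulate_reporter(curve, prog, eff)
  # constitutive a on constant OD c -> F linear with slope a*c
  expect_equal(rep_curve$f_true, 5 * 0.01 * t, tolerance = 1e-12)
  # zero base rate -> no reporter at all
  zero <- simulate_reporter(curve, promoter_program("custom", base_rate = 0),
                            eff)
  expect_equal(zero$f_true, rep(0, length(t)))
})

test_that("gene dosage favours origin-proximal modules during fast growth", {
  t <- seq(0, 1380, by = 10)
  g <- growth_params(lag_min = 40, mu_max = 0.028, od_capacity = 0.55)
  curve <- simulate_growth(g, t)
  prog <- promoter_program("fis")
  f_at <- function(x) {
    simulate_reporter(curve, prog,
                      position_effect(x, dosage_coeff = 1))$f_true
  }
  xs <- c(0, 0.25, 0.5, 0.75, 1)
  mid_expo <- which.min(abs(curve$od_true - 0.55 / 4))
  f_mid <- vapply(xs, function(x) f_at(x)[mid_expo], numeric(1))
  expect_true(all(diff(f_mid) < 0))
  # dosage effects vanish in stationary phase: a(t) converges across x
  a_end <- vapply(xs, function(x) {
    tail(simulate_reporter(curve, promoter_program("hns"),
                           position_effect(x, dosage_coeff = 1))$a_true, 1)
  }, numeric(1))
  expect_equal(a_end, rep(a_end[1], length(xs)), tolerance = 1e-6)
})

test_that("promoter archetypes express in their hallmark growth phases", {
  t <- seq(0, 1380, by = 10)
  g <- growth_params(lag_min = 60, mu_max = 0.02, od_capacity = 0.45)
  curve <- simulate_growth(g, t)
  eff <- position_effect(0.5, dosage_coeff = 0)
  a_of <- function(arch) simulate_reporter(curve, promoter_program(arch),
                                           eff)$a_true
  mid_expo <- which.min(abs(curve$od_true - 0.45 / 4))
  late <- length(t)
  a_fis <- a_of("fis"); a_dps <- a_of("dps"); a_hns <- a_of("hns")
  expect_gt(a_fis[mid_expo], 10 * max(a_fis[late], 1e-12))  # fis: expo pulse
  expect_gt(a_dps[late], 2.5 * a_dps[mid_expo])             # dps: stationary
  expect_lt(abs(a_hns[late] / a_hns[mid_expo] - 1.3 / 1.06), 0.2)  # hns: mild rise
  # dps pulse terminates after its configured duration
  pulse <- simulate_reporter(curve, promoter_program("dps"), eff,
                             events = list(treat_time = 300))
  base <- simulate_reporter(curve, promoter_program("dps"), eff)
  on <- t >= 300 & t < 340
  expect_true(all(pulse$a_true[on] > base$a_true[on]))
  expect_equal(pulse$a_true[!on], base$a_true[!on])
})

test_that("rendered plates are deterministic in the seed", {
  cfg <- plate_scenarios(seed = 17)$wt_fis_pair
  p1 <- render_plate(cfg)
  p2 <- render_plate(cfg)
  expect_identical(p1$wells, p2$wells)
  expect_identical(p1$truth, p2$truth)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  expect_false(identical(render_plate(cfg2)$wells$od_raw, p1$wells$od_raw))
})

test_that("zero noise, offset and autofluorescence make corrections identities", {
  cfg <- zero_noise_config()
  plate <- render_plate(cfg)
  expr <- correct_plate(plate$wells, plate$layout)
  truth <- dplyr::filter(plate$truth, well_id == "A1")
  expect_equal(expr$od_corr, truth$od_true, tolerance = 1e-12)
  expect_equal(expr$f_corr, truth$f_true, tolerance = 1e-12)
  # zero-noise constitutive well: d(F/OD) of a constant-rate reporter on
  # constant OD is constant (telescoping consistency)
  g <- growth_params(mu_max = 0, od_capacity = 2, od_blank_offset = 0.04)
  cfg2 <- zero_noise_config(
    growth = g,
    program = promoter_program("custom", base_rate = 5,
                               gains = list(const = 1)))
  cfg2$growth <- g
  plate2 <- render_plate(cfg2)
  expr2 <- correct_plate(plate2$wells, plate2$layout, od_epsilon = 0.005)
  act <- promoter_activity(expr2)
  d <- act$d_fod_raw[act$mask]
  expect_equal(d, rep(d[1], length(d)), tolerance = 1e-6)
})

test_that("measurement noise matches its configured level", {
  cfg <- plate_scenarios(seed = 21)$wt_hns
  plate <- render_plate(cfg)
  joined <- dplyr::left_join(plate$wells, plate$truth,
                             by = c("well_id", "time_min"))
  offset <- cfg$growth$od_blank_offset
  resid <- joined$od_raw - joined$od_true - offset
  expect_gt(length(resid), 1000)
  expect_lt(abs(sd(resid) - cfg$noise$od_sd) / cfg$noise$od_sd, 0.1)
})

test_that("the packaged scenario set encodes the study design", {
  sc <- plate_scenarios(seed = 7)
  expect_gte(length(sc), 8)
  cvs <- function(cfg) {
    vapply(cfg$wells, function(w) {
      if (w$role == "sample") w$effect$replicate_cv else NA_real_
    }, numeric(1))
  }
  for (name in names(sc)) {
    cv <- cvs(sc[[name]])
    if (grepl("^hup", name)) {
      expect_true(all(cv[!is.na(cv)] > 0), info = name)
    } else {
      expect_true(all(cv[!is.na(cv)] == 0), info = name)
    }
  }
  # hup fis pair: truth ratio of activities MLup/ML is 2.5 by construction
  cfg <- sc$hup_fis_pair
  mult <- vapply(cfg$wells, function(w) {
    if (w$role == "sample") w$effect$genotype_multiplier else NA_real_
  }, numeric(1))
  pos <- vapply(cfg$wells, function(w) w$position, character(1))
  expect_equal(unique(mult[pos == "MLup"]), 2.5)
  expect_equal(unique(mult[pos == "ML"]), 1)
  # media pair encodes the 2.5-fold base-rate ratio
  rate <- function(cfg) unique(vapply(cfg$wells, function(w) {
    if (w$role == "sample") w$program$base_rate else NA_real_
  }, numeric(1)))
  r_cas <- rate(sc$wt_dps_casamino)
  r_min <- rate(sc$wt_dps_minimal)
  expect_equal(r_cas[!is.na(r_cas)] / r_min[!is.na(r_min)], 2.5)
})
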