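test_that("discrete promoter activity is the first difference of F/OD", {
  expr <- expression_series(c(0, 10, 20, 30), rep(0.5, 4),
                            c(50, 80, 80, 60))
  act <- promoter_activity(expr)
  expect_equal(act$time_min, c(10, 20, 30))
  expect_equal(act$d_fod_raw, c(60, 0, -40))
  expect_equal(act$d_fod_clipped, c(60, 0, 0))
  # constant F/OD -> all differences zero
  flat <- expression_series(c(0, 10, 20), rep(0.5, 3), rep(400, 3))
  expect_equal(promoter_activity(flat)$d_fod_raw, c(0, 0))
})

test_that("activity differences telescope and are shift-invariant", {
  set.seed(7)
  for (i in 1:10) {
    n <- 40
    expr <- expression_series(seq(0, by = 10, length.out = n),
                              runif(n, 0.1, 0.6), runif(n, 0, 500))
    act <- promoter_activity(expr)
    expect_equal(sum(act$d_fod_raw), expr$fod[n] - expr$fod[1])
    expect_true(all(act$d_fod_clipped >= 0))
    expect_equal(act$d_fod_clipped, pmax(act$d_fod_raw, 0))
    shifted <- dplyr::mutate(expr, fod = fod + 123.4)
    expect_equal(promoter_activity(shifted)$d_fod_raw, act$d_fod_raw)
  }
})

test_that("masked points invalidate both adjacent differences", {
  expr <- expression_series(c(0, 10, 20, 30, 40),
                            c(0.5, 0.5, 0.001, 0.5, 0.5),
                            c(10, 20, 30, 40, 50))
  act <- promoter_activity(expr)
  expect_equal(act$mask, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(is.na(act$d_fod_raw[!act$mask])))
  all_masked <- expression_series(c(0, 10, 20), rep(0.001, 3), rep(10, 3))
  expect_warning(promoter_activity(all_masked), "No unmasked")
})

test_that("knot selection satisfies Schoenberg-Whitney admissibility", {
  # uniform 23 h grid at 10-min cadence
  t_uniform <- seq(0, 1380, by = 10)
  knots <- select_knots(t_uniform, 10)
  expect_true(sw_admissible(knots, t_uniform))
  expect_length(attr(knots, "interior"), 10)
  # interior knots track data quantiles (within one grid step)
  expect_lt(max(abs(attr(knots, "interior") -
                      unname(quantile(t_uniform, (1:10) / 11)))), 10)
  # n_interior = 0 -> boundary knots only (global cubic)
  k0 <- select_knots(t_uniform, 0)
  expect_equal(sort(unique(k0)), c(0, 1380))
  expect_length(k0, 8)
  # clustered sampling: knots denser where data are denser
  set.seed(123)
  t_clustered <- sort(c(runif(80, 0, 200), runif(20, 200, 1000)))
  kc <- select_knots(t_clustered, 8)
  expect_true(sw_admissible(kc, t_clustered))
  expect_gt(sum(attr(kc, "interior") < 200), sum(attr(kc, "interior") >= 200))
  # too few points is an explicit error
  expect_error(select_knots(seq(0, 50, 10), 4), "at least")
})

test_that("admissibility holds across random sampling patterns", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(12:200, 1)
    x <- sort(runif(n, 0, 1400))
    while (any(diff(x) <= 0)) x <- sort(runif(n, 0, 1400))
    n_int <- sample(0:min(12, n - 5), 1)
    knots <- select_knots(x, n_int)
    expect_true(sw_admissible(knots, x))
    # fit must be nonsingular
    fit <- fit_lsq_cubic_spline(x, sin(x / 100), knots)
    expect_true(all(is.finite(fit$coef)))
  }
})

test_that("least-squares spline reproduces polynomials up to cubics", {
  t <- seq(0, 1380, by = 10)
  lin <- fit_lsq_cubic_spline(t, 2 * t + 1, select_knots(t, 7))
  expect_lt(max(abs(residuals(lin))), 1e-9 * max(abs(2 * t + 1)))
  cub <- fit_lsq_cubic_spline(t, t^3, select_knots(t, 5))
  expect_lt(sqrt(sum(residuals(cub)^2)) / sqrt(sum((t^3)^2)), 1e-8)
  # derivative of the cubic is exact too
  d <- predict(cub, seq(100, 1200, by = 50), deriv = 1)
  expect_equal(d, 3 * seq(100, 1200, by = 50)^2, tolerance = 1e-8)
})

test_that("spline residuals match the injected noise level", {
  set.seed(5)
  t <- seq(0, 1380, by = 10)
  truth <- 5000 / (1 + exp(-(t - 600) / 120))
  sd_true <- 20
  y <- truth + rnorm(length(t), 0, sd_true)
  fit <- fit_lsq_cubic_spline(t, y, select_knots(t, 10))
  rms <- sqrt(mean(residuals(fit)^2))
  expect_gt(rms, 0.7 * sd_true)
  expect_lt(rms, 1.3 * sd_true)
})

test_that("more knots never worsen the fit on noiseless data", {
  cfg <- zero_noise_config(t_end = 1380, dt = 10)
  plate <- render_plate(cfg)
  expr <- correct_plate(plate$wells, plate$layout)
  w <- dplyr::filter(expr, mask)
  # nested refinement: adding knots to an existing vector cannot worsen the
  # least-squares residual
  all16 <- unname(quantile(w$time_min, (1:16) / 17))
  nested <- lapply(c(4, 2, 1), function(s) all16[seq(s, 16, by = s)])
  norms <- vapply(nested, function(interior) {
    knots <- sort(c(rep(range(w$time_min), each = 4), interior))
    sqrt(sum(residuals(fit_lsq_cubic_spline(w$time_min, w$f_corr, knots))^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6 * norms[1]))
  # the quantile selector also improves overall from coarse to fine
  norm_sel <- function(k) {
    sqrt(sum(residuals(fit_lsq_cubic_spline(w$time_min, w$f_corr,
                                            select_knots(w$time_min, k)))^2))
  }
  expect_lt(norm_sel(16), norm_sel(4))
})

test_that("synthesis rate has the closed form s/c for linear F, constant OD", {
  t <- seq(0, 500, by = 10)
  expr <- expression_series(t, rep(0.4, length(t)), 3 * t + 7)
  syn <- synthesis_rate(expr, n_interior = 4, margin_min = 30)
  expect_equal(syn$q, rep(3 / 0.4, nrow(syn)), tolerance = 1e-6)
  expect_true(all(syn$time_min >= 30 & syn$time_min <= 470))
})

test_that("synthesis rate recovers piecewise-constant activity plateaus", {
  t <- seq(0, 700, by = 1)
  growth <- growth_params(lag_min = 40, mu_max = 0.028, od_capacity = 0.55,
                          od_blank_offset = 0)
  curve <- simulate_growth(growth, t)
  prog <- promoter_program("custom", base_rate = 10,
                           gains = list(const = 1, pulse = 3),
                           pulse_duration = 40)
  eff <- position_effect(rel_position = 0.5, dosage_coeff = 0)
  rep_curve <- simulate_reporter(curve, prog, eff,
                                 events = list(treat_time = 300))
  expr <- expression_series(t, rep_curve$od_true, rep_curve$f_true)
  syn <- synthesis_rate(expr)
  plateau <- function(lo, hi) dplyr::filter(syn, time_min >= lo,
                                            time_min <= hi)$q
  expect_lt(max(abs(plateau(150, 240) - 10) / 10), 0.05)
  expect_lt(max(abs(plateau(420, 600) - 10) / 10), 0.05)
  expect_lt(abs(mean(plateau(310, 330)) - 40) / 40, 0.05)
})

test_that("spline derivative agrees with a finite-difference oracle", {
  t <- seq(0, 700, by = 1)
  growth <- growth_params(lag_min = 40, mu_max = 0.028, od_capacity = 0.55,
                          od_blank_offset = 0)
  curve <- simulate_growth(growth, t)
  rep_curve <- simulate_reporter(curve, promoter_program("hns"),
                                 position_effect(0.5, dosage_coeff = 0))
  expr <- expression_series(t, rep_curve$od_true, rep_curve$f_true)
  syn <- synthesis_rate(expr)
  m <- dplyr::filter(expr, mask)
  fd <- (dplyr::lead(m$f_corr) - dplyr::lag(m$f_corr)) /
    (dplyr::lead(m$time_min) - dplyr::lag(m$time_min))
  oracle <- tibble::tibble(time_min = m$time_min, q_fd = fd / m$od_corr)
  cmp <- dplyr::inner_join(syn, oracle, by = "time_min") %>%
    dplyr::filter(is.finite(q_fd))
  expect_lt(max(abs(cmp$q - cmp$q_fd) / abs(cmp$q_fd)), 0.01)
  # and with the true per-biomass activity
  truth <- tibble::tibble(time_min = t, a = rep_curve$a_true)
  cmp2 <- dplyr::inner_join(syn, truth, by = "time_min")
  expect_lt(max(abs(cmp2$q - cmp2$a) / cmp2$a), 0.05)
})

test_that("degenerate synthesis-rate inputs raise named errors", {
  short <- expression_series(seq(0, 50, 10), rep(0.5, 6), rep(10, 6))
  expect_error(synthesis_rate(short), "10 unmasked")
  t <- seq(0, 200, 10)
  neg <- compute_fod(tibble::tibble(well_id = "W1", time_min = t,
                                    od_corr = -0.5, f_corr = 10))
  expect_error(synthesis_rate(neg), "W1")
})
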