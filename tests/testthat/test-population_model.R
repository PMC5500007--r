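test_that("compartment derivatives match hand-evaluated expressions", {
  # treated condition: 18 nM + 2 Gy rates, conversion active
  rates <- effective_rates(fitted_coeffs(), 18, 2)
  st <- c(S = 0.5, R = 0.001, Dead = 0.2)
  nu <- 0.1768; K <- 4.2
  crowd <- 1 - 0.501 / 4.2
  expect_equal(compartment_derivatives(st, rates, nu, K),
               c(S = 1.7539 * 0.5 * crowd - 2.1450 * 0.5 - nu * 0.5,
                 R = 2.5369 * 0.001 * crowd - 2.4654 * 0.001 + nu * 0.5,
                 Dead = 2.1450 * 0.5 + 2.4654 * 0.001))
  # extinction is absorbing
  expect_equal(compartment_derivatives(c(S = 0, R = 0, Dead = 1), rates, nu, K),
               c(S = 0, R = 0, Dead = 0))
  # logistic equilibrium: no death, no conversion, S + R = K
  rates0 <- effective_rates(dose_response_coefficients(2, 2, 0, 0, 0, 0,
                                                       0, 0, 0, 0, 0, 0), 0, 0)
  expect_equal(compartment_derivatives(c(S = 3, R = 1.2, Dead = 0),
                                       rates0, 0, 4.2),
               c(S = 0, R = 0, Dead = 0))
})

test_that("radiation fractions apply the LQ kill and conserve live + dead", {
  rs <- fitted_rs()
  st <- list(S = 1, R = 0.4, Dead = 0.1)
  out <- apply_radiation_fraction(st, rs, 2)
  sf <- survival_fraction(rs, 2)
  expect_equal(out$S, sf)
  expect_equal(out$R, 0.4 * sf)
  expect_equal(out$S + out$R + out$Dead, st$S + st$R + st$Dead)
  expect_identical(apply_radiation_fraction(st, rs, 0), st)
  hi <- apply_radiation_fraction(st, rs, 200)
  expect_lt(hi$S + hi$R, 1e-50)
})

test_that("untreated growth matches the closed-form logistic solution", {
  coeffs <- dose_response_coefficients(2.5369, 2.5369, 0, 0, 0, 0,
                                       0, 0, 0, 0, 0, 0)
  params <- model_parameters(coeffs, fitted_rs(), nu_drug = 0, K = 4.2,
                             f_R0 = 0, N0 = 1)
  tr <- simulate_population(params, treatment_schedule(), t_out = 0:10)
  r <- 2.5369; K <- 4.2; N0 <- 1
  analytic <- K * N0 * exp(r * (0:10)) / (K + N0 * (exp(r * (0:10)) - 1))
  expect_equal(tr$S, analytic, tolerance = 1e-6)
  expect_equal(tr$R, rep(0, 11))
})

test_that("an acute fraction produces a single LQ jump with mass conserved", {
  params <- combo_params(nu = 0)
  tr <- simulate_population(params, acute_schedule(2, 0), t_out = c(0, 1, 5))
  sf <- survival_fraction(fitted_rs(), 2)
  expect_equal(tr$S[1], 0.999 * sf)
  expect_equal(tr$R[1], 0.001 * sf)
  expect_equal(tr$S[1] + tr$R[1] + tr$Dead[1], 1)  # live + dead across event
  # empty grid beyond t = 0 returns the initial (post-kill) state only
  tr0 <- simulate_population(params, acute_schedule(2, 0), t_out = 0)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$S, 0.999 * sf)
})

test_that("solver agrees with a brute-force Euler oracle on a 3-day horizon", {
  params <- combo_params()
  tr <- simulate_population(params, acute_schedule(2, 18, horizon = 3),
                            t_out = c(0, 3))
  # after the day-0 kill the rates are constant (cumulative dose 2 Gy, 18 nM)
  sf <- survival_fraction(fitted_rs(), 2)
  oracle <- euler_states(effective_rates(fitted_coeffs(), 18, 2),
                         nu = 0.1768, K = 4.2,
                         S0 = 0.999 * sf, R0 = 0.001 * sf, t_end = 3)
  expect_equal(tr$S[2], oracle[["S"]], tolerance = 1e-4)
  expect_equal(tr$R[2], oracle[["R"]], tolerance = 1e-4)
  expect_equal(tr$Dead[2], oracle[["Dead"]] + (1 - sf), tolerance = 1e-4)
})

test_that("populations stay non-negative and bounded under random regimens", {
  set.seed(7)
  for (i in 1:8) {
    v <- runif(12, 0, 0.05)
    v[c(1, 2)] <- runif(2, 0.5, 3); v[c(7, 8)] <- runif(2, 0, 2)
    coeffs <- do.call(dose_response_coefficients, as.list(v))
    K <- runif(1, 1, 8); N0 <- runif(1, 0.2, 2)
    params <- model_parameters(coeffs, radiosensitivity(runif(1, 0, 1),
                                                        runif(1, 0, 0.1)),
                               nu_drug = runif(1, 0, 0.3), K = K,
                               f_R0 = runif(1, 0, 0.05), N0 = N0)
    sched <- treatment_schedule(
      radiation_fractions = data.frame(time = c(0, 2), dose = runif(2, 0, 3)),
      drug_segments = data.frame(start = 0, end = 10, conc = runif(1, 0, 25)))
    tr <- suppressWarnings(
      simulate_population(params, sched, t_out = seq(0, 10, 0.5)))
    expect_true(all(tr$S >= -1e-12))
    expect_true(all(tr$R >= -1e-12))
    expect_true(all(tr$S + tr$R <= max(N0, K) * (1 + 1e-9)))
    expect_true(all(tr$viability_pct >= 0 & tr$viability_pct <= 100))
  }
})

test_that("viability read-outs behave at their fixed points", {
  params <- combo_params(nu = 0)
  # untreated against itself reads a constant 100 percent
  tr <- simulate_population(params, treatment_schedule(), t_out = 0:10)
  expect_equal(tr$viability_pct, rep(100, 11))
  # immediately after an acute 2 Gy the relative read-out equals 100 * SF
  tr2 <- simulate_population(params, acute_schedule(2, 0), t_out = c(0, 1))
  expect_equal(tr2$viability_pct[1], 100 * survival_fraction(fitted_rs(), 2))
  # an (effectively) fully killed culture reads 0 in live-fraction mode
  tr3 <- simulate_population(params, acute_schedule(200, 0), t_out = c(1, 3),
                             observable = "live_fraction")
  expect_lt(max(tr3$viability_pct), 1e-6)
  # viability() recomputes the simulation-time observable
  expect_equal(viability(tr2, "relative_to_control"), tr2$viability_pct)
})

test_that("dose-response assays are monotone and deterministic, with interpolated LD50", {
  params <- combo_params(nu = 0)
  curve <- dose_response_assay(params, c(0, 1, 2, 4, 6, 8, 10), "radiation")
  expect_equal(curve$viability_pct[1], 100)
  expect_true(all(diff(curve$viability_pct) < 0))
  # replicated grid point gives identical values
  rep2 <- dose_response_assay(params, c(4, 4), "radiation")
  expect_identical(rep2$viability_pct[1], rep2$viability_pct[2])
  # drug grid at zero dose reads 100
  drug0 <- dose_response_assay(combo_params(nu = 0.0409), 0, "nilotinib")
  expect_equal(drug0$viability_pct, 100)

  expect_equal(find_dose50(data.frame(dose = c(0, 2, 4),
                                      viability_pct = c(100, 50, 10))),
               list(reached = TRUE, dose = 2))
  expect_equal(find_dose50(data.frame(dose = c(0, 4),
                                      viability_pct = c(100, 0))),
               list(reached = TRUE, dose = 2))
  out <- find_dose50(data.frame(dose = c(0, 2), viability_pct = c(100, 80)))
  expect_false(out$reached)
  expect_true(is.na(out$dose))
})

test_that("schedule validation rejects malformed inputs", {
  expect_error(treatment_schedule(data.frame(time = c(2, 1),
                                             dose = c(1, 1))),
               "non-decreasing")
  expect_error(treatment_schedule(drug_segments = data.frame(
    start = c(0, 2), end = c(3, 5), conc = c(10, 10))), "overlap")
  expect_error(treatment_schedule(drug_segments = data.frame(
    start = 0, end = 0, conc = 10)), "end > start")
  expect_error(model_parameters(fitted_coeffs(), fitted_rs(),
                                nu_drug = 0.1, K = -1), "K must be > 0")
  expect_error(model_parameters(fitted_coeffs(), fitted_rs(),
                                nu_drug = 0.1, f_R0 = 2), "f_R0")
})
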