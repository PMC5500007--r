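test_that("noiseless generation equals the model read-out exactly", {
  params <- combo_params(nu = 0.0409)
  sched <- acute_schedule(0, 18)
  days <- c(1, 3, 6, 8, 10)
  obs <- generate_viability_series(params, sched, days,
                                   noise_spec(sd = 0, n_replicates = 2))
  tr <- simulate_population(params, sched, t_out = days,
                            observable = "live_fraction")
  expect_equal(obs$viability_pct, rep(tr$viability_pct, each = 2))
  expect_equal(obs$radiation_Gy, rep(0, 10))
  expect_equal(obs$nilotinib_nM, rep(18, 10))
})

test_that("the full suite has the designed layout and is seed-reproducible", {
  a <- suppressWarnings(generate_experiment_suite(seed = 3))
  b <- suppressWarnings(generate_experiment_suite(seed = 3))
  c <- suppressWarnings(generate_experiment_suite(seed = 4))
  expect_identical(a, b)
  expect_false(identical(a, c))

  # 6 arms x 5 days x 3 replicates + (2 x 7 + 4) assay points x 3 replicates
  expect_equal(sum(a$series == "timeseries"), 90)
  expect_equal(sum(a$series == "radiation_dr"), 42)
  expect_equal(sum(a$series == "drug_dr"), 12)
  expect_setequal(unique(a$radiation_Gy[a$series == "timeseries"]), c(0, 2, 4))
  expect_setequal(unique(a$day[a$series == "timeseries"]), c(1, 3, 6, 8, 10))
  # every generated row satisfies the observation contract
  expect_silent(validate_observations(a))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(suppressWarnings(generate_experiment_suite(seed = 5))); after <- runif(1)
  expect_identical(before, after)
})

test_that("replicate noise is unbiased at interior viability values", {
  params <- combo_params(nu = 0.0409)
  sched <- acute_schedule(0, 18)
  obs <- generate_viability_series(params, sched, days = 6,
                                   noise_spec(sd = 3, n_replicates = 1000,
                                              seed = 10))
  model_v <- simulate_population(params, sched, t_out = 6,
                                 observable = "live_fraction")$viability_pct
  expect_gt(model_v, 10); expect_lt(model_v, 90)  # interior: truncation inert
  expect_lt(abs(mean(obs$viability_pct) - model_v), 3 * 3 / sqrt(1000))
  expect_true(all(obs$viability_pct >= 0 & obs$viability_pct <= 100))
})

test_that("the noiseless suite shows the observed treatment-response patterns", {
  suite <- suppressWarnings(
    generate_experiment_suite(seed = 1, noise = noise_spec(sd = 0)))
  arm <- function(D, conc) {
    rows <- suite$series == "timeseries" & suite$radiation_Gy == D &
      suite$nilotinib_nM == conc & suite$replicate == 1
    suite$viability_pct[rows][order(suite$day[rows])]
  }
  nilo <- arm(0, 18); ctrl <- arm(0, 0)
  # drug-only: depressed below control, then partial recovery (resistance)
  expect_lt(min(nilo), min(ctrl))
  expect_gt(nilo[5], min(nilo))
  # combination arms stay below the drug-only arm at every day
  expect_true(all(arm(2, 18) < nilo))
  expect_true(all(arm(4, 18) < arm(2, 18)))
  # assay curves decrease with dose
  # the live-fraction assay read-out is not monotone at low dose (survivors
  # regrow with fewer dead per live cell than the near-equilibrium control),
  # but it collapses monotonically once the kill dominates
  rad0 <- suite[suite$series == "radiation_dr" & suite$nilotinib_nM == 0 &
                  suite$replicate == 1, ]
  v <- rad0$viability_pct[order(rad0$radiation_Gy)]
  expect_true(all(diff(v[rad0$radiation_Gy[order(rad0$radiation_Gy)] >= 2]) < 0))
  expect_lt(v[length(v)], 0.01)
})

test_that("noise specifications are validated", {
  expect_error(noise_spec(sd = -1), "sd")
  expect_error(noise_spec(n_replicates = 0), "n_replicates")
})
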