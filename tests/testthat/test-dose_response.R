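test_that("effective rates reproduce the fitted rate table at the four treatment conditions", {
  coeffs <- fitted_coeffs()
  expected <- list(
    # condition = c(nilotinib nM, Gy), rates = c(rS, rR, dS, dR)
    control = list(cond = c(0, 0),  rates = c(2.5369, 2.5369, 2.0550, 2.0550)),
    nilo    = list(cond = c(18, 0), rates = c(2.2579, 2.5369, 2.0550, 2.0550)),
    nilo2   = list(cond = c(18, 2), rates = c(1.7539, 2.5369, 2.1450, 2.4654)),
    nilo4   = list(cond = c(18, 4), rates = c(1.2499, 2.5369, 2.2350, 2.8758)))
  for (row in expected) {
    er <- effective_rates(coeffs, row$cond[1], row$cond[2])
    expect_equal(round(c(er$rS, er$rR, er$dS, er$dR), 4), row$rates)
  }
  # single-rate accessors agree with the bundle
  expect_equal(proliferation_rate(coeffs, "sensitive", 18, 2), 1.7539)
  expect_equal(death_rate(coeffs, "resistant", 18, 4), 2.8758)
})

test_that("zero-dose identities and input validation", {
  coeffs <- fitted_coeffs()
  expect_equal(proliferation_rate(coeffs, "sensitive", 0, 0), 2.5369)
  expect_equal(proliferation_rate(coeffs, "resistant", 0, 5), 2.5369)
  expect_equal(death_rate(coeffs, "sensitive", 0, 7), 2.0550)
  expect_error(proliferation_rate(coeffs, "sensitive", -1, 0), "must be >= 0")
  expect_error(death_rate(coeffs, "resistant", 0, -2), "must be >= 0")
  expect_error(dose_response_coefficients(1, 1, -0.1, 0, 0, 0,
                                          1, 1, 0, 0, 0, 0),
               "non-negative")
  expect_error(dose_response_coefficients(1, 2, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0,
                                          control_constrained = TRUE),
               "rS0 == rR0")
  zero <- dose_response_coefficients(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  er <- effective_rates(zero, 12, 3)
  expect_equal(unlist(unclass(er)), c(rS = 0, rR = 0, dS = 0, dR = 0))
})

test_that("proliferation is non-increasing and death non-decreasing in both doses", {
  set.seed(11)
  for (i in 1:10) {
    v <- runif(12, 0, 0.2)
    v[c(1, 2, 7, 8)] <- runif(4, 1, 4)  # baselines
    coeffs <- do.call(dose_response_coefficients, as.list(v))
    cs <- sort(runif(4, 0, 20)); Ds <- sort(runif(4, 0, 4))
    suppressWarnings({
      pr_c <- sapply(cs, function(cc) proliferation_rate(coeffs, "sensitive", cc, 1))
      pr_D <- sapply(Ds, function(DD) proliferation_rate(coeffs, "sensitive", 10, DD))
      dr_c <- sapply(cs, function(cc) death_rate(coeffs, "sensitive", cc, 1))
      dr_D <- sapply(Ds, function(DD) death_rate(coeffs, "resistant", 10, DD))
    })
    expect_true(all(diff(pr_c) <= 1e-12))
    expect_true(all(diff(pr_D) <= 1e-12))
    expect_true(all(diff(dr_c) >= -1e-12))
    expect_true(all(diff(dr_D) >= -1e-12))
  }
})

test_that("negative linear rates are floored at zero with a classed warning", {
  coeffs <- fitted_coeffs()
  # rS = 2.5369 - (0.0155 + 0.014 * 10) * 18 < 0
  expect_warning(r <- proliferation_rate(coeffs, "sensitive", 18, 10),
                 class = "nilrad_rate_floor")
  expect_identical(r, 0)
})

test_that("LQ survival fraction matches direct evaluation and fractionation sparing holds", {
  rs <- fitted_rs()
  expect_identical(survival_fraction(rs, 0), 1)
  expect_equal(survival_fraction(rs, 2), exp(-0.6647 * 2 - 0.079 * 4),
               tolerance = 1e-15)
  expect_equal(survival_fraction(rs, 4), exp(-0.6647 * 4 - 0.079 * 16),
               tolerance = 1e-15)
  # strictly decreasing in dose
  sf <- survival_fraction(rs, seq(0, 6, 0.5))
  expect_true(all(diff(sf) < 0))
  # beta > 0: split doses spare; beta = 0: exactly log-linear
  expect_gt(survival_fraction(rs, 1.2) * survival_fraction(rs, 0.8),
            survival_fraction(rs, 2))
  rs0 <- radiosensitivity(0.5, 0)
  expect_equal(survival_fraction(rs0, 1.2) * survival_fraction(rs0, 0.8),
               survival_fraction(rs0, 2), tolerance = 1e-12)
  expect_error(survival_fraction(rs, -1), "must be >= 0")
  expect_error(radiosensitivity(-0.1, 0), "non-negative")
})
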