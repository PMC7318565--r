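test_that("vulnerability curve hits its defining points and stays in [0,1]", {
  tr <- hydraulic_traits(-2, 3, rp_min = 1000)
  expect_identical(vulnerability_k(0, tr), 1)
  expect_equal(vulnerability_k(-2, tr), 0.5)
  expect_equal(vulnerability_k(-4, tr), 1 / 9)
  expect_error(vulnerability_k(0.1, tr), "<= 0")
  expect_error(vulnerability_k(NaN, tr), "finite")

  for (tr in random_traits(20)) {
    psi <- seq(-10, 0, length.out = 60)
    k <- vulnerability_k(psi, tr)
    expect_true(all(k >= 0 & k <= 1))
    expect_true(all(diff(k) >= 0)) # K rises toward wetter potentials
    expect_equal(vulnerability_k(tr$psi50, tr), 0.5, tolerance = 1e-12)
  }
})

test_that("analytic vulnerability slope matches central differences", {
  tr <- hydraulic_traits(-2, 3, rp_min = 1000)
  expect_equal(vulnerability_slope(-2, tr), 3 / 8) # a / (4 |psi50|)
  expect_equal(vulnerability_slope(-1e-8, tr), 0, tolerance = 1e-12)

  for (psi50 in c(-6, -3, -0.5)) {
    for (a in c(1, 3, 10)) {
      tr <- hydraulic_traits(psi50, a, rp_min = 1000)
      for (psi in c(-8, -4, -1.3, -0.3, -0.1)) {
        ana <- vulnerability_slope(psi, tr)
        num <- vulnerability_slope(psi, tr, method = "central_difference")
        # truncation envelope of the fixed 1e-4 MPa step: ~ a^2 h^2 / psi^2
        # relative, floored at 1e-6
        bound <- max(1e-6, a^2 * 1e-8 / (3 * psi^2))
        expect_lt(abs(num - ana), bound * ana + 2e-10)
        expect_gte(ana, 0)
      }
      # the reference interior point meets the strict tolerance
      ana <- vulnerability_slope(-1.3, hydraulic_traits(-2, 3, rp_min = 1))
      num <- vulnerability_slope(-1.3, hydraulic_traits(-2, 3, rp_min = 1),
                                 method = "central_difference")
      expect_equal(num, ana, tolerance = 1e-6)
      # at the -0.01 MPa edge the fixed 1e-4 MPa step is 1% of psi and the
      # difference is truncation-limited (~ (a-1)(a-2) h^2 / (6 psi^2))
      ana <- vulnerability_slope(-0.01, tr)
      num <- vulnerability_slope(-0.01, tr, method = "central_difference")
      expect_lt(abs(num - ana), 1e-4 * ana + 1e-12)
    }
  }
})

test_that("shape parameter inverts the P50/P88 pair exactly", {
  a <- shape_from_p50_p88(-2, -4)
  expect_equal(a, log(0.88 / 0.12) / log(2))
  tr <- hydraulic_traits(-2, a, rp_min = 1000)
  expect_equal(vulnerability_k(-4, tr), 0.12, tolerance = 1e-12)

  # round trip a -> psi88 -> a
  for (a0 in c(1.3, 2.8745, 6)) {
    psi88 <- -2 * (0.88 / 0.12)^(1 / a0)
    expect_equal(shape_from_p50_p88(-2, psi88), a0, tolerance = 1e-12)
  }
  expect_equal(shape_from_p50_p88(-2, -2 * (0.88 / 0.12)), 1)
  expect_error(shape_from_p50_p88(-2, -1), "more negative")
})

test_that("plant resistance follows the conductance loss and conserves rp * K", {
  tr <- hydraulic_traits(-2, 3, rp_min = 500)
  expect_equal(as.numeric(plant_resistance(0, tr)), 500)
  expect_equal(as.numeric(plant_resistance(-2, tr)), 1000)
  expect_equal(as.numeric(plant_resistance(-4, tr)), 4500)

  for (tr in random_traits(10, seed = 7)) {
    psi <- seq(-6, -0.05, length.out = 30)
    rp <- as.numeric(plant_resistance(psi, tr))
    expect_true(all(diff(rp) <= 1e-12)) # non-increasing toward wetter
    # conservation rp * K = rp_min wherever the conductance floor is idle
    expect_equal(rp * pmax(vulnerability_k(psi, tr), 1e-6),
                 rep(tr$rp_min, 30), tolerance = 1e-10)
  }
  # extreme drought engages the conductance floor
  rp_deep <- plant_resistance(-200, hydraulic_traits(-1, 8, rp_min = 100))
  expect_true(attr(rp_deep, "clamped"))
  expect_true(is.finite(rp_deep))
})

test_that("canopy drawdown is linear in gs and midpoint is the mean", {
  expect_equal(canopy_water_potential(0, -0.5, 0.004935, 1000), -0.5)
  expect_equal(canopy_water_potential(0.1, -0.5, 0.004935, 1000),
               -0.5 - 0.7896, tolerance = 1e-10)
  dd1 <- -0.5 - canopy_water_potential(0.05, -0.5, 0.01, 800)
  dd2 <- -0.5 - canopy_water_potential(0.10, -0.5, 0.01, 800)
  expect_equal(dd2, 2 * dd1)

  expect_equal(midpoint_potential(-0.5, -0.5), -0.5)
  expect_equal(midpoint_potential(-0.5, -1.5), -1)
  expect_equal(midpoint_potential(0, -2), -1)
  expect_error(midpoint_potential(-2, -1), "psi_c")
})

test_that("hydraulic cost term has the stated value and monotonicities", {
  tr <- hydraulic_traits(-2, 3, rp_min = 500)
  xi <- hydraulic_cost_xi(-2, -2, 0.004935, tr)
  expect_equal(xi, 2 * 0.5 / (0.375 * 1000 * 1.6 * 0.004935), tolerance = 1e-12)
  expect_equal(xi, 0.33772, tolerance = 1e-4)

  # xi ~ 1/D
  expect_equal(hydraulic_cost_xi(-2, -2, 0.01, tr) /
                 hydraulic_cost_xi(-2, -2, 0.02, tr), 2, tolerance = 1e-12)
  expect_error(hydraulic_cost_xi(-2, -2, 0, tr), "undefined")

  # drought (more negative psi_pd, evaluated there) raises the cost
  for (tr in random_traits(10, seed = 3)) {
    psi <- seq(max(-3 * abs(tr$psi50), -8), -0.2, length.out = 15)
    xi <- hydraulic_cost_xi(psi, psi, 0.01, tr)
    expect_true(all(xi > 0))
    expect_lt(xi[1], xi[length(xi)])
  }
  expect_lt(hydraulic_cost_xi(-3, -3, 0.01, hydraulic_traits(-2, 3, rp_min = 500)),
            hydraulic_cost_xi(-1, -1, 0.01, hydraulic_traits(-2, 3, rp_min = 500)))
})

test_that("trait constructor validates and converts units", {
  expect_equal(hydraulic_traits(-2, 3, rp_min = 1, rp_units = "per_mmol")$rp_min,
               1000)
  expect_equal(hydraulic_traits(-2, psi88 = -4, rp_min = 100)$shape_a,
               shape_from_p50_p88(-2, -4))
  expect_error(hydraulic_traits(1, 3, rp_min = 1), "negative")
  expect_error(hydraulic_traits(-2, -3, rp_min = 1), "positive")
  expect_error(hydraulic_traits(-2, 3, rp_min = 0), "positive")
})
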