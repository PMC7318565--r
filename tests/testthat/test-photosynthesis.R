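test_that("temperature adjustment follows Q10 with sigmoidal inhibition", {
  # thresholds far away so the inhibition factor is ~1 at the test points
  p <- photo_params(t_upp = 200, t_low = -200, q10_vcmax = 2)
  expect_equal(temperature_adjust(p, 25)$vcmax, p$vcmax25, tolerance = 1e-12)
  expect_equal(temperature_adjust(p, 35)$vcmax, 2 * p$vcmax25, tolerance = 1e-12)
  kin <- temperature_adjust(p, 25)
  expect_equal(kin$gamma, 21000 / 5200, tolerance = 1e-12)
  expect_equal(kin$r_d, p$f_dr * kin$vcmax)
  # high-temperature inhibition suppresses vcmax
  p2 <- photo_params(t_upp = 30)
  expect_lt(temperature_adjust(p2, 40)$vcmax,
            temperature_adjust(p2, 25)$vcmax)
  # C4 has no CO2 compensation point
  expect_equal(temperature_adjust(photo_params("C4"), 25)$gamma, 0)
})

test_that("limiting rates match hand evaluation and vanish where they must", {
  p <- photo_params(t_upp = 200, t_low = -200)
  kin <- list(vcmax = 1e-4, kc = 30, ko = 30000, tau = 2600, gamma = 4,
              r_d = 0)
  w <- limiting_rates(40, ipar = 1e-3, patm = 101325, p, kin)
  expect_equal(w$w_carbox, 1e-4 * 36 / (40 + 30 * 1.7), tolerance = 1e-12)
  expect_equal(w$w_export, 0.5e-4)

  w0 <- limiting_rates(4, ipar = 1e-3, patm = 101325, p, kin) # ci = gamma
  expect_equal(w0$w_carbox, 0)
  expect_equal(w0$w_light, 0)
  wdark <- limiting_rates(40, ipar = 0, patm = 101325, p, kin)
  expect_equal(wdark$w_light, 0)

  p4 <- photo_params("C4")
  kin4 <- temperature_adjust(p4, 25)
  w4 <- limiting_rates(20, ipar = 1e-3, patm = 101325, p4, kin4)
  expect_equal(w4$w_carbox, kin4$vcmax)
  expect_equal(w4$w_export, 2e4 * kin4$vcmax * 20 / 101325)
})

test_that("colimitation reduces to the minimum at beta = 1 and bounds the root", {
  set.seed(1)
  for (i in 1:1000) {
    w <- runif(3, 0, 3e-4)
    expect_equal(colimit(w[1], w[2], w[3], 1, 1), min(w), tolerance = 1e-12)
  }
  expect_equal(colimit(0, 2, 3, 0.83, 0.93), 0)
  # smaller-root value against a direct polynomial-root oracle
  quad_oracle <- function(p, q, b) min(Re(polyroot(c(p * q, -(p + q), b))))
  wp <- quad_oracle(3, 4, 0.83)
  w <- quad_oracle(wp, 5, 0.93)
  got <- colimit(3, 4, 5, 0.83, 0.93)
  expect_equal(got, w, tolerance = 1e-10)
  expect_lte(got, 3)
})

test_that("assimilation from prescribed ci behaves across the ci range", {
  p <- photo_params()
  env <- ref_env(ipar = 1500e-6)
  kin <- temperature_adjust(p, env$t_air)
  r <- solve_a_from_ci(kin$gamma, env, p)
  expect_equal(r$a_net, -kin$r_d, tolerance = 1e-15) # gross is zero at gamma
  ci <- seq(kin$gamma, env$ca, length.out = 40)
  a <- solve_a_from_ci(ci, env, p)$a_net
  expect_true(all(diff(a) > 0)) # increasing below saturation at high light

  # independent re-implementation of the full chain at one point
  ci0 <- 25
  kc_eff <- kin$kc * (1 + p$oa / kin$ko)
  wc <- kin$vcmax * (ci0 - kin$gamma) / (ci0 + kc_eff)
  wl <- p$alpha_q * (1 - p$omega) * env$ipar * (ci0 - kin$gamma) /
    (ci0 + 2 * kin$gamma)
  we <- 0.5 * kin$vcmax
  sm <- function(pp, qq, b) (pp + qq - sqrt((pp + qq)^2 - 4 * b * pp * qq)) / (2 * b)
  expect_equal(solve_a_from_ci(ci0, env, p)$a_net,
               sm(sm(wc, wl, p$beta1), we, p$beta2) - kin$r_d,
               tolerance = 1e-12)
})

test_that("coupled solve satisfies supply = demand and its limits", {
  p <- photo_params()
  env <- ref_env()
  # large gs pins ci at ca
  big <- solve_a_from_gs(1e3, env, p)
  expect_equal(big$ci, env$ca, tolerance = 1e-3)
  # gs = 0 sits at the net compensation point
  z <- solve_a_from_gs(0, env, p)
  expect_equal(z$a_net, 0)
  expect_equal(solve_a_from_ci(z$ci, env, p)$a_net, 0, tolerance = 1e-12)
  # darkness at gs = 0 has no compensation point
  expect_match(paste(solve_a_from_gs(0, ref_env(ipar = 0), p)$flags,
                     collapse = ";"), "no_compensation")

  # mid-range gs against a brute-force bisection oracle on the residual
  gs <- 0.1
  f <- function(ci) solve_a_from_ci(ci, env, p)$a_net -
    gs * (env$ca - ci) / env$patm
  lo <- 0; hi <- env$ca
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) > 0) hi <- mid else lo <- mid }
  got <- solve_a_from_gs(gs, env, p)
  expect_equal(got$ci, (lo + hi) / 2, tolerance = 1e-8)
  expect_lt(abs(got$a_net - gs * (env$ca - got$ci) / env$patm),
            1e-10 * max(1, abs(got$a_net)))

  # consistency: demand at the returned ci equals the returned a_net
  set.seed(8)
  for (i in 1:25) {
    env_i <- ref_env(ipar = runif(1, 0, 2000e-6), t_air = runif(1, 5, 40),
                     ca = runif(1, 15, 80), d = runif(1, 0.001, 0.03),
                     psi_pd = -runif(1, 0.05, 5))
    gs_i <- runif(1, 0, 1)
    s <- solve_a_from_gs(gs_i, env_i, p)
    expect_equal(solve_a_from_ci(s$ci, env_i, p)$a_net, s$a_net,
                 tolerance = 1e-12)
  }

  # a_net is monotone non-decreasing in gs
  for (ipar in c(200e-6, 1500e-6)) {
    env_m <- ref_env(ipar = ipar)
    a <- solve_a_from_gs(seq(0, 1.5, length.out = 30), env_m, p)$a_net
    expect_true(all(diff(a) >= -1e-12))
  }
})

test_that("dA/dci is non-negative, accurate and convergent", {
  env <- ref_env(ipar = 2000e-6)
  # isolate the Rubisco branch: hard minimum colimitation, saturating light
  p <- photo_params(beta1 = 1, beta2 = 1)
  kin <- temperature_adjust(p, env$t_air)
  kc_eff <- kin$kc * (1 + p$oa / kin$ko)
  ci0 <- 20 # Rubisco-limited at high light, below the export crossover
  analytic <- kin$vcmax * (kin$gamma + kc_eff) / (ci0 + kc_eff)^2 * env$patm
  expect_equal(dA_dci(ci0, env, p), analytic, tolerance = 1e-3)

  # darkness: flat response above compensation
  expect_equal(dA_dci(20, ref_env(ipar = 0), p), 0, tolerance = 1e-15)

  # Richardson: halving the step barely moves the estimate
  d1 <- dA_dci(25, env, p, rel_step = 1e-3)
  d2 <- dA_dci(25, env, p, rel_step = 5e-4)
  expect_equal(d1, d2, tolerance = 1e-6)

  # non-negative over (gamma, ca] for assorted parameterizations
  for (p_i in list(photo_params(), photo_params(vcmax25 = 3e-5),
                   photo_params("C4"))) {
    kin_i <- temperature_adjust(p_i, env$t_air)
    ci <- seq(kin_i$gamma + 0.5, env$ca, length.out = 20)
    expect_true(all(dA_dci(ci, env, p_i) >= 0))
  }
})
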