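test_that("error statistics match their definitions", {
  obs <- c(1, 2, 3)
  expect_equal(rmse(obs, obs), 0)
  expect_equal(rmse(obs, obs + 0.7), 0.7)
  expect_equal(rmse(obs, c(2, 2, 2)), sqrt(2 / 3))

  expect_equal(nse(obs, obs), 1)
  expect_equal(nse(obs, rep(mean(obs), 3)), 0)
  expect_lt(nse(obs, c(3, 1, 2)), 0) # worse than the mean predictor
  expect_error(nse(rep(1, 5), rep(1, 5)), "variance")

  # NSE = 1 - rmse^2 n / sum((obs - mean)^2) identity
  set.seed(2)
  o <- rnorm(50); m <- o + rnorm(50, 0, 0.3)
  expect_equal(nse(o, m), 1 - rmse(o, m)^2 * 50 / sum((o - mean(o))^2),
               tolerance = 1e-12)
})

test_that("least-squares AIC obeys its log identities", {
  expect_equal(aic_ls(2, 100, 3) - aic_ls(4, 100, 3), -100 * log(2))
  expect_equal(aic_ls(2, 100, 4) - aic_ls(2, 100, 3), 2)
  expect_error(aic_ls(0, 10, 2), "rss")
  expect_error(aic_ls(1, 3, 3), "n_obs")
})

test_that("noiseless self-generated campaigns recover the true traits", {
  tr_true <- hydraulic_traits(-2, 3, rp_min = 1000)
  cfg <- campaign_config(n_records = 200, sigma = 0,
                         psi_pd_wet = c(-1.5, -0.1), psi_pd_dry = c(-5, -1.5))
  camp <- gen_campaign(cfg, tr_true, seed = 5)
  fit <- fit_sox_traits(camp, multistart = 3, seed = 5)
  expect_lt(abs(fit$params$psi50 - tr_true$psi50) / abs(tr_true$psi50), 0.01)
  expect_gt(fit$nse, 0.999)
  # fitted parameters respect the bounds; best beats every start
  expect_true(fit$params$psi50 >= -8 && fit$params$psi50 <= -0.5)
  expect_true(all(fit$rss <= fit$multistart$start_rss + 1e-8))
})

test_that("point bounds are returned verbatim with their rss", {
  tr_true <- hydraulic_traits(-2, 3, rp_min = 1000)
  camp <- gen_campaign(campaign_config(n_records = 30, sigma = 0), tr_true,
                       seed = 2)
  b <- list(psi50 = c(-2.5, -2.5), shape_a = c(3, 3), rp_min = c(800, 800))
  fit <- fit_sox_traits(camp, bounds = b, multistart = 2, seed = 1)
  expect_equal(fit$params$psi50, -2.5)
  expect_equal(fit$params$shape_a, 3)
  expect_equal(fit$params$rp_min, 800, tolerance = 1e-9)
})

test_that("baseline parameters are recovered from baseline-generated data", {
  base_true <- baseline_params(f0 = 0.7, d_crit = 0.05)
  cfg <- campaign_config(n_records = 200, sigma = 0, truth = "beta",
                         d_span = c(0.003, 0.06))
  camp <- gen_campaign(cfg, base = base_true, seed = 3)
  fit <- fit_beta_params(camp, multistart = 4, seed = 3)
  expect_lt(abs(fit$params$f0 - 0.7) / 0.7, 0.01)
  expect_lt(abs(fit$params$d_crit - 0.05) / 0.05, 0.05)
})

test_that("model selection favours the generating scheme under noise", {
  tr_true <- hydraulic_traits(-2, 3, rp_min = 1000)
  camp <- gen_campaign(campaign_config(n_records = 300, sigma = 0.1),
                       tr_true, seed = 17)
  fs <- fit_sox_traits(camp, multistart = 3, seed = 17)
  fb <- fit_beta_params(camp, multistart = 3, seed = 17)
  expect_lt(fs$aic - fb$aic, 0)
  expect_gt(fs$nse, fb$nse)
})

test_that("bootstrap bands behave as percentile envelopes", {
  grid <- psi_grid(n = 12)
  tt_same <- data.frame(psi50 = rep(-2, 5), shape_a = 3, rp_min = 1000)
  bb <- bootstrap_bands(tt_same, grid, n_rep = 50, seed = 1)
  expect_equal(bb$gs_lo, bb$gs_hi, tolerance = 1e-12) # zero-width band
  expect_equal(bb$gs_lo, bb$gs_mean, tolerance = 1e-12)

  tt <- gen_trait_table(trait_prior(), 25, seed = 6)
  bb1 <- bootstrap_bands(tt, grid, n_rep = 400, seed = 1)
  expect_true(all(bb1$gs_lo <= bb1$gs_mean & bb1$gs_mean <= bb1$gs_hi))
  # wider trait dispersion gives (weakly) wider bands
  tt_tight <- tt
  tt_tight$psi50 <- mean(tt$psi50) + 0.1 * (tt$psi50 - mean(tt$psi50))
  bb2 <- bootstrap_bands(tt_tight, grid, n_rep = 400, seed = 1)
  expect_gte(mean(bb1$gs_hi - bb1$gs_lo), mean(bb2$gs_hi - bb2$gs_lo))
  # seed stability at the production replicate count
  bb3 <- bootstrap_bands(tt, grid, n_rep = 1000, seed = 2)
  bb4 <- bootstrap_bands(tt, grid, n_rep = 1000, seed = 3)
  expect_equal(bb3$gs_hi, bb4$gs_hi, tolerance = 0.1)
  expect_equal(bb3$gs_mean, bb4$gs_mean, tolerance = 1e-12) # seed-free part
})
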