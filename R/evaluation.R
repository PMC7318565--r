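#' Root-mean-square error
#'
#' @param obs,mod Numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((obs - mod)^2))`, in the units of `obs`.
#' @export
rmse <- function(obs, mod) {
  stopifnot(length(obs) == length(mod), length(obs) >= 1)
  sqrt(mean((obs - mod)^2))
}

#' Nash-Sutcliffe model efficiency
#'
#' `NSE = 1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2)`. Ranges from
#' -Inf to 1; 1 is perfect agreement, 0 means the model is no better than
#' the observation mean, and negative values mean the mean is the better
#' predictor.
#'
#' @param obs,mod Numeric vectors of equal length; `obs` must have positive
#'   variance.
#' @return The efficiency (dimensionless, <= 1).
#' @export
nse <- function(obs, mod) {
  stopifnot(length(obs) == length(mod), length(obs) >= 2)
  denom <- sum((obs - mean(obs))^2)
  if (denom <= 0) stop("observations have zero variance; NSE undefined")
  1 - sum((obs - mod)^2) / denom
}

#' Least-squares Akaike information criterion
#'
#' `AIC = n ln(rss/n) + 2k`, the Gaussian least-squares form without
#' small-sample correction. Only AIC differences between models fitted to
#' the same observations are meaningful.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_obs Number of observations (> `k_params`).
#' @param k_params Number of fitted parameters.
#' @return The criterion (dimensionless).
#' @export
aic_ls <- function(rss, n_obs, k_params) {
  stopifnot(rss > 0, n_obs > k_params, k_params >= 0)
  n_obs * log(rss / n_obs) + 2 * k_params
}

# shared bounded multistart least-squares driver.
# rss_fn takes the parameter vector on the optimizer scale.
.multistart_fit <- function(rss_fn, lower, upper, multistart, seed) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  k <- length(lower)
  set.seed(seed)
  starts <- matrix(stats::runif(multistart * k, rep(lower, each = multistart),
                                rep(upper, each = multistart)),
                   nrow = multistart)
  point_bounds <- all(upper - lower < 1e-12)
  best <- NULL
  start_rss <- numeric(multistart)
  for (m in seq_len(multistart)) {
    p0 <- starts[m, ]
    start_rss[m] <- rss_fn(p0)
    if (point_bounds) {
      cand <- list(par = p0, value = start_rss[m], convergence = 0L)
    } else {
      cand <- tryCatch(
        stats::optim(p0, rss_fn, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(factr = 1e9, maxit = 200)),
        error = function(e) list(par = p0, value = start_rss[m],
                                 convergence = 99L))
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  list(par = best$par, rss = best$value,
       converged = best$convergence == 0L, start_rss = start_rss,
       starts = starts)
}

#' Fit SOX hydraulic traits to gas-exchange data
#'
#' Bounded least squares of the analytical SOX prediction against observed
#' stomatal conductance over the three hydraulic parameters (psi50, shape a
#' and the minimum plant resistance, the latter fitted on a log10 scale
#' because it spans orders of magnitude). The best of `multistart` seeded
#' starting points drawn uniformly inside the bounds is returned, which
#' guards against the RSS plateaus that arise when the drought signal in the
#' data is weak.
#'
#' @param data Data frame of gas-exchange records with driver columns
#'   `ipar`, `t_air`, `ca`, `patm`, `d`, `psi_pd` (internal units) and
#'   `gs_obs` (mol m^-2 s^-1, CO2 basis).
#' @param bounds List with elements `psi50`, `shape_a`, `rp_min`, each a
#'   length-2 numeric `c(lower, upper)` (`rp_min` in mol^-1 m^2 s MPa).
#' @param params A [photo_params()] object.
#' @param options Solver options from [sox_options()].
#' @param multistart Number of seeded starts (default 8).
#' @param seed Integer seed for the start draws.
#' @return Object of class `"fit_result"`: fitted `traits`, `rss`, `n_obs`,
#'   `k_params`, `nse`, `rmse`, `aic`, `converged`, `seed`, and the
#'   multistart table.
#' @export
fit_sox_traits <- function(data,
                           bounds = list(psi50 = c(-8, -0.5),
                                         shape_a = c(1, 10),
                                         rp_min = c(1e2, 1e4)),
                           params = photo_params(),
                           options = sox_options(),
                           multistart = 8, seed = 1) {
  stopifnot(nrow(data) >= 10, "gs_obs" %in% names(data))
  if (length(unique(data$psi_pd)) < 2)
    warning("single predawn potential in data: hydraulic traits are weakly identified")
  lower <- c(bounds$psi50[1], bounds$shape_a[1], log10(bounds$rp_min[1]))
  upper <- c(bounds$psi50[2], bounds$shape_a[2], log10(bounds$rp_min[2]))
  engine <- .sox_fit_engine(data, params, options)
  rss_fn <- function(p) sum((data$gs_obs - engine(p[1], p[2], 10^p[3]))^2)
  fit <- .multistart_fit(rss_fn, lower, upper, multistart, seed)
  traits <- hydraulic_traits(fit$par[1], fit$par[2], rp_min = 10^fit$par[3])
  pred <- sox_predict_gs(data, traits, params, options)
  .fit_result(traits, list(psi50 = traits$psi50, shape_a = traits$shape_a,
                           rp_min = traits$rp_min),
              data$gs_obs, pred, k_params = 3, fit, seed)
}

#' Fit baseline drought-factor parameters to gas-exchange data
#'
#' Bounded least squares of the empirical baseline prediction over the two
#' closure parameters `f0` and `d_crit`; the critical and wilting moisture
#' contents stay fixed at their defaults (soil potentials of -0.033 and
#' -1.5 MPa). The soil moisture driving the drought factor is obtained from
#' each record's predawn potential through the Brooks-Corey inverse
#' (potentials above the air-entry value saturate at `theta_sat`).
#'
#' @param data As in [fit_sox_traits()].
#' @param soil A [soil_params()] object (held fixed).
#' @param bounds List with `f0` and `d_crit` bounds (`d_crit` in
#'   mol mol^-1).
#' @param params,options,multistart,seed As in [fit_sox_traits()].
#' @return A `"fit_result"` with `base` the fitted [baseline_params()].
#' @export
fit_beta_params <- function(data, soil = soil_params(),
                            bounds = list(f0 = c(0.05, 0.95),
                                          d_crit = c(0.005, 0.3)),
                            params = photo_params(),
                            options = sox_options(),
                            multistart = 8, seed = 1) {
  stopifnot(nrow(data) >= 10, "gs_obs" %in% names(data))
  theta <- ifelse(data$psi_pd >= soil$psi_sat, soil$theta_sat,
                  brooks_corey_theta(pmin(data$psi_pd, soil$psi_sat), soil))
  lower <- c(bounds$f0[1], bounds$d_crit[1])
  upper <- c(bounds$f0[2], bounds$d_crit[2])
  pred_fn <- function(p) {
    base <- baseline_params(f0 = p[1], d_crit = p[2])
    v <- .beta_predict_vec(data$ipar, data$t_air, data$ca, data$patm,
                           data$d, theta, soil, base, params)
    ifelse(is.na(v$gs), options$gs_max, v$gs)
  }
  rss_fn <- function(p) sum((data$gs_obs - pred_fn(p))^2)
  fit <- .multistart_fit(rss_fn, lower, upper, multistart, seed)
  base <- baseline_params(fit$par[1], fit$par[2])
  pred <- pred_fn(fit$par)
  out <- .fit_result(NULL, list(f0 = base$f0, d_crit = base$d_crit),
                     data$gs_obs, pred, k_params = 2, fit, seed)
  out$base <- base
  # flat-likelihood flag: all observed D far below the fitted critical value
  if (max(data$d) < 0.5 * base$d_crit) out$flags <- c(out$flags, "d_crit_weakly_identified")
  out
}

.fit_result <- function(traits, par_list, obs, pred, k_params, fit, seed) {
  rss <- sum((obs - pred)^2)
  structure(list(traits = traits, params = par_list, rss = rss,
                 n_obs = length(obs), k_params = k_params,
                 nse = nse(obs, pred), rmse = rmse(obs, pred),
                 aic = aic_ls(rss, length(obs), k_params),
                 converged = fit$converged, seed = seed,
                 multistart = data.frame(fit$starts,
                                         start_rss = fit$start_rss),
                 flags = character(0)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Least-squares fit (", x$k_params, " parameters, n = ", x$n_obs,
      ")\n", sep = "")
  for (nm in names(x$params))
    cat(sprintf("  %-8s %.4g\n", nm, x$params[[nm]]))
  cat(sprintf("  RSS %.5g  RMSE %.4g  NSE %.4f  AIC %.2f\n",
              x$rss, x$rmse, x$nse, x$aic))
  if (!x$converged) cat("  (optimizer did not report convergence)\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap uncertainty bands for the SOX response curve
#'
#' Propagates within-group trait variability to the predicted stomatal
#' conductance: species rows of the trait table are resampled with
#' replacement, each replicate's mean traits produce one SOX curve over the
#' driver grid, and pointwise percentile bands are reported. Deterministic
#' given the seed. Curves (including the central prediction) are evaluated
#' with the tabulated marginal-gain engine also used for fitting, so a
#' thousand replicates cost little more than one direct solve of the grid.
#'
#' @param trait_table Data frame with columns `psi50`, `shape_a`, `rp_min`
#'   (mol basis), one row per species (>= 2 rows).
#' @param env_grid Data frame of driver rows (`ipar`, `t_air`, `ca`,
#'   `patm`, `d`, `psi_pd`).
#' @param params A [photo_params()] object.
#' @param n_rep Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param probs Band percentiles (default 2.5 and 97.5).
#' @param options Solver options from [sox_options()].
#' @return Data frame: the grid plus `gs_mean` (point prediction at the
#'   trait means), `gs_lo`, `gs_hi`.
#' @export
bootstrap_bands <- function(trait_table, env_grid, params = photo_params(),
                            n_rep = 1000, seed = 1,
                            probs = c(0.025, 0.975),
                            options = sox_options()) {
  stopifnot(nrow(trait_table) >= 2,
            all(c("psi50", "shape_a", "rp_min") %in% names(trait_table)))
  n_sp <- nrow(trait_table)
  # the driver grid is fixed across replicates, so the trait-independent
  # marginal-gain table is computed once and each replicate is arithmetic
  engine <- .sox_fit_engine(env_grid, params, options)
  set.seed(seed)
  curves <- matrix(NA_real_, nrow = n_rep, ncol = nrow(env_grid))
  for (r in seq_len(n_rep)) {
    idx <- sample.int(n_sp, n_sp, replace = TRUE)
    curves[r, ] <- engine(mean(trait_table$psi50[idx]),
                          mean(trait_table$shape_a[idx]),
                          mean(trait_table$rp_min[idx]))
  }
  q <- apply(curves, 2, stats::quantile, probs = probs, names = FALSE)
  out <- env_grid
  out$gs_mean <- engine(mean(trait_table$psi50),
                        mean(trait_table$shape_a),
                        mean(trait_table$rp_min))
  out$gs_lo <- q[1, ]
  out$gs_hi <- q[2, ]
  out
}
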