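#' Brooks-Corey soil parameters
#'
#' Power-law soil water retention: `psi = psi_sat (theta/theta_sat)^(-b)`.
#' The critical and wilting moisture contents used by the empirical
#' drought factor are derived on construction as the moisture at soil
#' potentials of -0.033 and -1.5 MPa respectively.
#'
#' @param theta_sat Saturation volumetric moisture, m^3 m^-3 (> 0).
#' @param psi_sat Air-entry (saturation) potential, MPa (< 0).
#' @param b_exp Retention-curve exponent (> 0).
#' @return Object of class `"soil_params"` with fields `theta_sat`,
#'   `psi_sat`, `b_exp` and derived `theta_c`, `theta_w`.
#' @examples
#' soil_params(0.45, -0.003, 4)
#' @export
soil_params <- function(theta_sat = 0.45, psi_sat = -0.003, b_exp = 4) {
  stopifnot(theta_sat > 0, psi_sat < 0, b_exp > 0)
  s <- structure(list(theta_sat = theta_sat, psi_sat = psi_sat,
                      b_exp = b_exp),
                 class = "soil_params")
  cw <- critical_wilting_points(s)
  s$theta_c <- cw[["theta_c"]]
  s$theta_w <- cw[["theta_w"]]
  s
}

#' Soil water potential from moisture (Brooks-Corey)
#'
#' @param theta Volumetric moisture, m^3 m^-3, in `(0, theta_sat]`.
#' @param soil A [soil_params()] object.
#' @return Potential in MPa (<= `psi_sat`).
#' @export
brooks_corey_psi <- function(theta, soil) {
  if (any(theta <= 0) || any(theta > soil$theta_sat + 1e-12))
    stop("theta must lie in (0, theta_sat]")
  soil$psi_sat * (theta / soil$theta_sat)^(-soil$b_exp)
}

#' Soil moisture from water potential (Brooks-Corey inverse)
#'
#' @param psi Soil water potential, MPa (<= `psi_sat`).
#' @param soil A [soil_params()] object.
#' @return Moisture in m^3 m^-3.
#' @export
brooks_corey_theta <- function(psi, soil) {
  if (any(psi > soil$psi_sat + 1e-15)) stop("psi must be <= psi_sat")
  soil$theta_sat * (psi / soil$psi_sat)^(-1 / soil$b_exp)
}

#' Critical and wilting soil moisture
#'
#' Moisture contents at soil water potentials of -0.033 MPa (critical point)
#' and -1.5 MPa (wilting point), via the Brooks-Corey inverse.
#'
#' @param soil A [soil_params()] object.
#' @return Named numeric vector `c(theta_c, theta_w)`.
#' @export
critical_wilting_points <- function(soil) {
  c(theta_c = brooks_corey_theta(-0.033, soil),
    theta_w = brooks_corey_theta(-1.5, soil))
}

#' Empirical soil drought factor
#'
#' The piecewise-linear factor multiplying assimilation in the baseline
#' scheme: 1 above the critical moisture, 0 at or below wilting, and a
#' linear ramp `(theta - theta_w)/(theta_c - theta_w)` in between.
#'
#' @param theta Root-zone volumetric moisture, m^3 m^-3. Vectorized.
#' @param soil A [soil_params()] object.
#' @return Factor in `[0, 1]`.
#' @export
beta_factor <- function(theta, soil) {
  if (any(theta < 0) || any(theta > soil$theta_sat + 1e-12))
    stop("theta must lie in [0, theta_sat]")
  pmin(pmax((theta - soil$theta_w) / (soil$theta_c - soil$theta_w), 0), 1)
}

#' Empirical parameters of the baseline internal-CO2 closure
#'
#' @param f0 Closure intercept, dimensionless in (0, 1).
#' @param d_crit Critical vapour pressure difference, mol mol^-1 (> 0).
#' @return Object of class `"baseline_params"`.
#' @export
baseline_params <- function(f0 = 0.875, d_crit = 0.09) {
  stopifnot(f0 > 0, f0 < 1, d_crit > 0)
  structure(list(f0 = f0, d_crit = d_crit), class = "baseline_params")
}

#' Internal CO2 from vapour pressure difference (Jacobs closure)
#'
#' `ci = gamma + f0 (1 - D/d_crit) (ca - gamma)`, clamped to
#' `[gamma, ca]`; for `D >= d_crit` the closure returns the compensation
#' point.
#'
#' @param ca Atmospheric CO2 partial pressure, Pa. Vectorized, as are `d`
#'   and `gamma`.
#' @param d Leaf-to-air vapour pressure difference, mol mol^-1 (>= 0).
#' @param gamma CO2 compensation point, Pa.
#' @param base A [baseline_params()] object.
#' @return Internal CO2, Pa.
#' @examples
#' jacobs_ci(36, d = 0.045, gamma = 4, baseline_params(0.875, 0.09)) # 18 Pa
#' @export
jacobs_ci <- function(ca, d, gamma, base) {
  if (any(d < 0)) stop("D must be >= 0")
  ci <- gamma + base$f0 * (1 - d / base$d_crit) * (ca - gamma)
  pmin(pmax(ci, gamma), ca)
}

# vectorized baseline gs prediction over plain driver vectors
.beta_predict_vec <- function(ipar, t_air, ca, patm, d, theta,
                              soil, base, params) {
  kin <- temperature_adjust(params, t_air)
  beta <- beta_factor(theta, soil)
  ci <- jacobs_ci(ca, d, kin$gamma, base)
  a_pot <- .a_from_ci_vec(ci, ipar, patm, params, kin)
  a_str <- beta * a_pot
  denom <- (ca - ci) / patm
  gs <- ifelse(denom > 1e-12, pmax(a_str / denom, 0), NA_real_)
  list(gs = gs, a_net = a_str, ci = ci, beta = beta,
       at_ca = !(denom > 1e-12))
}

#' Baseline (drought-factor) stomatal solve
#'
#' The empirical baseline scheme: internal CO2 from the Jacobs closure,
#' potential net assimilation at that `ci`, soil-moisture stress applied as
#' the multiplicative factor `beta(theta)`, and stomatal conductance
#' diagnosed from the diffusion supply `gs = A patm / (ca - ci)`, floored
#' at zero. When the closure returns `ci = ca` (so the supply relation is
#' singular) gs is reported at `gs_max` with a flag.
#'
#' @param env A [leaf_env()] object.
#' @param theta Root-zone volumetric moisture, m^3 m^-3.
#' @param soil A [soil_params()] object.
#' @param base A [baseline_params()] object.
#' @param params A [photo_params()] object.
#' @param options Solver options from [sox_options()] (for `gs_max`).
#' @return A `"stomatal_solution"` with `scheme = "beta_baseline"` and the
#'   applied `beta`.
#' @export
beta_gs_solve <- function(env, theta, soil, base = baseline_params(),
                          params = photo_params(), options = sox_options()) {
  v <- .beta_predict_vec(env$ipar, env$t_air, env$ca, env$patm, env$d,
                         theta, soil, base, params)
  flags <- character(0)
  if (any(v$at_ca)) {
    v$gs[v$at_ca] <- options$gs_max
    flags <- "ci_at_ca_gs_max"
  }
  sol <- list(gs = v$gs, a_net = v$a_net, ci = v$ci,
              e_trans = 1.6 * v$gs * env$d,
              psi_c = NA_real_, psi_m = NA_real_, k = NA_real_,
              xi = NA_real_, rp = NA_real_, iterations = NA_integer_,
              flags = flags)
  .solution(sol, "beta_baseline", beta = v$beta)
}
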