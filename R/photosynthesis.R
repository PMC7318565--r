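#' Leaf photosynthesis parameters (Collatz-type, JULES-style colimitation)
#'
#' Parameter set for the C3/C4 leaf photosynthesis scheme: potential rates
#' limited by Rubisco carboxylation, light and photoassimilate export (C3)
#' or PEP-carboxylase (C4), combined through two nested quadratic
#' colimitation steps.
#'
#' Defaults follow the broadleaf evergreen tropical tree parameterization
#' used with JULES: `vcmax25 = 100e-6` mol m^-2 s^-1, Q10 of 2 (Vcmax),
#' 2.1/1.2 (Michaelis constants), 0.57 (CO2/O2 specificity), quantum
#' efficiency 0.08 mol CO2 per mol photons, leaf scattering 0.15, Michaelis
#' constants 30 Pa (CO2) and 30000 Pa (O2) at 25 C, specificity 2600, dark
#' respiration 1.5% of Vcmax, colimitation coefficients 0.83 and 0.93, and
#' high/low temperature inhibition thresholds of 43/13 C. All fields can be
#' overridden.
#'
#' @param pathway `"C3"` or `"C4"`.
#' @param vcmax25 Maximum carboxylation rate at 25 C, mol CO2 m^-2 s^-1.
#' @param q10_vcmax,q10_kc,q10_ko,q10_tau Q10 temperature sensitivities.
#' @param t_upp,t_low High/low temperature inhibition thresholds, C.
#' @param alpha_q Quantum efficiency, mol CO2 per mol photons.
#' @param omega Leaf scattering coefficient (dimensionless).
#' @param kc25,ko25 Michaelis constants for CO2/O2 at 25 C, Pa.
#' @param oa Atmospheric O2 partial pressure, Pa.
#' @param tau25 CO2/O2 specificity at 25 C (dimensionless).
#' @param f_dr Dark respiration as a fraction of Vcmax.
#' @param beta1,beta2 Colimitation quadratic coefficients, in (0, 1].
#' @return An object of class `"photo_params"`.
#' @export
photo_params <- function(pathway = c("C3", "C4"),
                         vcmax25 = 100e-6,
                         q10_vcmax = 2, q10_kc = 2.1, q10_ko = 1.2,
                         q10_tau = 0.57,
                         t_upp = 43, t_low = 13,
                         alpha_q = 0.08, omega = 0.15,
                         kc25 = 30, ko25 = 30000, oa = 21000,
                         tau25 = 2600, f_dr = 0.015,
                         beta1 = 0.83, beta2 = 0.93) {
  pathway <- match.arg(pathway)
  stopifnot(vcmax25 > 0, alpha_q > 0, kc25 > 0, ko25 > 0, tau25 > 0,
            oa > 0, f_dr >= 0, omega >= 0, omega < 1)
  if (!(beta1 > 0 && beta1 <= 1 && beta2 > 0 && beta2 <= 1))
    stop("colimitation coefficients must lie in (0, 1]")
  structure(list(pathway = pathway, vcmax25 = vcmax25,
                 q10_vcmax = q10_vcmax, q10_kc = q10_kc, q10_ko = q10_ko,
                 q10_tau = q10_tau, t_upp = t_upp, t_low = t_low,
                 alpha_q = alpha_q, omega = omega, kc25 = kc25, ko25 = ko25,
                 oa = oa, tau25 = tau25, f_dr = f_dr,
                 beta1 = beta1, beta2 = beta2),
            class = "photo_params")
}

#' Leaf environment for one stomatal solve
#'
#' Instantaneous drivers of a single leaf-level solve. Internally radiation
#' is in mol photons m^-2 s^-1, CO2 in Pa, and the vapour pressure difference
#' is a mole fraction; `d_units = "kPa"` converts by dividing by the ambient
#' pressure.
#'
#' @param ipar Incident photosynthetically active radiation,
#'   mol photons m^-2 s^-1 (>= 0).
#' @param t_air Air (= leaf) temperature, C.
#' @param ca Atmospheric CO2 partial pressure, Pa (> 0).
#' @param patm Atmospheric pressure, Pa (default 101325).
#' @param d Leaf-to-air vapour pressure difference; mole fraction unless
#'   `d_units = "kPa"`.
#' @param psi_pd Predawn water potential, MPa (<= 0).
#' @param d_units `"mol_mol"` (default) or `"kPa"`.
#' @return An object of class `"leaf_env"`.
#' @examples
#' leaf_env(ipar = 600e-6, t_air = 25, ca = 36, d = 0.5, psi_pd = -0.5,
#'          d_units = "kPa")
#' @export
leaf_env <- function(ipar, t_air, ca, patm = 101325, d, psi_pd,
                     d_units = c("mol_mol", "kPa")) {
  d_units <- match.arg(d_units)
  stopifnot(ipar >= 0, ca > 0, patm > 0, d >= 0, psi_pd <= 0)
  if (d_units == "kPa") d <- d * 1000 / patm
  structure(list(ipar = ipar, t_air = t_air, ca = ca, patm = patm,
                 d = d, psi_pd = psi_pd),
            class = "leaf_env")
}

#' Temperature-adjusted kinetic constants
#'
#' Scales each kinetic constant by `Q10^((T - 25)/10)`; Vcmax is further
#' divided by the sigmoidal high/low temperature inhibition factor
#' `(1 + exp(0.3 (T - t_upp))) (1 + exp(0.3 (t_low - T)))`. The CO2
#' compensation point is `gamma = oa / (2 tau)` (0 for C4) and dark
#' respiration `r_d = f_dr * vcmax`. The inhibition factor is not normalized
#' to unity at 25 C.
#'
#' @param params A [photo_params()] object.
#' @param t_air Temperature, C. Vectorized.
#' @return List with vectors `vcmax`, `kc`, `ko`, `tau`, `gamma`, `r_d`.
#' @export
temperature_adjust <- function(params, t_air) {
  q10f <- function(q10) q10^((t_air - 25) / 10)
  inhib <- (1 + exp(0.3 * (t_air - params$t_upp))) *
    (1 + exp(0.3 * (params$t_low - t_air)))
  vcmax <- params$vcmax25 * q10f(params$q10_vcmax) / inhib
  tau <- params$tau25 * q10f(params$q10_tau)
  gamma <- if (params$pathway == "C3") params$oa / (2 * tau) else 0 * tau
  list(vcmax = vcmax,
       kc = params$kc25 * q10f(params$q10_kc),
       ko = params$ko25 * q10f(params$q10_ko),
       tau = tau, gamma = gamma,
       r_d = params$f_dr * vcmax)
}

#' Limiting photosynthetic rates
#'
#' The three potential gross rates at a given internal CO2. For C3:
#' Rubisco `vcmax (ci - gamma) / (ci + kc (1 + oa/ko))`, light
#' `alpha (1 - omega) Ipar (ci - gamma) / (ci + 2 gamma)` and export
#' `0.5 vcmax`. For C4: `vcmax`, `alpha (1 - omega) Ipar` and
#' `2e4 vcmax ci / patm`. Rates may be negative below the compensation
#' point (net CO2 efflux).
#'
#' @param ci Internal CO2 partial pressure, Pa (>= 0). Vectorized, as are
#'   `ipar` and `patm`.
#' @param ipar Incident PAR, mol photons m^-2 s^-1.
#' @param patm Atmospheric pressure, Pa.
#' @param params A [photo_params()] object.
#' @param kin Temperature-adjusted constants from [temperature_adjust()].
#' @return List with vectors `w_carbox`, `w_light`, `w_export`
#'   (mol CO2 m^-2 s^-1).
#' @export
limiting_rates <- function(ci, ipar, patm, params, kin) {
  if (any(ci < 0)) stop("ci must be >= 0")
  if (params$pathway == "C3") {
    list(w_carbox = kin$vcmax * (ci - kin$gamma) /
           (ci + kin$kc * (1 + params$oa / kin$ko)),
         w_light = params$alpha_q * (1 - params$omega) * ipar *
           (ci - kin$gamma) / (ci + 2 * kin$gamma),
         w_export = 0.5 * kin$vcmax + 0 * ci)
  } else {
    list(w_carbox = kin$vcmax + 0 * ci,
         w_light = params$alpha_q * (1 - params$omega) * ipar + 0 * ci,
         w_export = 2e4 * kin$vcmax * ci / patm)
  }
}

# smaller root of b x^2 - (p + q) x + p q = 0; reduces to min(p, q) at b = 1
.colimit_root <- function(p, q, b) {
  s <- p + q
  disc <- s^2 - 4 * b * p * q
  disc[disc < 0 & disc > -1e-14 * pmax(s^2, 1)] <- 0 # roundoff guard
  if (any(disc < 0)) stop("colimitation discriminant negative: invalid inputs")
  (s - sqrt(disc)) / (2 * b)
}

#' Colimited gross assimilation
#'
#' Combines the three limiting rates through two nested quadratics: `Wp` is
#' the smaller root of `beta1 Wp^2 - Wp (w_carbox + w_light) + w_carbox
#' w_light = 0`, and the gross rate `W` the smaller root of
#' `beta2 W^2 - W (Wp + w_export) + Wp w_export = 0`. With both coefficients
#' at 1 this reduces to the hard minimum of the three rates; values below 1
#' smooth the transitions.
#'
#' @param w_carbox,w_light,w_export Limiting rates, mol CO2 m^-2 s^-1.
#'   Vectorized.
#' @param beta1,beta2 Colimitation coefficients in (0, 1].
#' @return Gross assimilation `W <= min(w_carbox, w_light, w_export)`.
#' @export
colimit <- function(w_carbox, w_light, w_export, beta1, beta2) {
  if (!(beta1 > 0 && beta1 <= 1 && beta2 > 0 && beta2 <= 1))
    stop("colimitation coefficients must lie in (0, 1]")
  wp <- .colimit_root(w_carbox, w_light, beta1)
  .colimit_root(wp, w_export, beta2)
}

# internal vectorized net assimilation at prescribed ci (plain vectors)
.a_from_ci_vec <- function(ci, ipar, patm, params, kin) {
  w <- limiting_rates(ci, ipar, patm, params, kin)
  colimit(w$w_carbox, w$w_light, w$w_export, params$beta1, params$beta2) -
    kin$r_d
}

#' Net assimilation at prescribed internal CO2
#'
#' Evaluates the colimited gross rate at the given `ci` and subtracts dark
#' respiration.
#'
#' @param ci Internal CO2 partial pressure, Pa (>= 0).
#' @param env A [leaf_env()] object.
#' @param params A [photo_params()] object.
#' @return List of class `"assimilation_result"` with `a_net`, `ci`,
#'   `w_carbox`, `w_light`, `w_export`, `r_d`, `gamma`.
#' @export
solve_a_from_ci <- function(ci, env, params) {
  kin <- temperature_adjust(params, env$t_air)
  w <- limiting_rates(ci, env$ipar, env$patm, params, kin)
  gross <- colimit(w$w_carbox, w$w_light, w$w_export, params$beta1, params$beta2)
  structure(list(a_net = gross - kin$r_d, ci = ci,
                 w_carbox = w$w_carbox, w_light = w$w_light,
                 w_export = w$w_export, r_d = kin$r_d, gamma = kin$gamma),
            class = "assimilation_result")
}

# Vectorized joint solve of the diffusion supply a = gs (ca - ci) / patm with
# the biochemical demand a = A(ci). The residual demand - supply is monotone
# increasing in ci, so a guarded bisection is exact to bracket-width 2^-nbits.
# gs == 0 rows solve A(ci) = 0 (net compensation point); if none exists in
# the bracket (e.g. darkness) ci is clamped at the top and flagged.
.a_from_gs_vec <- function(gs, ipar, patm, ca, params, kin, nbits = 60L) {
  n <- max(length(gs), length(ipar), length(patm), length(ca),
           length(kin$vcmax))
  gs <- rep_len(gs, n); ipar <- rep_len(ipar, n)
  patm <- rep_len(patm, n); ca <- rep_len(ca, n)
  kin <- lapply(kin, rep_len, n)
  rd <- kin$r_d
  lo <- numeric(n)
  hi <- pmax(1.5 * ca, ca + 1 + rd * patm / pmax(gs, 1e-9))
  hi <- pmin(hi, 1e7)
  resid <- function(ci) .a_from_ci_vec(ci, ipar, patm, params, kin) -
    gs * (ca - ci) / patm
  no_root <- resid(hi) < 0
  for (i in seq_len(nbits)) {
    mid <- 0.5 * (lo + hi)
    up <- resid(mid) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  ci <- 0.5 * (lo + hi)
  ci[no_root] <- hi[no_root]
  a <- gs * (ca - ci) / patm
  a[no_root & gs == 0] <- 0
  list(a_net = a, ci = ci, no_root = no_root)
}

#' Net assimilation at prescribed stomatal conductance
#'
#' Solves simultaneously the diffusion supply `a = gs (ca - ci) / patm`
#' (mole-fraction form; `gs` is the CO2-basis conductance) and the
#' biochemical demand `a = A(ci)` from [solve_a_from_ci()]. The residual
#' demand minus supply is monotone increasing in `ci`, so the root is found
#' by guarded bisection to machine-level bracket width.
#'
#' At `gs = 0` the returned `a_net` is 0 and `ci` sits at the net
#' compensation point (gross assimilation equals respiration); in darkness no
#' such point exists and the result is flagged `"no_compensation"`.
#'
#' @param gs Stomatal conductance to CO2, mol m^-2 s^-1 (>= 0).
#' @param env A [leaf_env()] object.
#' @param params A [photo_params()] object.
#' @return List with `a_net`, `ci` (Pa), `r_d`, `gamma`, `flags` (character).
#' @export
solve_a_from_gs <- function(gs, env, params) {
  if (any(gs < 0)) stop("gs must be >= 0")
  kin <- temperature_adjust(params, env$t_air)
  sol <- .a_from_gs_vec(gs, env$ipar, env$patm, env$ca, params, kin)
  flags <- character(0)
  if (any(sol$no_root)) flags <- "no_compensation"
  list(a_net = sol$a_net, ci = sol$ci, r_d = kin$r_d, gamma = kin$gamma,
       flags = flags)
}

# internal vectorized central-difference dA/dci, mole-fraction basis
.dadci_vec <- function(ci, ipar, patm, params, kin, rel_step = 1e-3) {
  h <- pmax(0.01, rel_step * ci)
  lo <- pmax(ci - h, 0)
  hi <- ci + h
  slope_pa <- (.a_from_ci_vec(hi, ipar, patm, params, kin) -
                 .a_from_ci_vec(lo, ipar, patm, params, kin)) / (hi - lo)
  slope_pa * patm
}

#' Sensitivity of net assimilation to internal CO2
#'
#' Central-difference derivative of [solve_a_from_ci()] with respect to `ci`
#' (step `max(0.01 Pa, 1e-3 ci)`), returned on the mole-fraction basis: the
#' per-Pa slope is multiplied by `patm` so that the ratio `xi / (dA/dci)`
#' in the stomatal optimum is dimensionless in conductance units.
#'
#' @param ci Internal CO2 partial pressure, Pa (> 0).
#' @param env A [leaf_env()] object.
#' @param params A [photo_params()] object.
#' @param rel_step Relative step of the central difference.
#' @return Slope in mol m^-2 s^-1 per (mol mol^-1).
#' @export
dA_dci <- function(ci, env, params, rel_step = 1e-3) {
  if (any(ci <= 0)) stop("ci must be > 0")
  kin <- temperature_adjust(params, env$t_air)
  .dadci_vec(ci, env$ipar, env$patm, params, kin, rel_step)
}
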