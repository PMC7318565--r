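#' Trait prior for synthetic trait tables
#'
#' Mean and standard deviation per hydraulic trait, with truncation bounds
#' keeping draws physically valid. The default prior follows broadleaf
#' evergreen tropical trees: psi50 -1.9 (+-1.3) MPa, shape 4.4 (+-2.1),
#' minimum resistance 2.2 (+-3.4) on the mmol basis (converted to
#' mol^-1 m^2 s MPa internally).
#'
#' @param pft Label.
#' @param psi50_mean,psi50_sd Mean/SD of psi50, MPa.
#' @param shape_mean,shape_sd Mean/SD of the vulnerability shape.
#' @param rpmin_mean,rpmin_sd Mean/SD of the minimum resistance,
#'   mmol^-1 m^2 s MPa.
#' @param psi50_range,shape_range,rpmin_range Truncation bounds (rpmin
#'   bounds on the mmol basis).
#' @return Object of class `"trait_prior"`.
#' @export
trait_prior <- function(pft = "BET-Tr",
                        psi50_mean = -1.9, psi50_sd = 1.3,
                        shape_mean = 4.4, shape_sd = 2.1,
                        rpmin_mean = 2.2, rpmin_sd = 3.4,
                        psi50_range = c(-12, -0.2),
                        shape_range = c(0.8, 15),
                        rpmin_range = c(0.1, 30)) {
  stopifnot(psi50_sd >= 0, shape_sd >= 0, rpmin_sd >= 0,
            psi50_range[2] < 0, shape_range[1] > 0, rpmin_range[1] > 0)
  structure(list(pft = pft, psi50_mean = psi50_mean, psi50_sd = psi50_sd,
                 shape_mean = shape_mean, shape_sd = shape_sd,
                 rpmin_mean = rpmin_mean, rpmin_sd = rpmin_sd,
                 psi50_range = psi50_range, shape_range = shape_range,
                 rpmin_range = rpmin_range),
            class = "trait_prior")
}

# truncated-normal draws by rejection; exact for sd = 0 (returns the mean,
# which must lie inside the bounds)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate prior mean outside truncation bounds")
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic species trait table
#'
#' Truncated-normal draws of the three hydraulic traits, one row per
#' species. Deterministic given the seed.
#'
#' @param prior A [trait_prior()] object.
#' @param n_species Number of rows (>= 1).
#' @param seed Integer seed.
#' @return Data frame with `pft`, `species`, `psi50`, `shape_a`, `rp_min`
#'   (mol basis, i.e. prior mmol values times 1000).
#' @export
gen_trait_table <- function(prior = trait_prior(), n_species, seed = 1) {
  stopifnot(n_species >= 1)
  set.seed(seed)
  data.frame(
    pft = prior$pft,
    species = sprintf("sp%03d", seq_len(n_species)),
    psi50 = .rtruncnorm(n_species, prior$psi50_mean, prior$psi50_sd,
                        prior$psi50_range[1], prior$psi50_range[2]),
    shape_a = .rtruncnorm(n_species, prior$shape_mean, prior$shape_sd,
                          prior$shape_range[1], prior$shape_range[2]),
    rp_min = 1000 * .rtruncnorm(n_species, prior$rpmin_mean, prior$rpmin_sd,
                                prior$rpmin_range[1], prior$rpmin_range[2]))
}

#' Campaign configuration for the gas-exchange generator
#'
#' Driver spans and noise model for [gen_campaign()]. The predawn-potential
#' sampler is a two-component uniform mixture (by default 70% over the
#' well-watered span -1.5 to -0.05 MPa and 30% over the drought tail -7 to
#' -1.5 MPa) so that campaigns cover well-watered through extreme drought
#' with a realistic drought tail.
#'
#' @param n_records Number of records (>= 1).
#' @param psi_pd_wet,psi_pd_dry Length-2 spans (MPa) of the wet component
#'   and the drought tail.
#' @param p_wet Mixture weight of the wet component.
#' @param d_span Span of the vapour pressure difference, mol mol^-1.
#' @param ipar_span Span of incident PAR, mol m^-2 s^-1.
#' @param t_span Temperature span, C.
#' @param ca Atmospheric CO2 values, Pa (sampled uniformly from the set).
#' @param patm Atmospheric pressure, Pa.
#' @param noise `"multiplicative"` (`gs_obs = gs (1 + eps)`) or
#'   `"additive"` (`gs_obs = gs + eps`), Gaussian `eps` with sd `sigma`
#'   (additive sd in mol m^-2 s^-1); observations floored at 0.
#' @param sigma Noise standard deviation (default 0.1 multiplicative).
#' @param truth `"sox"` or `"beta"`: scheme generating the true gs.
#' @return Object of class `"campaign_config"`.
#' @export
campaign_config <- function(n_records = 300,
                            psi_pd_wet = c(-1.5, -0.05),
                            psi_pd_dry = c(-7, -1.5), p_wet = 0.7,
                            d_span = c(0.003, 0.03),
                            ipar_span = c(100e-6, 2000e-6),
                            t_span = c(15, 35),
                            ca = 36, patm = 101325,
                            noise = c("multiplicative", "additive"),
                            sigma = 0.1,
                            truth = c("sox", "beta")) {
  noise <- match.arg(noise)
  truth <- match.arg(truth)
  stopifnot(n_records >= 1, sigma >= 0, p_wet >= 0, p_wet <= 1,
            diff(psi_pd_wet) > 0, diff(psi_pd_dry) > 0,
            diff(d_span) > 0, diff(ipar_span) >= 0, diff(t_span) >= 0)
  structure(list(n_records = n_records, psi_pd_wet = psi_pd_wet,
                 psi_pd_dry = psi_pd_dry, p_wet = p_wet, d_span = d_span,
                 ipar_span = ipar_span, t_span = t_span, ca = ca,
                 patm = patm, noise = noise, sigma = sigma, truth = truth),
            class = "campaign_config")
}

#' Generate a synthetic gas-exchange campaign
#'
#' Draws environmental drivers independently within the configured spans,
#' computes the true stomatal conductance under the declared scheme
#' (analytical SOX with the supplied traits, or the drought-factor baseline
#' with moisture from the Brooks-Corey inverse of the predawn potential),
#' and adds observation noise. Deterministic given the seed.
#'
#' @param config A [campaign_config()] object.
#' @param traits A [hydraulic_traits()] object (used when `truth = "sox"`).
#' @param params A [photo_params()] object.
#' @param soil,base Soil and closure parameters (used when
#'   `truth = "beta"`).
#' @param seed Integer seed.
#' @param options Solver options from [sox_options()].
#' @return Data frame of records: drivers (`ipar`, `t_air`, `ca`, `patm`,
#'   `d`, `psi_pd`), `gs_true`, `gs_obs`, `species`, `pft`.
#' @export
gen_campaign <- function(config = campaign_config(),
                         traits = hydraulic_traits(-2, 3, rp_min = 1000),
                         params = photo_params(),
                         soil = soil_params(), base = baseline_params(),
                         seed = 1, options = sox_options()) {
  n <- config$n_records
  set.seed(seed)
  wet <- stats::runif(n) < config$p_wet
  psi_pd <- ifelse(wet,
                   stats::runif(n, config$psi_pd_wet[1], config$psi_pd_wet[2]),
                   stats::runif(n, config$psi_pd_dry[1], config$psi_pd_dry[2]))
  d <- stats::runif(n, config$d_span[1], config$d_span[2])
  ipar <- stats::runif(n, config$ipar_span[1], config$ipar_span[2])
  t_air <- stats::runif(n, config$t_span[1], config$t_span[2])
  ca <- if (length(config$ca) == 1L) rep(config$ca, n) else
    sample(config$ca, n, replace = TRUE)
  rec <- data.frame(ipar = ipar, t_air = t_air, ca = ca, patm = config$patm,
                    d = d, psi_pd = psi_pd)
  if (config$truth == "sox") {
    gs_true <- sox_predict_gs(rec, traits, params, options)
  } else {
    theta <- ifelse(psi_pd >= soil$psi_sat, soil$theta_sat,
                    brooks_corey_theta(pmin(psi_pd, soil$psi_sat), soil))
    v <- .beta_predict_vec(ipar, t_air, ca, config$patm, d, theta,
                           soil, base, params)
    gs_true <- ifelse(is.na(v$gs), options$gs_max, v$gs)
  }
  eps <- stats::rnorm(n, 0, config$sigma)
  gs_obs <- if (config$noise == "multiplicative") gs_true * (1 + eps) else
    gs_true + eps
  rec$gs_true <- gs_true
  rec$gs_obs <- pmax(gs_obs, 0)
  rec$species <- "synthetic"
  rec$pft <- if (config$truth == "sox") "synthetic-sox" else "synthetic-beta"
  rec
}

#' Generate synthetic daily drydown forcing
#'
#' Seeded stochastic daily weather for [drydown_simulate()]: PAR,
#' temperature and vapour pressure difference follow a sinusoidal seasonal
#' cycle with Gaussian day-to-day noise, and rainfall is Bernoulli
#' occurrence times an exponential depth. Reproducible given the seed.
#'
#' @param days Number of days (>= 1).
#' @param ipar_mean Mean daytime PAR, mol m^-2 s^-1.
#' @param ipar_amp Seasonal amplitude of PAR (fraction of the mean).
#' @param t_mean,t_amp Mean and seasonal amplitude of temperature, C.
#' @param d_mean,d_amp Mean and seasonal amplitude of the vapour pressure
#'   difference, mol mol^-1.
#' @param rain_prob Daily rain probability in `[0, 1]`.
#' @param rain_depth_mm Mean depth of a rain day, mm.
#' @param ca,patm CO2 (Pa) and pressure (Pa).
#' @param seed Integer seed.
#' @return Data frame with `day`, `ipar`, `t_air`, `ca`, `patm`, `d`,
#'   `precip_mm`.
#' @export
gen_drydown_forcing <- function(days, ipar_mean = 800e-6, ipar_amp = 0.3,
                                t_mean = 22, t_amp = 6,
                                d_mean = 0.012, d_amp = 0.4,
                                rain_prob = 0.25, rain_depth_mm = 8,
                                ca = 36, patm = 101325, seed = 1) {
  stopifnot(days >= 1, rain_prob >= 0, rain_prob <= 1, rain_depth_mm > 0)
  set.seed(seed)
  phase <- 2 * pi * (seq_len(days) - 1) / 365
  cyc <- sin(phase)
  ipar <- pmax(ipar_mean * (1 + ipar_amp * cyc) *
                 (1 + stats::rnorm(days, 0, 0.15)), 1e-6)
  t_air <- t_mean + t_amp * cyc + stats::rnorm(days, 0, 1.5)
  d <- pmax(d_mean * (1 + d_amp * cyc) * (1 + stats::rnorm(days, 0, 0.2)),
            1e-4)
  rain <- (stats::runif(days) < rain_prob) *
    stats::rexp(days, rate = 1 / rain_depth_mm)
  data.frame(day = seq_len(days), ipar = ipar, t_air = t_air, ca = ca,
             patm = patm, d = d, precip_mm = rain)
}
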