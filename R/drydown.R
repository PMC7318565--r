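#' Single-bucket soil drydown simulation
#'
#' A deliberately minimal daily soil water bucket contrasting the SOX and
#' drought-factor stomatal schemes under the same forcing. Each day the
#' predawn water potential is taken from the Brooks-Corey retention curve at
#' the current moisture, the leaf-level scheme is solved with the day's
#' drivers, canopy fluxes are scaled by leaf area index over the daylight
#' period, and the bucket is updated with precipitation minus transpiration.
#' A single soil layer, fixed LAI, residual moisture floor and
#' saturation clipping; no drainage or runoff beyond the clip.
#'
#' The GPP proxy is the gross canopy assimilation
#' `(A_net + R_d) * LAI * daylight`; light-use efficiency is that proxy per
#' absorbed PAR, with absorption `1 - exp(-0.5 LAI)` (Beer's law).
#'
#' @param forcing Data frame with daily columns `ipar`
#'   (mol photons m^-2 s^-1, daytime mean), `t_air` (C), `ca` (Pa), `patm`
#'   (Pa), `d` (mol mol^-1) and `precip_mm` (mm d^-1), e.g. from
#'   [gen_drydown_forcing()].
#' @param traits A [hydraulic_traits()] object (SOX scheme).
#' @param params A [photo_params()] object.
#' @param soil A [soil_params()] object.
#' @param base A [baseline_params()] object (drought-factor scheme).
#' @param scheme `"sox"` or `"beta"`.
#' @param theta0 Initial moisture, m^3 m^-3 (default: critical point).
#' @param bucket_depth Bucket depth, m.
#' @param lai Leaf area index (one-sided).
#' @param theta_residual Moisture floor, m^3 m^-3.
#' @param daylight_s Daylight seconds per day over which daytime-mean fluxes
#'   act.
#' @param options Solver options from [sox_options()].
#' @return Data frame of class `"drydown_result"` with daily `theta`,
#'   `psi_pd`, `gs`, `gpp` (mol CO2 m^-2 ground d^-1), `e_mm` (mm d^-1),
#'   `lue`, `beta` (NA for SOX) and `balance_err_m` (per-step water-balance
#'   closure, m). Attribute `truncated` flags days when demand exceeded the
#'   available water.
#' @export
drydown_simulate <- function(forcing, traits, params = photo_params(),
                             soil = soil_params(), base = baseline_params(),
                             scheme = c("sox", "beta"), theta0 = NULL,
                             bucket_depth = 1, lai = 2,
                             theta_residual = 0.01, daylight_s = 43200,
                             options = sox_options()) {
  scheme <- match.arg(scheme)
  need <- c("ipar", "t_air", "ca", "patm", "d", "precip_mm")
  miss <- setdiff(need, names(forcing))
  if (length(miss)) stop("forcing lacks columns: ", paste(miss, collapse = ", "))
  ndays <- nrow(forcing)
  if (is.null(theta0)) theta0 <- soil$theta_c
  stopifnot(theta0 > theta_residual, theta0 <= soil$theta_sat,
            bucket_depth > 0, lai > 0)
  theta <- numeric(ndays); psi_pd <- numeric(ndays); gs <- numeric(ndays)
  gpp <- numeric(ndays); e_mm <- numeric(ndays); lue <- numeric(ndays)
  beta <- rep(NA_real_, ndays); bal <- numeric(ndays)
  truncated <- logical(ndays)
  th <- theta0
  fapar <- 1 - exp(-0.5 * lai)
  for (i in seq_len(ndays)) {
    theta[i] <- th
    psi <- brooks_corey_psi(th, soil)
    psi_pd[i] <- psi
    row <- forcing[i, ]
    if (scheme == "sox") {
      v <- .sox_predict_vec(row$ipar, row$t_air, row$ca, row$patm, row$d,
                            min(psi, 0), traits, params, options)
      gs[i] <- v$gs
      a_net <- v$a_net
    } else {
      v <- .beta_predict_vec(row$ipar, row$t_air, row$ca, row$patm, row$d,
                             th, soil, base, params)
      gs[i] <- ifelse(is.na(v$gs), options$gs_max, v$gs)
      a_net <- v$a_net
      beta[i] <- v$beta
    }
    rd <- temperature_adjust(params, row$t_air)$r_d
    gpp[i] <- max(a_net + rd, 0) * lai * daylight_s
    apar <- row$ipar * fapar * daylight_s
    lue[i] <- if (apar > 0) gpp[i] / apar else NA_real_
    e_mol <- 1.6 * gs[i] * row$d * lai * daylight_s # mol H2O m^-2 d^-1
    e_m <- e_mol * 18.01528e-3 * 1e-3               # kg m^-2 = mm, then m
    p_m <- row$precip_mm * 1e-3
    avail <- (th - theta_residual) * bucket_depth + p_m
    if (e_m > avail) {
      e_m <- avail
      truncated[i] <- TRUE
    }
    th_new <- th + (p_m - e_m) / bucket_depth
    overflow <- max(th_new - soil$theta_sat, 0) * bucket_depth
    th_new <- min(th_new, soil$theta_sat)
    bal[i] <- bucket_depth * (th_new - th) - (p_m - e_m - overflow)
    e_mm[i] <- e_m * 1e3
    th <- th_new
  }
  out <- data.frame(day = seq_len(ndays), theta = theta, psi_pd = psi_pd,
                    gs = gs, gpp = gpp, e_mm = e_mm, lue = lue, beta = beta,
                    balance_err_m = bal)
  attr(out, "truncated") <- truncated
  attr(out, "scheme") <- scheme
  class(out) <- c("drydown_result", class(out))
  out
}

#' Walsh-Lawler seasonality index
#'
#' Relative seasonality of 12 monthly totals:
#' `SI = (1/R) * sum(|x_i - R/12|)` with `R` the annual total. 0 for a
#' uniform regime; the maximum, `2 * 11/12`, when everything falls in one
#' month. Invariant to rescaling all months by a constant.
#'
#' @param monthly Numeric vector of 12 non-negative monthly totals with a
#'   positive sum.
#' @return The index (dimensionless).
#' @examples
#' seasonality_index(rep(10, 12)) # 0
#' @export
seasonality_index <- function(monthly) {
  if (length(monthly) != 12) stop("monthly must have 12 values")
  if (any(monthly < 0) || any(!is.finite(monthly))) stop("monthly totals must be non-negative and finite")
  r <- sum(monthly)
  if (r <= 0) stop("annual total must be positive")
  sum(abs(monthly - r / 12)) / r
}
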