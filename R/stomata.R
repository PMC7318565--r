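#' Closed-form optimal stomatal conductance
#'
#' The SOX optimum: given the marginal carbon benefit of opening stomata
#' (`dadci`, the sensitivity of net assimilation to internal CO2 on the
#' mole-fraction basis) and the hydraulic cost term `xi`,
#' `gs = 0.5 dadci (sqrt(4 xi / dadci + 1) - 1)`.
#' The limit `dadci -> 0` gives `gs = 0`; for `xi >> dadci` the optimum
#' behaves as `sqrt(xi dadci)`. Monotone increasing in both arguments.
#'
#' @param dadci Marginal assimilation gain, mol m^-2 s^-1 per mol mol^-1
#'   (>= 0). Vectorized.
#' @param xi Hydraulic cost term, mol m^-2 s^-1 (>= 0). Vectorized.
#' @return Optimal stomatal conductance to CO2, mol m^-2 s^-1.
#' @examples
#' optimal_gs_analytic(0.05, 0.3377) # about 0.1073
#' @export
optimal_gs_analytic <- function(dadci, xi) {
  if (any(dadci < 0) || any(xi < 0)) stop("dadci and xi must be >= 0")
  n <- max(length(dadci), length(xi))
  dadci <- rep_len(dadci, n)
  xi <- rep_len(xi, n)
  gs <- numeric(n)
  pos <- dadci > 0
  gs[pos] <- 0.5 * dadci[pos] * (sqrt(4 * xi[pos] / dadci[pos] + 1) - 1)
  gs
}

#' Solver options for the stomatal schemes
#'
#' @param gs_tol Bracket width at which the self-consistency bisection on
#'   gs stops, mol m^-2 s^-1.
#' @param max_iter Maximum bisection iterations of the gs solve.
#' @param gs_max Upper bound on gs (CO2 basis), mol m^-2 s^-1; also the value
#'   reported when `D = 0` makes the hydraulic cost unbounded.
#' @param xi_mode Potential at which the cost terms of `xi` are evaluated:
#'   `"psi_m"` (default), the midpoint potential implied by the current gs,
#'   solved self-consistently, or `"psi_pd"`, a single evaluation at the
#'   predawn potential. The midpoint mode is the default because at the
#'   solution the closed form's optimality condition then holds at the
#'   actual operating potential, which the numerical optimizer confirms;
#'   the predawn mode overstates gs in wet soil, where the vulnerability
#'   slope at the predawn potential vanishes.
#' @param numeric_tol Golden-section tolerance of the numerical solver.
#' @return List of options.
#' @export
sox_options <- function(gs_tol = 1e-6, max_iter = 50L, gs_max = 2,
                        xi_mode = c("psi_m", "psi_pd"),
                        numeric_tol = 1e-7) {
  xi_mode <- match.arg(xi_mode)
  stopifnot(gs_tol > 0, gs_max > 0, numeric_tol > 0)
  list(gs_tol = gs_tol, max_iter = as.integer(max_iter), gs_max = gs_max,
       xi_mode = xi_mode, numeric_tol = numeric_tol)
}

# Vectorized analytical SOX over plain driver vectors. Returns a list of
# vectors. This is the hot path for fitting, sweeps and bootstrap.
.sox_predict_vec <- function(ipar, t_air, ca, patm, d, psi_pd,
                             traits, params, options = sox_options()) {
  n <- max(length(ipar), length(t_air), length(ca), length(patm),
           length(d), length(psi_pd))
  ipar <- rep_len(ipar, n); t_air <- rep_len(t_air, n)
  ca <- rep_len(ca, n); patm <- rep_len(patm, n)
  d <- rep_len(d, n); psi_pd <- rep_len(psi_pd, n)
  kin <- temperature_adjust(params, t_air)
  kin <- lapply(kin, rep_len, n)
  rp <- plant_resistance(psi_pd, traits)
  flags <- character(0)
  if (isTRUE(attr(rp, "clamped"))) flags <- c(flags, "k_floor")
  rp <- as.numeric(rp)
  d_zero <- d <= 0
  d_eff <- ifelse(d_zero, 1e-9, d) # placeholder; d = 0 rows overwritten below

  xi_at <- function(psi_eval) {
    k <- vulnerability_k(psi_eval, traits)
    dk <- vulnerability_slope(psi_eval, traits)
    2 * k / (pmax(dk, .Machine$double.xmin) * rp * 1.6 * d_eff)
  }

  # self-consistency: the optimum satisfies gs = G(dA/dci(gs), xi(psi_m(gs)))
  # with G decreasing in gs (rising ci flattens the assimilation gain and a
  # deeper midpoint potential raises the hydraulic cost), so gs - G(gs) is
  # increasing and a guarded bisection is robust even for very steep
  # vulnerability curves, where a plain fixed-point iteration can cycle
  gstep <- function(gs) {
    psi_eval <- if (options$xi_mode == "psi_m")
      pmin(psi_pd - 0.8 * gs * d_eff * rp, 0) else psi_pd
    xi <- xi_at(psi_eval)
    sol <- .a_from_gs_vec(gs, ipar, patm, ca, params, kin)
    dadci <- pmax(.dadci_vec(pmax(sol$ci, 0.01), ipar, patm, params, kin), 0)
    list(g_opt = pmin(optimal_gs_analytic(dadci, xi), options$gs_max),
         xi = xi)
  }
  lo <- numeric(n)
  hi <- rep(options$gs_max, n)
  it <- 0L
  while (it < options$max_iter && max(hi - lo) > options$gs_tol) {
    it <- it + 1L
    gs <- 0.5 * (lo + hi)
    up <- gs > gstep(gs)$g_opt
    hi[up] <- gs[up]
    lo[!up] <- gs[!up]
  }
  gs <- 0.5 * (lo + hi)
  gs[gs < options$gs_tol] <- 0 # below solver resolution: closed
  if (max(hi - lo) > options$gs_tol) flags <- c(flags, "not_converged")
  xi <- gstep(gs)$xi
  sol <- .a_from_gs_vec(gs, ipar, patm, ca, params, kin)
  a_net <- sol$a_net
  ci <- sol$ci
  if (any(d_zero)) {
    gs[d_zero] <- options$gs_max
    sol0 <- .a_from_gs_vec(gs, ipar, patm, ca, params, kin)
    ci[d_zero] <- sol0$ci[d_zero]
    a_net[d_zero] <- sol0$a_net[d_zero]
    flags <- c(flags, "d_zero_gs_max")
  }
  psi_c <- canopy_water_potential(gs, psi_pd, ifelse(d_zero, 0, d), rp)
  psi_m <- midpoint_potential(psi_pd, psi_c)
  list(gs = gs, a_net = a_net, ci = ci,
       e_trans = 1.6 * gs * ifelse(d_zero, 0, d),
       psi_c = psi_c, psi_m = psi_m,
       k = vulnerability_k(pmin(psi_m, 0), traits),
       xi = xi, rp = as.numeric(rp),
       iterations = it, flags = flags)
}

.solution <- function(v, scheme, beta = NA_real_) {
  structure(list(gs = v$gs, gs_h2o = 1.6 * v$gs, a_net = v$a_net, ci = v$ci,
                 e_trans = v$e_trans,
                 hydraulic = list(K = v$k, rp = v$rp, psi_c = v$psi_c,
                                  psi_m = v$psi_m, xi = v$xi),
                 beta = beta, scheme = scheme,
                 iterations = v$iterations, flags = v$flags),
            class = "stomatal_solution")
}

#' @export
print.stomatal_solution <- function(x, ...) {
  cat(sprintf("Stomatal solution [%s]\n", x$scheme))
  cat(sprintf("  gs      %10.5f mol m-2 s-1 (CO2)   gs_h2o %10.5f\n",
              x$gs[1], x$gs_h2o[1]))
  cat(sprintf("  A_net   %10.3f umol m-2 s-1        ci     %10.3f Pa\n",
              x$a_net[1] * 1e6, x$ci[1]))
  cat(sprintf("  E       %10.5f mol H2O m-2 s-1\n", x$e_trans[1]))
  cat(sprintf("  psi_c   %10.3f MPa   psi_m %8.3f MPa   K %6.4f\n",
              x$hydraulic$psi_c[1], x$hydraulic$psi_m[1], x$hydraulic$K[1]))
  if (!is.na(x$beta[1])) cat(sprintf("  beta    %10.4f\n", x$beta[1]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Analytical SOX stomatal solve
#'
#' Computes the optimal stomatal conductance by the closed-form SOX solution:
#' the dynamic plant resistance is set from the predawn potential, the
#' hydraulic cost `xi` is evaluated (by default at the midpoint potential
#' implied by the current gs; optionally at the predawn potential), and the
#' assimilation gain `dA/dci` at the internal CO2 of the coupled `A(gs)`
#' solution. The self-consistent gs -- the closed form evaluated at its own
#' operating point -- is found by a monotone bisection to `gs_tol`.
#'
#' At `D = 0` the cost term is unbounded and gs is reported at `gs_max` with
#' a flag.
#'
#' @param env A [leaf_env()] object.
#' @param traits A [hydraulic_traits()] object.
#' @param params A [photo_params()] object.
#' @param options Solver options from [sox_options()].
#' @return A `"stomatal_solution"`: gs (CO2 and H2O basis), net
#'   assimilation, ci, transpiration, hydraulic diagnostics (K, rp, psi_c,
#'   psi_m, xi), iteration count and flags.
#' @examples
#' tr <- hydraulic_traits(-2, 3, rp_min = 1, rp_units = "per_mmol")
#' env <- leaf_env(600e-6, 25, 36, d = 0.5, psi_pd = -0.5, d_units = "kPa")
#' sox_solve(env, tr, photo_params())
#' @export
sox_solve <- function(env, traits, params = photo_params(),
                      options = sox_options()) {
  v <- .sox_predict_vec(env$ipar, env$t_air, env$ca, env$patm, env$d,
                        env$psi_pd, traits, params, options)
  .solution(v, "sox_analytic")
}

#' Numerical SOX stomatal solve
#'
#' The numerical oracle for [sox_solve()]: maximizes the SOX objective
#' `F(gs) = A(gs) * K(psi_m(gs))` directly by golden-section search on
#' `gs` in `[0, gs_max]`, where `A(gs)` comes from the coupled
#' supply--demand solution and `psi_m(gs)` from the steady-state canopy
#' drawdown. No linearization is involved, so this arbitrates the quality of
#' the closed-form approximation.
#'
#' @inheritParams sox_solve
#' @return A `"stomatal_solution"` with `scheme = "sox_numeric"`.
#' @export
sox_solve_numeric <- function(env, traits, params = photo_params(),
                              options = sox_options()) {
  kin <- temperature_adjust(params, env$t_air)
  rp <- plant_resistance(env$psi_pd, traits)
  objective <- function(gs) {
    sol <- .a_from_gs_vec(gs, env$ipar, env$patm, env$ca, params, kin)
    psi_c <- env$psi_pd - 1.6 * gs * env$d * rp
    psi_m <- pmin((env$psi_pd + psi_c) / 2, 0)
    f <- sol$a_net * vulnerability_k(psi_m, traits)
    if (!is.finite(f)) stop("non-finite SOX objective at gs = ", gs)
    f
  }
  opt <- stats::optimize(objective, c(0, options$gs_max), maximum = TRUE,
                         tol = options$numeric_tol)
  gs <- opt$maximum
  # the golden-section bracket never quite reaches the boundary; snap to 0
  # when the objective there is at least as good
  if (gs < 1e-5 && objective(0) >= opt$objective) gs <- 0
  sol <- .a_from_gs_vec(gs, env$ipar, env$patm, env$ca, params, kin)
  # when no gs achieves positive net assimilation (e.g. darkness) the
  # product objective is maximized by shedding conductance, which is not a
  # stomatal optimum: closure is
  if (sol$a_net <= 0) {
    gs <- 0
    sol <- .a_from_gs_vec(gs, env$ipar, env$patm, env$ca, params, kin)
  }
  psi_c <- canopy_water_potential(gs, env$psi_pd, env$d, rp)
  psi_m <- midpoint_potential(env$psi_pd, psi_c)
  v <- list(gs = gs, a_net = sol$a_net, ci = sol$ci,
            e_trans = 1.6 * gs * env$d, psi_c = psi_c, psi_m = psi_m,
            k = vulnerability_k(pmin(psi_m, 0), traits),
            xi = NA_real_, rp = as.numeric(rp), iterations = NA_integer_,
            flags = character(0))
  .solution(v, "sox_numeric")
}

#' Predict SOX stomatal conductance for a table of records
#'
#' Vectorized analytical SOX over a data frame of driver records (columns
#' `ipar`, `t_air`, `ca`, `patm`, `d`, `psi_pd`, all in internal units as in
#' [leaf_env()]). Used by the fitting, sweep and bootstrap routines.
#'
#' @param records Data frame of drivers.
#' @param traits A [hydraulic_traits()] object.
#' @param params A [photo_params()] object.
#' @param options Solver options from [sox_options()].
#' @return Numeric vector of gs (CO2 basis), one per row.
#' @export
sox_predict_gs <- function(records, traits, params = photo_params(),
                           options = sox_options()) {
  need <- c("ipar", "t_air", "ca", "patm", "d", "psi_pd")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lacks columns: ", paste(miss, collapse = ", "))
  .sox_predict_vec(records$ipar, records$t_air, records$ca, records$patm,
                   records$d, records$psi_pd, traits, params, options)$gs
}

# Trait-independent part of the SOX solve, precomputed for fitting.
#
# The coupled photosynthesis solution -- and hence the marginal gain
# dA/dci as a function of gs -- does not depend on the hydraulic traits,
# so for repeated evaluations over trait candidates (least-squares fitting)
# it is tabulated once per record on a common gs grid and interpolated.
# The optimum then solves gs = G(dadci(gs), xi(psi_m(gs))) by a vectorized
# bisection of pure arithmetic.
.sox_fit_engine <- function(data, params, options, grid_n = 40L) {
  n <- nrow(data)
  kin <- temperature_adjust(params, data$t_air)
  kin <- lapply(kin, rep_len, n)
  gs_grid <- c(0, 10^seq(-4, log10(options$gs_max), length.out = grid_n))
  m <- length(gs_grid)
  dadci_tab <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    sol <- .a_from_gs_vec(rep(gs_grid[j], n), data$ipar, data$patm,
                          data$ca, params, kin)
    dadci_tab[, j] <- pmax(.dadci_vec(pmax(sol$ci, 0.01), data$ipar,
                                      data$patm, params, kin), 0)
  }
  rows <- seq_len(n)
  interp <- function(gs) {
    idx <- pmin(pmax(findInterval(gs, gs_grid), 1L), m - 1L)
    g0 <- gs_grid[idx]; g1 <- gs_grid[idx + 1L]
    w <- pmin(pmax((gs - g0) / (g1 - g0), 0), 1)
    dadci_tab[cbind(rows, idx)] * (1 - w) +
      dadci_tab[cbind(rows, idx + 1L)] * w
  }
  d <- pmax(data$d, 1e-9)
  psi_pd <- pmin(data$psi_pd, 0)
  function(psi50, shape_a, rp_min) {
    rp <- rp_min / pmax(1 / (1 + (psi_pd / psi50)^shape_a), .K_FLOOR)
    lo <- numeric(n)
    hi <- rep(options$gs_max, n)
    for (i in 1:50) {
      gs <- 0.5 * (lo + hi)
      psi_m <- psi_pd - 0.8 * gs * d * rp
      x <- (psi_m / psi50)^shape_a
      k <- 1 / (1 + x)
      dk <- ifelse(psi_m < 0, (shape_a / abs(psi_m)) * x / (1 + x)^2, 0)
      xi <- 2 * k / (pmax(dk, .Machine$double.xmin) * rp * 1.6 * d)
      g_opt <- pmin(optimal_gs_analytic(interp(gs), xi), options$gs_max)
      up <- gs > g_opt
      hi[up] <- gs[up]
      lo[!up] <- gs[!up]
    }
    0.5 * (lo + hi)
  }
}

#' Analytic-versus-numeric driver sweep
#'
#' Sweeps one driver over a range while the others stay at their reference
#' values, computing gs by both the closed-form and the numerically
#' optimized SOX. The default reference state is D = 0.5 kPa,
#' psi_pd = -0.5 MPa, Ipar = 600e-6 mol m^-2 s^-1, ca = 36 Pa at standard
#' pressure and 25 C.
#'
#' @param var One of `"d"`, `"psi_pd"`, `"ipar"`, `"ca"`.
#' @param range Length-2 numeric, sweep limits in internal units
#'   (d in mol mol^-1, ipar in mol m^-2 s^-1, ca in Pa, psi_pd in MPa).
#' @param n Number of sweep points.
#' @param reference Named list of reference drivers (internal units).
#' @param traits,params,options As in [sox_solve()].
#' @return Data frame with columns `var`, `value`, `gs_analytic`,
#'   `gs_numeric`.
#' @export
sox_sweep <- function(var = c("d", "psi_pd", "ipar", "ca"), range, n = 50,
                      reference = list(ipar = 600e-6, t_air = 25, ca = 36,
                                       patm = 101325, d = 0.5 * 1000 / 101325,
                                       psi_pd = -0.5),
                      traits = hydraulic_traits(-2, 3, rp_min = 1,
                                                rp_units = "per_mmol"),
                      params = photo_params(),
                      options = sox_options()) {
  var <- match.arg(var)
  stopifnot(length(range) == 2, n >= 2)
  vals <- seq(range[1], range[2], length.out = n)
  drv <- reference
  drv[[var]] <- vals
  ana <- .sox_predict_vec(drv$ipar, drv$t_air, drv$ca, drv$patm, drv$d,
                          drv$psi_pd, traits, params, options)$gs
  num <- vapply(seq_len(n), function(i) {
    e <- lapply(drv, function(x) rep_len(x, n)[i])
    env <- leaf_env(e$ipar, e$t_air, e$ca, e$patm, e$d, e$psi_pd)
    sox_solve_numeric(env, traits, params, options)$gs
  }, numeric(1))
  data.frame(var = var, value = vals, gs_analytic = ana, gs_numeric = num)
}
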