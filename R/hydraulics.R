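#' Plant hydraulic traits
#'
#' Container for the three plant-side parameters of the SOX model: the water
#' potential at 50% loss of xylem conductance (`psi50`, MPa, strictly
#' negative), the shape (steepness) of the vulnerability curve (`shape_a`,
#' dimensionless, strictly positive) and the minimum whole-plant hydraulic
#' resistance per unit leaf area (`rp_min`, mol^-1 m^2 s MPa on the water
#' basis, strictly positive).
#'
#' When `shape_a` is not supplied it can be derived from the potential at 88%
#' conductance loss via [shape_from_p50_p88()]. Resistances quoted per mmol
#' (the unit often used for branch-level measurements) are accepted through
#' `rp_units = "per_mmol"` and converted once, here: 1 mmol^-1 m^2 s MPa =
#' 1000 mol^-1 m^2 s MPa. All downstream code uses the mol basis exclusively.
#'
#' @param psi50 Water potential at 50% conductance loss, MPa (< 0).
#' @param shape_a Vulnerability-curve steepness (> 0). Omit to derive from
#'   `psi88`.
#' @param psi88 Water potential at 88% conductance loss, MPa (< `psi50`);
#'   used only when `shape_a` is missing.
#' @param rp_min Minimum plant hydraulic resistance per leaf area (> 0).
#' @param rp_units Unit of `rp_min`: `"per_mol"` (default, mol^-1 m^2 s MPa)
#'   or `"per_mmol"` (mmol^-1 m^2 s MPa, multiplied by 1000 on input).
#' @return An object of class `"hydraulic_traits"`: a list with elements
#'   `psi50`, `shape_a`, `rp_min` (mol basis).
#' @examples
#' tr <- hydraulic_traits(psi50 = -2, shape_a = 3, rp_min = 1, rp_units = "per_mmol")
#' tr$rp_min # 1000 mol^-1 m^2 s MPa
#' @export
hydraulic_traits <- function(psi50, shape_a = NULL, psi88 = NULL, rp_min,
                             rp_units = c("per_mol", "per_mmol")) {
  rp_units <- match.arg(rp_units)
  stopifnot(is.numeric(psi50), length(psi50) == 1L, is.finite(psi50),
            is.numeric(rp_min), length(rp_min) == 1L, is.finite(rp_min))
  if (psi50 >= 0) stop("psi50 must be strictly negative (MPa)")
  if (rp_min <= 0) stop("rp_min must be strictly positive")
  if (is.null(shape_a)) {
    if (is.null(psi88)) stop("supply either shape_a or psi88")
    shape_a <- shape_from_p50_p88(psi50, psi88)
  }
  stopifnot(is.numeric(shape_a), length(shape_a) == 1L, is.finite(shape_a))
  if (shape_a <= 0) stop("shape_a must be strictly positive")
  if (rp_units == "per_mmol") rp_min <- rp_min * 1000
  structure(list(psi50 = psi50, shape_a = shape_a, rp_min = rp_min),
            class = "hydraulic_traits")
}

#' @export
print.hydraulic_traits <- function(x, ...) {
  cat("Hydraulic traits:\n")
  cat(sprintf("  psi50   %8.3f MPa\n", x$psi50))
  cat(sprintf("  shape a %8.3f\n", x$shape_a))
  cat(sprintf("  rp_min  %8.3g mol^-1 m2 s MPa\n", x$rp_min))
  invisible(x)
}

.check_psi <- function(psi, allow_zero = TRUE) {
  if (any(!is.finite(psi))) stop("water potential must be finite")
  if (allow_zero) {
    if (any(psi > 0)) stop("water potential must be <= 0 MPa (sign convention)")
  } else if (any(psi >= 0)) stop("water potential must be < 0 MPa")
  invisible(psi)
}

#' Xylem vulnerability curve
#'
#' Normalized xylem hydraulic conductance as a sigmoidal function of water
#' potential, `K(psi) = 1 / (1 + (psi/psi50)^a)`. `K` is 1 at `psi = 0`,
#' exactly 0.5 at `psi = psi50`, and declines monotonically as the potential
#' becomes more negative.
#'
#' @param psi Water potential, MPa (<= 0). Vectorized.
#' @param traits A [hydraulic_traits()] object.
#' @return Normalized conductance in `[0, 1]`.
#' @examples
#' tr <- hydraulic_traits(-2, 3, rp_min = 1000)
#' vulnerability_k(c(0, -2, -4), tr) # 1, 0.5, 1/9
#' @export
vulnerability_k <- function(psi, traits) {
  .check_psi(psi)
  1 / (1 + (psi / traits$psi50)^traits$shape_a)
}

#' Slope of the vulnerability curve
#'
#' Derivative of [vulnerability_k()] with respect to water potential,
#' `dK/dpsi`, which is >= 0 for psi <= 0 (conductance recovers toward wetter
#' potentials). The analytic form is, with `x = (psi/psi50)^a`,
#' `slope = (a/|psi|) * x / (1 + x)^2`. A central-difference estimate
#' (step 1e-4 MPa) is retained because applications of the model commonly
#' evaluate this derivative numerically.
#'
#' @param psi Water potential, MPa (< 0; at `psi = 0` the one-sided limit,
#'   0 for `a > 1`, is returned). Vectorized.
#' @param traits A [hydraulic_traits()] object.
#' @param method `"analytic"` (default) or `"central_difference"`.
#' @return Slope in MPa^-1.
#' @examples
#' tr <- hydraulic_traits(-2, 3, rp_min = 1000)
#' vulnerability_slope(-2, tr) # a / (4 |psi50|) = 0.375
#' @export
vulnerability_slope <- function(psi, traits,
                                method = c("analytic", "central_difference")) {
  method <- match.arg(method)
  .check_psi(psi)
  if (method == "analytic") {
    a <- traits$shape_a
    out <- numeric(length(psi))
    nz <- psi < 0
    x <- (psi[nz] / traits$psi50)^a
    out[nz] <- (a / abs(psi[nz])) * x / (1 + x)^2
    # psi == 0: limit is 0 for a > 1, a/|psi50| for a == 1, Inf for a < 1
    if (any(!nz)) {
      out[!nz] <- if (a > 1) 0 else if (a == 1) 1 / abs(traits$psi50) else Inf
    }
    out
  } else {
    h <- 1e-4
    lo <- psi - h
    hi <- pmin(psi + h, 0)
    (vulnerability_k(hi, traits) - vulnerability_k(lo, traits)) / (hi - lo)
  }
}

#' Vulnerability shape parameter from P50 and P88
#'
#' Inverts the two-point definition of the curve: returns the steepness `a`
#' such that the conductance is exactly 0.12 at `psi88` (and, by
#' construction, 0.5 at `psi50`): `a = log(0.88/0.12) / log(psi88/psi50)`.
#'
#' @param psi50 Water potential at 50% conductance loss, MPa (< 0).
#' @param psi88 Water potential at 88% conductance loss, MPa (< `psi50`).
#' @return The shape parameter `a` (> 0).
#' @examples
#' shape_from_p50_p88(-2, -4) # about 2.874
#' @export
shape_from_p50_p88 <- function(psi50, psi88) {
  stopifnot(is.finite(psi50), is.finite(psi88))
  if (psi50 >= 0) stop("psi50 must be negative")
  if (psi88 >= psi50) stop("psi88 must be more negative than psi50")
  log(0.88 / 0.12) / log(psi88 / psi50)
}

# K floor used wherever K divides something (extreme drought guard)
.K_FLOOR <- 1e-6

#' Dynamic whole-plant hydraulic resistance
#'
#' The plant resistance rises as the xylem embolizes:
#' `rp = rp_min / K(psi_pd)`. `K` is floored at 1e-6 before division so the
#' resistance stays finite at extreme drought; when the floor engages the
#' result carries attribute `clamped = TRUE`.
#'
#' @param psi_pd Predawn water potential, MPa (<= 0). Vectorized.
#' @param traits A [hydraulic_traits()] object.
#' @return Resistance in mol^-1 m^2 s MPa, with attribute `clamped`.
#' @examples
#' tr <- hydraulic_traits(-2, 3, rp_min = 500)
#' plant_resistance(-2, tr) # 1000
#' @export
plant_resistance <- function(psi_pd, traits) {
  .check_psi(psi_pd)
  k <- vulnerability_k(psi_pd, traits)
  clamped <- k < .K_FLOOR
  rp <- traits$rp_min / pmax(k, .K_FLOOR)
  attr(rp, "clamped") <- any(clamped)
  rp
}

#' Canopy water potential at steady state
#'
#' Steady-state supply: the canopy potential is drawn down from the predawn
#' (soil) potential by the transpiration stream through the plant resistance,
#' `psi_c = psi_pd - 1.6 gs D rp`, with `E = 1.6 gs D` (gs is the CO2-basis
#' stomatal conductance; the 1.6 converts to water vapour). Gravity and
#' capacitance are neglected.
#'
#' @param gs Stomatal conductance to CO2, mol m^-2 s^-1 (>= 0). Vectorized.
#' @param psi_pd Predawn water potential, MPa.
#' @param d Leaf-to-air vapour pressure difference, mol mol^-1 (>= 0).
#' @param rp Plant hydraulic resistance, mol^-1 m^2 s MPa.
#' @return Canopy water potential, MPa (<= `psi_pd`).
#' @export
canopy_water_potential <- function(gs, psi_pd, d, rp) {
  if (any(gs < 0)) stop("gs must be >= 0")
  if (any(d < 0)) stop("D must be >= 0")
  psi_pd - 1.6 * gs * d * rp
}

#' Midpoint water potential
#'
#' Mean of the predawn and canopy water potentials, the single potential at
#' which the vulnerability curve is evaluated to represent the gradual
#' decline in potential along the soil-to-canopy pathway.
#'
#' @param psi_pd Predawn water potential, MPa.
#' @param psi_c Canopy water potential, MPa (<= `psi_pd`).
#' @return `(psi_pd + psi_c) / 2`, MPa.
#' @export
midpoint_potential <- function(psi_pd, psi_c) {
  if (any(psi_c > psi_pd + 1e-12)) stop("psi_c must not exceed psi_pd")
  (psi_pd + psi_c) / 2
}

#' SOX hydraulic cost term
#'
#' The cost of stomatal opening in terms of prospective loss of xylem
#' conductance:
#' `xi = 2 / ((1/K) (dK/dpsi) * rp * 1.6 D)`
#' with `K` and its slope evaluated at `psi_eval` and the plant resistance at
#' the predawn potential. Low `xi` means high hydraulic cost (drought: low
#' predawn potential and/or high vapour pressure difference). `xi` carries
#' conductance units (mol m^-2 s^-1) and is strictly positive for `D > 0`.
#'
#' @param psi_eval Potential at which the conductance and its slope are
#'   evaluated, MPa (<= 0). The default choice in [sox_solve()] is the
#'   predawn potential.
#' @param psi_pd Predawn water potential, MPa (<= 0), sets `rp`.
#' @param d Leaf-to-air vapour pressure difference, mol mol^-1 (> 0).
#' @param traits A [hydraulic_traits()] object.
#' @return `xi`, mol m^-2 s^-1.
#' @examples
#' tr <- hydraulic_traits(-2, 3, rp_min = 500)
#' hydraulic_cost_xi(-2, -2, d = 0.004935, tr) # about 0.3377
#' @export
hydraulic_cost_xi <- function(psi_eval, psi_pd, d, traits) {
  .check_psi(psi_eval)
  .check_psi(psi_pd)
  if (any(d <= 0)) stop("xi is undefined at D = 0; handle the D -> 0 limit upstream")
  k <- vulnerability_k(psi_eval, traits)
  dk <- vulnerability_slope(psi_eval, traits)
  rp <- as.numeric(plant_resistance(psi_pd, traits))
  2 * k / (pmax(dk, .Machine$double.xmin) * rp * 1.6 * d)
}
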