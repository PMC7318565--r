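---
title: "Stomatal optimization on xylem hydraulics: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stomatal optimization on xylem hydraulics: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxopt)
```

## The model

SOX (stomatal optimization based on xylem hydraulics) assumes that stomata
behave so as to maximize the product of leaf net photosynthesis and the
plant's normalized xylem hydraulic conductance,

$$\max_{g_s} \; A[c_i(g_s)] \cdot K[\Psi_m(g_s)],$$

where $A$ is net CO$_2$ assimilation (mol m$^{-2}$ s$^{-1}$), $c_i$ the
internal CO$_2$ partial pressure (Pa), $g_s$ the stomatal conductance to
CO$_2$ (mol m$^{-2}$ s$^{-1}$), and $K \in [0,1]$ the xylem conductance
normalized by its maximum. $K$ follows the sigmoidal vulnerability curve

$$K(\Psi) = \frac{1}{1 + (\Psi/\Psi_{50})^a},$$

with $\Psi_{50}$ the potential at 50% conductance loss and $a$ the
steepness. $K$ is evaluated at the midpoint potential
$\Psi_m = (\Psi_{pd} + \Psi_c)/2$ between the predawn (soil) and canopy
potentials, standing in for the gradual decline of potential along the
soil-to-canopy pathway. The canopy potential follows the steady-state
supply line $\Psi_c = \Psi_{pd} - 1.6\, g_s D\, r_p$, with $D$ the
leaf-to-air vapour pressure difference (mole fraction) and $r_p$ the
whole-plant hydraulic resistance, which itself degrades with embolism:
$r_p = r_{p,\min}/K(\Psi_{pd})$.

The first-order condition admits a closed form,

$$g_s = \tfrac{1}{2}\,\frac{\partial A}{\partial c_i}
  \left(\sqrt{\frac{4\xi}{\partial A/\partial c_i} + 1} - 1\right),
\qquad
\xi = \frac{2}{\frac{1}{K}\frac{\partial K}{\partial \Psi_m}\; r_p\, 1.6 D},$$

where $\partial A/\partial c_i$ (mole-fraction basis) is the marginal
carbon benefit of opening stomata and $\xi$ (conductance units) the
marginal hydraulic cost: low $\xi$ -- dry soil, high $D$, steep point on
the vulnerability curve -- closes stomata. The whole plant side of the
model is three parameters: $\Psi_{50}$, $a$, $r_{p,\min}$.

Photosynthesis is the Collatz C3/C4 scheme with JULES-style smoothed
colimitation of Rubisco-, light- and export-limited (PEP-limited for C4)
rates: two nested quadratics with coefficients 0.83 and 0.93, Q10
temperature responses with sigmoidal high/low temperature inhibition of
$V_{c,\max}$, $\Gamma = O_a / (2\tau)$, and dark respiration as a fixed
fraction of $V_{c,\max}$. The baseline the optimization replaces is the
empirical drought-factor scheme: a piecewise-linear $\beta(\theta)$ ramp
between the wilting and critical soil moistures (the Brooks-Corey moisture
at $-1.5$ and $-0.033$ MPa), multiplying assimilation, with internal CO$_2$
prescribed by the Jacobs closure
$c_i = \Gamma + f_0 (1 - D/D_{crit}) (c_a - \Gamma)$. We include the
additive $\Gamma$ of the original closure; some restatements drop it
typographically.

## Where the cost terms are evaluated

The closed form needs $K$ and $\partial K/\partial\Psi_m$ at a known
potential. Two modes are provided (`sox_options(xi_mode = ...)`):

* `"psi_m"` (default): the cost terms are evaluated at the midpoint
  potential implied by the candidate $g_s$ itself, and the resulting
  self-consistency equation $g_s = G(g_s)$ is solved. At the solution the
  first-order optimality condition holds *at the actual operating point*:
  because the exact coupled solution satisfies
  $A'(g_s)/A(g_s) = s/(g_s(g_s+s))$ with $s$ the local
  $\partial A/\partial c_i$, the converged closed form reproduces the
  numerical argmax of $A \cdot K$ to solver tolerance (the acceptance
  sweeps measure Pearson $r > 0.999$ per driver).
* `"psi_pd"`: a single evaluation at the predawn potential, consistent
  with the $r_p$ update. This mode overstates $g_s$ in wet soil -- the
  vulnerability slope at $\Psi_{pd} \to 0^-$ vanishes, sending the
  apparent cost to zero -- and is retained for comparison rather than as
  the default.

A consequence of full convergence is that the analytic and numerical
solutions carry no systematic directional differences; one-shot
linearizations of the same closed form (evaluating the derivatives once,
from secants over fixed intervals) under-predict at low $D$ and
over-predict at low $c_a$. We do not reproduce that behaviour, since the
iterated scheme strictly dominates it in accuracy.

## Numerical choices

* **Coupled leaf solve.** Supply $A = g_s (c_a - c_i)/P_{atm}$ equals
  biochemical demand $A(c_i)$ at a unique $c_i$ (demand minus supply is
  monotone increasing), found by vectorized bisection (60 halvings; final
  interval $\ll 10^{-10}$ Pa). At $g_s = 0$ the solution is the net
  compensation point; in darkness no compensation point exists and the
  result is flagged `no_compensation` with $A = 0$.
* **Derivatives.** $\partial A/\partial c_i$ is a central difference with
  step $\max(0.01\ \mathrm{Pa}, 10^{-3} c_i)$, converted to the
  mole-fraction basis by multiplying by $P_{atm}$ (this is what makes
  $\xi/(\partial A/\partial c_i)$ dimensionless).
  $\partial K/\partial\Psi$ uses the exact analytic form by default; a
  central difference (step $10^{-4}$ MPa) is retained. The fixed step is
  truncation-limited near $\Psi = 0$ (relative error
  $\sim a^2 h^2/\Psi^2$), which the tests acknowledge explicitly.
* **The gs solve.** $g_s - G(g_s)$ is increasing in $g_s$ (a higher
  $c_i$ flattens the assimilation gain; a deeper $\Psi_m$ raises the
  cost), so the self-consistent optimum is found by bisection on
  $[0, g_{s,\max}]$ ($g_{s,\max} = 2$ mol m$^{-2}$ s$^{-1}$ CO$_2$ basis)
  to $10^{-6}$; conductances below the tolerance are reported as closed.
  Bisection replaces a plain fixed-point iteration, which can cycle for
  very steep vulnerability curves ($a \gtrsim 8$).
* **Numerical oracle.** `sox_solve_numeric()` maximizes $A \cdot K$
  directly by golden-section search (tolerance $10^{-7}$), cross-checked
  against a dense-grid argmax in the tests. When no conductance achieves
  positive net assimilation (darkness), the product objective is negative
  and its maximizer degenerately sheds conductance; the solver returns
  closure instead.
* **Guards.** $K$ is floored at $10^{-6}$ when used as a divisor
  (flagged `k_floor`); $D = 0$ makes $\xi$ unbounded and is reported as
  $g_s = g_{s,\max}$ with a flag; potentials must be $\le 0$ MPa (inputs
  above zero are rejected, not mirrored).
* **Fitting engine.** Trait calibration repeatedly evaluates SOX under
  candidate traits. The photosynthesis side -- $\partial A/\partial c_i$
  as a function of $g_s$ -- does not depend on the traits, so it is
  tabulated once per record on a 41-point logarithmic $g_s$ grid and
  linearly interpolated inside the optimizer (relative error below ~2%,
  and $\ll 1\%$ at the optimum); the reported fit statistics are
  recomputed with the full solver at the fitted parameters. The bootstrap
  uses the same engine, making 1000 replicates cheap.
* **Optimization.** Bounded least squares uses `stats::optim`
  (L-BFGS-B) from multiple seeded starts drawn uniformly inside the
  bounds (default 8; the RSS surface develops plateaus when the drought
  signal is weak). $r_{p,\min}$ is fitted on a log10 scale. The least
  squares AIC is $n \ln(\mathrm{RSS}/n) + 2k$ without small-sample
  correction; only differences between models on the same data are
  interpreted.

## Units

Internal units are fixed: mol, m$^2$, s, MPa for potentials, Pa for CO$_2$
pressures, mole fraction for $D$; conversions (kPa, µmol, mmol-basis
resistances, H$_2$O-basis conductances) happen only in readers/writers and
constructors. Published resistance values appear in two conventions
(mmol$^{-1}$ and mol$^{-1}$ m$^2$ s MPa, a factor $10^3$ apart, sometimes
typeset ambiguously); this package treats literature trait-table values as
mmol-basis and stores mol-basis, with the conversion explicit at I/O.

## The synthetic generators

The generators emulate the statistical structure of leaf gas-exchange
campaigns so that fitting, model selection and the bootstrap are testable
end to end:

* **Trait tables**: truncated-normal draws around literature means; the
  default prior is the broadleaf evergreen tropical tree group,
  $\Psi_{50} = -1.9\ (\pm 1.3)$ MPa, $a = 4.4\ (\pm 2.1)$,
  $r_{p,\min} = 2.2\ (\pm 3.4)$ mmol$^{-1}$ m$^2$ s MPa. With the upper
  truncation just below zero, roughly 10% of the $\Psi_{50}$ prior mass is
  cut, so the generated mean sits ~0.2 MPa below the prior mean; tests
  compare against the closed-form truncated-normal mean.
* **Campaigns**: drivers drawn independently; $\Psi_{pd}$ from a 70/30
  mixture of uniform draws over $[-1.5, -0.05]$ and $[-7, -1.5]$ MPa,
  giving a drought tail down to $-7$ MPa as in field campaigns spanning
  well-watered to extreme drought. The observation noise default is
  multiplicative Gaussian with $\sigma = 0.1$ -- campaign repeatability is
  rarely reported, and a scale-free residual on $g_s$ is the conservative
  choice. True conductances come from either scheme (`truth = "sox"` or
  `"beta"`).
* **Drydown forcing**: sinusoidal seasonal cycles with day-to-day noise,
  rainfall as Bernoulli occurrence times exponential depth.

What passing these tests does *not* show: real campaigns have correlated
drivers (hot days are dry days), instrument-specific error structure,
species mixtures within groups, and leaf temperatures that depart from air
temperature. Parameter recovery here demonstrates the estimator is
consistent under the model, not that field identifiability is as clean.

## The drydown simulator

A deliberately minimal single-layer bucket (default depth 1 m, fixed leaf
area index 2, daylight 12 h, residual moisture 0.01 m$^3$ m$^{-3}$, no
drainage beyond saturation clipping) driven by daily forcing. Its purpose
is the qualitative contrast between schemes: the optimization keeps
exchanging gas below the ramp's wilting cutoff, so under rain-free forcing
it ends with drier soil and a weaker dependence of light-use efficiency on
moisture than the drought-factor baseline. It is not a site water-balance
model: canopy radiative transfer, soil evaporation, drainage and runoff
are all absent.

## Problem sizes used by the test suite

The acceptance checks run four 50-point driver sweeps for the
analytic-numeric comparison; parameter recovery uses campaigns of
$n = 300$ records with $\sigma = 0.1$ noise over 20 seeds, with 3 seeded
multistarts per fit (the surface is well-behaved at this sample size; the
function default stays at 8); the drydown contrast uses 90 rain-free days;
bootstrap stability is checked at 1000 replicates.

## Known limitations

* One hydraulic compartment: no segmentation into root/stem/leaf, no
  capacitance, no gravitational potential, no refilling dynamics.
* Leaf temperature equals air temperature (no energy balance).
* The midpoint-potential convention is a first-order stand-in for the
  continuous potential profile.
* Under the self-consistent solution, a large $r_{p,\min}$ depresses the
  midpoint potential already in wet soil, which compresses the *relative*
  wet-to-dry response even though the conductance curve lies uniformly
  lower; orderings of drought sensitivity between trait sets are therefore
  asserted on the curves at fixed drought levels, not on ratios.
* Ecosystem-scale conclusions (annual productivity, flux-tower skill)
  require a host land-surface model and are out of scope here.
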