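---
title: "Models and methods in leafgas"
author: "leafgas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in leafgas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgas)
```

## The models

### Photosynthetic demand

Net CO2 assimilation of a C3 leaf follows the Farquhar-von Caemmerer-Berry
(FvCB) scheme: the gross rate is limited either by Rubisco carboxylation,

$$A_c = \frac{V_{cmax}\,(C - \Gamma^*)}{C + K_m}, \qquad
  K_m = K_c\left(1 + \frac{O_i}{K_o}\right),$$

or by RuBP regeneration driven by electron transport,

$$A_j = \frac{J}{4}\,\frac{C - \Gamma^*}{C + 2\Gamma^*},$$

and the net rate is $A_n = \min(A_c, A_j) - R_d$. Here $C$ is the CO2 mole
fraction at the carboxylation site: the intercellular value $C_i$ when no
mesophyll conductance is given, or the chloroplastic value
$C_c = C_i - A_n/g_m$ when it is. `aci_demand()` evaluates this demand
function; `fit_aci()` estimates $V_{cmax}$, $J_{max}$ and $R_d$ from
measured curves.

Two numerical choices matter:

* **Hyperbolic minimum.** Fitting `min(Ac, Aj)` directly creates a
  derivative discontinuity at the limitation transition. We instead use the
  smaller root of $\theta A_m^2 - (A_c + A_j) A_m + A_c A_j = 0$ with shape
  $\theta = 0.9999$ (`hyperbolic_min()`). At equal rates of 10 the smoothed
  minimum is 9.9010; away from the transition it is numerically
  indistinguishable from the strict minimum. The smoothing also means the
  mesophyll-conductance fixed point $\{A_n = f(C_c),\ C_c = C_i - A_n/g_m\}$,
  which each limitation satisfies exactly through its analytic quadratic
  solution, closes for the combined rate only to within the smoothing
  deficit (about $10^{-3}$ at the default $\theta$).

* **Electron-transport light response.** $J$ is the smaller root of the
  non-rectangular hyperbola
  $\theta_J J^2 - (\alpha Q + J_{max}) J + \alpha Q J_{max} = 0$ with
  quantum yield $\alpha = 0.24$ mol mol$^{-1}$ and curvature
  $\theta_J = 0.85$.

Temperature sensitivity uses a plain Arrhenius form for $K_c$, $K_o$,
$\Gamma^*$ and $R_d$ and a peaked (deactivating) Arrhenius form for
$V_{cmax}$ and $J_{max}$; all constants are listed by `fvcb_defaults()` and
can be overridden in `biochem_params()`. Every response returns its
reference value exactly at 25 degC. The default kinetic constants
($\Gamma^*_{25} = 42.75$, $K_{c,25} = 404.9$ umol mol$^{-1}$,
$K_{o,25} = 278.4$, $O_i = 210$ mmol mol$^{-1}$) are the conventional C3
parameterization; they are inputs, never fitted.

A C4 demand model (`aci_c4()`) combines an enzyme-limited rate (PEP
carboxylation feeding the bundle sheath, with leakage through the bundle
sheath conductance) and a light-limited rate as quadratics of the same
supply/demand form, taking mesophyll CO2 equal to $C_i$. It is provided for
simulation only; no C4 fitting is offered.

### Fitting A-Ci curves

`fit_aci()` minimises $\sum (A_{n,obs} - A_{n,model})^2$ over
$(V_{cmax}, J_{max}, R_d \ge 0)$ with bounded Levenberg-Marquardt
(minpack.lm). Starting values are inverted from the data: the
Rubisco-limited form on the lowest-Ci points, the RuBP-limited form (then
the light response) on the highest-Ci points, and an initial $R_d$ taken
from the magnitude of negative assimilation near the compensation point
when present. The optimisation is repeated over a grid of $\{0.5, 1, 2\}$
scalings of the three starting values and stops once at least three starts
have converged and the last two brought no improvement beyond $10^{-10}$ in
SSR; the best fit wins. Without this multi-start the fit can lock onto a
local optimum in which $J_{max}$ runs away and the Rubisco limb covers the
whole curve.

By default estimates are normalised to 25 degC using each observation's
leaf temperature (`tcorrect = TRUE`); with `tcorrect = FALSE` they apply at
measurement temperature (the Michaelis constants and $\Gamma^*$ still track
leaf temperature). Standard errors come from the linearised covariance of
the least-squares fit, confidence intervals are t-based on the residual
degrees of freedom, and $R^2$ is the squared Pearson correlation of
measured versus fitted. The transition $C_i$ (where $A_c = A_j$) is located
by root finding; the user never supplies it, but `citransition` can fix it,
in which case observations below the transition fit the Rubisco limb and
the rest the RuBP limb with a shared $R_d$. If at the estimates no
observation lies on one of the limbs, the corresponding parameter is
flagged as unconstrained rather than silently reported. Observations are
unweighted; $R_d$ is box-constrained to be non-negative and can be fixed
when measured independently, and a known mesophyll conductance `gm` makes
the fitted capacities chloroplastic rates.

### Stomatal conductance models

`gs_predict()` and `fit_bb()` implement three Ball-Berry-type variants
(conductances to H2O throughout — measured conductance must be supplied on
the H2O basis):

| variant | form | humidity driver |
|---|---|---|
| `ballberry` | $g_s = g_0 + g_1 A_n\,(h_s/100)/C_a$ | relative humidity |
| `leuning` | $g_s = g_0 + g_1 A_n / (C_a (1 + D/D_0))$ | VPD, scale $D_0$ |
| `medlyn` | $g_s = g_0 + 1.6\,(1 + g_1/\sqrt{D})\,A_n/C_a$ | VPD |

In the medlyn (optimality-based) variant the 1.6 diffusivity factor is
written explicitly so $g_1$ (kPa$^{0.5}$) is comparable across studies; in
the other two variants any such factor is absorbed into the empirical
$g_1$. The original Ball-Berry humidity term uses air relative humidity as
a proxy for the leaf surface value (a boundary-layer-free assumption). The
linear-in-parameters variants are fitted by linear regression, the medlyn
variant by nonlinear least squares; `g0` may be fixed (commonly 0), and
$D_0$ is a fixed constant (default 1.5 kPa), not estimated.

With $g_0 = 0$ and a perfectly coupled leaf ($E = g_s D / P_a$), the medlyn
variant implies a closed form for the instantaneous transpiration
efficiency,

$$A_n/E = \frac{C_a P_a}{1.6\,(g_1 \sqrt{D} + D)},$$

implemented in `ite_medlyn()` in umol CO2 per mmol H2O (with $C_a$ in
umol mol$^{-1}$ and $D$, $P_a$ in kPa, the quotient is umol mol$^{-1}$; the
1/1000 scaling to the mmol basis is part of the function and is tested
against the coupled model to $10^{-6}$ relative).

### The coupled model

At steady state the biochemical demand equals the diffusive supply
$A_n = (g_s/1.6)(C_a - C_i)$, with $g_s$ itself responding to $A_n$ through
the stomatal model. `photosyn()` solves the resulting scalar problem with a
bracketed root search in $C_i$ (tolerance $10^{-12}$), which is robust to
the curvature of the hyperbolic minimum; supply-demand residuals at the
solution are below $10^{-8}$ umol m$^{-2}$ s$^{-1}$. Degenerate cases are
explicit: VPD is floored at 0.05 kPa (the $1/\sqrt{D}$ response diverges at
zero) with a warning, and when demand is negative everywhere (darkness) the
stomata sit at $g_0$ and $C_i$ rises above $C_a$; with $g_0 = 0$ no steady
state exists and the row is flagged unconverged.

`photosyn_eb()` drops the assumption that leaf temperature equals air
temperature: transpiration comes from the Penman-Monteith combination
equation, CO2 diffuses through boundary layer (factor 1.37) and stomata
(factor 1.6) in series, and leaf temperature iterates on the energy budget
$R_n = \lambda E + c_p g_h (T_{leaf} - T_{air})$ until the update is below
0.01 degC (closure residuals are reported and stay far below 0.5 W
m$^{-2}$). The boundary-layer conductance is a forced-convection flat-plate
estimate, $0.003\sqrt{u / w}$ in velocity units converted to molar units
with the molar density of air; heat leaves both leaf sides, vapour through
the stomatal side with a 1.075 diffusivity ratio. The stomatal model sees
the air-based VPD. The default net radiation $0.15 \cdot$PAR is a crude
shortwave conversion: supply measurements where available.

### Optimal stomatal behaviour

`optimal_stomata()` finds the $C_i$ that maximises $A_n - \lambda E$, where
$\lambda$ (mol C mol$^{-1}$ H2O) is the marginal cost of water, $g_s$
follows from the rearranged supply function and $E = g_s D / P_a$ (mol
basis, matching $\lambda$'s units; the $A_n$ term is umol, so the cost is
scaled by $10^6$). The search scans a 500-point grid on
$[0.01 C_a,\ 0.999 C_a]$ — the supply function is singular at $C_i = C_a$,
hence the upper bound — and refines the best bracket with golden-section
search to $10^{-4}$ umol mol$^{-1}$. Concavity is not assumed; the
grid-first strategy resolves multi-modal objectives, and an optimum on a
search bound is flagged (`interior_optimum = FALSE`) rather than hidden.
Agreement with a $10^4$-point brute-force scan is within $10^{-9}$ of the
objective, and at interior optima the first-order condition
$dA_n/dC_i = \lambda\,dE/dC_i$ holds to well under 1%. In energy-balance
mode each candidate $C_i$ solves the leaf temperature iteration first;
candidates that fail to converge are treated as invalid rather than
aborting the sweep — with a strong boundary layer an optimum may genuinely
not exist, and the flag records that.

A known property of this optimisation is that the humidity response it
implies, $f(D) = g_s C_a / (1.6 A_n) - 1$, declines approximately as a
power of $D$. The exponent depends on which limitation is active at the
optimum: under the package defaults (saturating light, $\lambda = 0.002$,
Rubisco-limited optimum) the log-log slope over $D \in [0.5, 3]$ kPa is
about $-0.68$, moving to about $-0.44$ near co-limitation (e.g. PAR around
400 umol m$^{-2}$ s$^{-1}$), bracketing the $-0.5$ of the RuBP-limited
analytic approximation that motivates the medlyn variant. The tests assert
the monotone power-law decline, not a specific exponent.

## The synthetic-data generators

`simulate_aci()` emulates a CO2 response curve: 12 points spanning 40-1500
umol mol$^{-1}$ (the range a chamber protocol covers), default capacities
$V_{cmax} = 47$, $J_{max} = 105$, $R_d = 1.3$ umol m$^{-2}$ s$^{-1}$
(typical temperate broadleaf magnitudes), and additive Gaussian noise on
the response only, default SD 0.5 umol m$^{-2}$ s$^{-1}$ (instrument
scale). `simulate_spot()` emulates survey-style measurements: drivers
sampled uniformly over PAR 200-2000 umol m$^{-2}$ s$^{-1}$, leaf
temperature 15-35 degC, VPD 0.5-3.5 kPa and ambient CO2 380-420
umol mol$^{-1}$, assimilation and conductance from the coupled model under
a stated stomatal-model truth, and Gaussian noise (default SD 0.02 mol
m$^{-2}$ s$^{-1}$) on the observed conductance.

Because noise is additive, Gaussian, and on the response only, the
generators match the error model the least-squares fitters assume. Passing
the recovery and calibration tests therefore demonstrates correctness of
the estimation machinery, not robustness to what real gas-exchange data
add: errors in $C_i$ itself (which is derived, not measured), leaks and
matching offsets, autocorrelated drift, and non-constant variance. Fits to
field data should be judged with the diagnostic plot and the reported
standard errors, not by analogy with the synthetic results.

## Problem sizes used in the tests

The shipped test-suite and the acceptance script use desk-scale problems
chosen to make the Monte Carlo error of each check small relative to its
tolerance: 50 random truths for noiseless recovery, 200 replicates for
standard-error calibration, 500 replicates for confidence-interval coverage
(at 200 the coverage estimate's own sampling noise of about 1.5 points is
not negligible against a 3-point band; an independent 2000-replicate run
measured coverage at 95.2%), 100 random draws for the coupled-solver
contract, and a $10^4$-point brute-force grid for the optimality check.

## Known limitations

* Mesophyll conductance is a constant parameter; dynamic responses to
  environment are not modelled (none is established), though simulations
  can vary it manually.
* No triose-phosphate-utilisation limitation in the C3 demand function.
* No fitting of $\Gamma^*$, $K_m$, $g_m$ or $\alpha$ from curves; these are
  inputs.
* No soil-water modifiers, canopy scaling, or dynamic stomatal kinetics.
* The energy-balance leaf is a single flat plate with forced convection;
  free convection and radiative conductance are not included, so the
  closure contract (not parity with any particular instrument model) is
  what the package guarantees.

## A worked example

```{r example}
set.seed(1)
curve <- simulate_aci(noise_sd = 0.5, seed = 10)
fit <- fit_aci(curve)
fit
coef(fit)

spot <- simulate_spot(n = 60, model = "medlyn", g0 = 0, g1 = 4,
                      noise_sd = 0.02, seed = 11)
fit_bb(spot, model = "medlyn", g0 = 0)

photosyn(vpd = c(1, 2, 3))
optimal_stomata(vpd = 1.5, lambda = 0.002)
```
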