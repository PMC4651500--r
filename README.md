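# leafgas

Analysis and simulation of leaf gas exchange in R.

Leaf-level measurements of CO2 assimilation and transpiration, collected
with portable gas-exchange instruments, are interpreted through a small set
of standard models. This package implements that toolkit for plant
ecophysiologists:

* **A-Ci curve fitting** (`fit_aci()`, `fit_aci_batch()`) — estimates the
  photosynthetic capacities of the Farquhar-von Caemmerer-Berry (FvCB)
  model by nonlinear least squares. Net assimilation is
  `An = min(Ac, Aj) - Rd` with the Rubisco-limited rate
  `Ac = Vcmax (C - Γ*)/(C + Km)` and the RuBP-regeneration-limited rate
  `Aj = (J/4)(C - Γ*)/(C + 2Γ*)`; the fit uses a hyperbolic minimum
  (shape 0.9999) so the limitation transition is smooth and located
  automatically. Standard errors, t-based 95% confidence intervals, R²,
  fixed-Rd, fixed-transition and mesophyll-conductance (`gm`) options, and
  per-observation temperature correction are included.
* **Stomatal conductance models** (`fit_bb()`, `gs_predict()`) — the
  Ball-Berry (RH), Leuning (VPD with scale D0), and optimality-based
  `gs = g0 + 1.6 (1 + g1/√D) An/Ca` variants, fitted by linear or nonlinear
  least squares on conductance to H2O. The closed-form instantaneous
  transpiration efficiency `An/E = Ca Pa / (1.6 (g1 √D + D))` is
  `ite_medlyn()`.
* **The coupled model** (`photosyn()`) — solves the steady-state
  intersection of the FvCB demand function, the diffusive supply function
  `An = (gs/1.6)(Ca - Ci)`, and a stomatal model; also runs with `Ci` or
  `gs` imposed. `photosyn_eb()` adds a leaf energy balance (Penman-Monteith
  transpiration, boundary-layer conductances, iterative leaf temperature).
* **Optimal stomatal behaviour** (`optimal_stomata()`,
  `optimal_gs_vpd()`) — numerically locates the Ci that maximises
  `An - λE` (λ = marginal cost of water, mol C per mol H2O), grid scan plus
  golden-section refinement, optionally with the energy balance.
* **Synthetic data with known truth** (`simulate_aci()`,
  `simulate_spot()`) — generators matched to the fitters' error model, so
  the whole workflow is testable end to end.
* **Utilities** — humidity conversions (`esat()`, `rh_to_vpd()`,
  `vpd_to_rh()`, `dew_to_vpd()`, `vpd_from_tair()`), a C4 simulator
  (`aci_c4()`), gas-analyser CSV I/O (`read_gas_exchange()`), YAML/JSON
  parameter configs, and a command-line interface (`exec/leafgas`,
  `gx_cli()`).

Units throughout: conductances in mol m⁻² s⁻¹ (H2O basis), CO2 in
µmol mol⁻¹, VPD and pressure in kPa, temperatures in °C, assimilation in
µmol m⁻² s⁻¹, transpiration in mmol m⁻² s⁻¹.

## Worked example

```r
library(leafgas)

# A CO2 response curve with known truth (Vcmax 47, Jmax 105, Rd 1.3)
curve <- simulate_aci(noise_sd = 0.5, seed = 10)
fit <- fit_aci(curve)
fit
#> FvCB model fit to an A-Ci curve (12 observations)
#>       estimate     se    lower    upper
#> vcmax  45.9758 0.8603  44.0295  47.9220
#> jmax  106.7970 1.4165 103.5926 110.0014
#> rd      1.3814 0.1941   0.9424   1.8204
#> R2 (measured vs fitted): 0.9986   SSR: 1.179
#> Transition Ci (Ac = Aj): 693.7 umol mol-1
```

The estimates recover the generating truth within their standard errors;
the transition Ci is where the Rubisco- and RuBP-limited rates cross.
`plot(fit)` draws the measurements, the fitted curve and both limitation
lines.

```r
# Spot gas exchange and the optimality-based stomatal model (g0 fixed at 0)
spot <- simulate_spot(n = 60, model = "medlyn", g0 = 0, g1 = 4,
                      noise_sd = 0.02, seed = 11)
fit_bb(spot, model = "medlyn", g0 = 0)
#> Stomatal conductance model fit (variant: medlyn, 60 observations)
#>    estimate      se   lower   upper
#> g0  0.00000      NA      NA      NA
#> g1  4.09082 0.07701 3.93673 4.24491
#> RMSE: 0.01926 mol m-2 s-1   R2: 0.8545

# Coupled leaf gas exchange across a humidity gradient
photosyn(vpd = c(1, 2, 3))[, c("an", "gs", "e", "ci", "ite")]
#>         an        gs        e       ci      ite
#> 1 11.94841 0.2389682 2.359015 320.0000 5.065000
#> 2 11.06034 0.1693748 3.344024 295.5185 3.307494
#> 3 10.44114 0.1382157 4.093259 279.1322 2.550814

# Cowan-Farquhar optimum at a water cost of 0.002 mol C per mol H2O
optimal_stomata(vpd = 1.5, lambda = 0.002)
#>     ci_opt       an        gs objective interior_optimum
#> 1 264.9246 9.887308 0.1171175  6.418872             TRUE
```

As VPD rises the coupled stomata close (`gs` falls), intercellular CO2
drops, and transpiration still increases — so the instantaneous
transpiration efficiency `ite = an/e` (µmol CO2 per mmol H2O) declines.

The command line mirrors these functions:

```sh
leafgas simulate aci --seed 1 --out curve.csv
leafgas fit-aci --input curve.csv --out coefs.csv
leafgas photosyn --tleaf 5:40:5 --vpd 1.5
leafgas farao --lambda 0.002 --vpd 0.5:3:0.25
```

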