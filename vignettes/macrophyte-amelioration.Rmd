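---
title: "Quantifying macrophyte amelioration of seawater acidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrophyte amelioration of seawater acidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycarb)
```

`phycarb` implements the computational chain behind a pair of
macrophyte–carbonate-chemistry experiments and the predictive model built
on them: closed-chamber incubations comparing four species across a pCO₂
gradient, and a flow-through kelp experiment crossing CO₂/temperature
scenario with water residence time along an irradiance gradient. This
vignette is the package's own account of the science: the models, the
parameters that matter, the numerical choices, and what the shipped tests
do and do not demonstrate.

## The carbonate system solver

All chemistry is solved on the **total pH scale** at surface pressure
(0 dbar). The alkalinity model keeps the terms that the measured inputs
constrain:

$$TA = [\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}] + [\mathrm{B(OH)_4^-}] +
[\mathrm{OH^-}] - [\mathrm{H^+}]_F - [\mathrm{HSO_4^-}] - [\mathrm{HF}]$$

Phosphate, silicate and ammonia alkalinity are omitted — nutrients were
not measured in the experiments the package models, and at the
sub-micromolar levels typical of the study region their contribution is
well below the 5 µmol kg⁻¹ titration precision. There is deliberately no
air–sea gas-exchange term: chambers and tanks were sealed or
continuously flushed, and the prediction model describes the water inside
a macrophyte bed before re-equilibration.

Constant formulations (all evaluated from in-situ temperature and
salinity): carbonic acid K₁/K₂ from Lueker et al. (2000, total scale),
bisulfate from Dickson (1990a, free scale), fluoride from Pérez & Fraga
(1987), CO₂ solubility from Weiss (1974), borate from Dickson (1990b),
water from Millero (1995), aragonite solubility from Mucci (1983), and
conservative totals (B, SO₄, F, Ca) proportional to salinity. This is the
default set of the CO2SYS/seacarb family; an independent Python
transcription of the same primary-literature formulas, written before the
R code, provides the frozen cross-implementation reference values used in
the tests.

Two directions are exposed. `carb_from_ph_ta()` is a direct algebraic
solution: with H⁺ known, the non-carbonate terms are subtracted from TA
and the speciation follows in closed form. `carb_from_dic_ta()` finds pH
by bracketed root-finding of the TA residual on pH ∈ [3, 12]
(`uniroot`, tolerance 10⁻¹⁰ pH); the bracket is checked for a sign change
and the solver errors rather than clamps when a state is infeasible. The
round-trip pH → DIC → pH closes to better than 10⁻⁶ pH across the tested
envelope (pH 7–8.5, TA 1800–2500 µmol kg⁻¹, S 25–36, T 5–30 °C; 1000
random states in the suite).

Volumetric (µmol L⁻¹) and gravimetric (µmol kg⁻¹) concentrations are
interconverted with a fixed 1.024 kg L⁻¹ seawater density. A full
equation of state would vary this by ~0.5% over the package's
temperature–salinity envelope; the fixed factor is kept because the
prediction chain is defined with it and the error is far below the other
uncertainties involved.

One reference computation recurs throughout the documentation: the
background parcel DIC = 2200 µmol kg⁻¹, TA = 2100 µmol kg⁻¹, S = 30,
T = 11 °C. With the constant set above this parcel sits at pH 7.208, and
removing 22.5 µmol L⁻¹ of DIC (21.97 µmol kg⁻¹) at constant TA raises it
to 7.271. The pair of states is internally consistent; quoted headline
values for the *initial* pH of such a parcel vary with the constant set
and rounding conventions used, which is why the package always reports
both states from its own solver rather than mixing sources.

```{r}
apply_to_background(22.5, DIC = 2200, TA = 2100,
                    temperature = 11, salinity = 30)[c("pH_before",
                                                       "pH_after")]
```

## Monte-Carlo uncertainty propagation

`propagate_uncertainty()` perturbs a central (pH, TA) state with
independent Gaussian errors — defaults σ_pH = 0.01 (spectrophotometric /
TRIS-calibrated electrode precision) and σ_TA = 5 µmol kg⁻¹ (open-cell
titration precision) — re-solves every draw, and reports one standard
deviation of each derived parameter. The default of 100 simulations
matches common practice for instrument-error budgets; tests that assert
numerical bands use 5,000–20,000 draws so the SD estimate itself is not
the limiting noise. Chemically infeasible draws are *excluded and
counted*, never clamped: clamping would bias the SD toward zero.
Reproducibility is part of the contract — the report stores the seed.

Two qualitative behaviours are asserted in the suite: DIC uncertainty is
dominated by, and comparable to, the TA error (0.7–1.4 × σ_TA over
pH 7.5–8.1), and the relative pCO₂ uncertainty falls as pCO₂ rises.
The relative uncertainty of Ω is reported but no fixed value is asserted:
Ω is the most pH-sensitive derived parameter, and its relative SD at
these conditions is of order 2%, not hundredths of a percent.

## Light-response curves

The photosynthesis–irradiance model is the saturating hyperbolic tangent
without photoinhibition,

$$P = P_{max}\tanh\!\left(\frac{\alpha E}{P_{max}}\right), \qquad
E_k = \frac{P_{max}}{\alpha},$$

fitted by derivative-free Nelder–Mead least squares (`optim`), restarted
once from the first optimum with a tight relative tolerance (10⁻¹⁴).
Starting values are `pmax₀ = max(P)` and `alpha₀` from the slope of the
two lowest non-zero light levels — robust for saturating curves.
Exact synthetic data are recovered to better than 10⁻⁴ relative, and a
200 × 200 brute-force grid over (Pmax, α) never improves on the simplex
optimum by more than 10⁻⁶ RSS in the suite.

Two modelling choices deserve explanation:

* **The dark step is excluded by default.** The model forces P(0) = 0,
  so the E = 0 observation carries no information about (Pmax, α) — its
  residual is parameter-free — while the *observed* dark response
  reflects respiration. `dark_offset = TRUE` fits the net model
  `P = JP(E) − R_d` instead, keeping the dark step and estimating the
  respiration offset; this is the right form for data generated with
  nonzero dark offsets and is what gives the amelioration threshold
  (below) its meaning.
* **Identifiability flags.** With only one or two supra-saturating light
  levels, noise can push the least-squares optimum to a degenerate limit:
  Pmax → ∞ with the curve a straight line (Ek far above the measured
  range), or α → ∞ with an instant plateau (Ek below the lowest light
  level). Fits whose Ek falls outside [min E/3, 3 max E] (or with
  Pmax > 5 max |P|) are flagged unidentified; `fit_tank_curves()` drops
  them from treatment summaries by default, mirroring the practical
  treatment of replicate curves that never approach saturation.

A genuine information limit follows from the six-step light design
(0–260 µmol photons m⁻² s⁻¹ with Ek ≈ 210): at response noise of 10% of
Pmax the median relative error of fitted Pmax is ~15%, however the
optimizer is driven. The suite therefore asserts accurate recovery
(≤ 5% median error) at 2% noise and monotone degradation with noise,
rather than a blanket precision claim.

Treatment comparisons use Welch's unequal-variance t-test with
Satterthwaite degrees of freedom, implemented from summary statistics
(mean, SE, n) so that published treatment tables can be compared
directly; `welch_from_samples()` delegates to the same formula, and the
suite cross-checks it against base `t.test()` and verifies null p-value
uniformity by simulation.

## Chamber analysis

`chamber_deltas()` derives DIC and Ω at both incubation time points from
measured pH and TA, then normalizes the changes per gram dry weight and
hour (chambers are 1 L, so concentration change per litre is the chamber
change). Sign conventions are explicit: ΔDO, ΔpH, ΔΩ are final − initial;
ΔDIC is initial − final so that *uptake is positive*. Controls (no
macrophyte) are normalized per litre and hour only. Alkalinity measured
on representative chambers can be supplied as a species × level table
(`species_ta`), with per-chamber measurements taking precedence.

`fit_species_pco2_model()` is ordinary least squares of a normalized
response on species (categorical) × pCO₂ (continuous), with the
sequential (Type-I) ANOVA in the fixed order species, pCO₂, interaction —
the default decomposition of the analysis environment this workflow comes
from, and the order in which the design questions are nested. Per-species
slopes and their standard errors are assembled from the coefficient
covariance matrix; `confint()` gives per-species slope intervals.

## The amelioration prediction model

The ecosystem-scale predictor rests on one biological assumption —
**the bulk chemical change scales linearly with biomass density** — and
one interpolation assumption — **the response is linear in water flow
between the two fitted endpoints** (0.5 and 1.4 L min⁻¹; equivalently 60
and ~21 min residence time in a 30 L tank, though flow, not residence
time, is the interpolation axis). Per treatment, the mean light curve is
evaluated at the requested irradiance, divided by the tank biomass
density (150 g FW / 30 L = 5 g L⁻¹), and interpolated point-wise in flow:

$$r(E, f) = \frac{v}{B}\left[(1-w)\,JP(E;\bar P^{lo},\bar\alpha^{lo}) +
w\,JP(E;\bar P^{hi},\bar\alpha^{hi})\right],
\quad w = \frac{f - f_{lo}}{f_{hi} - f_{lo}}$$

Interpolating the *curves* point-wise rather than the *parameters*
(P̄max, ᾱ) was a genuine design choice: the two differ slightly between
endpoints because tanh is nonlinear in its parameters. Point-wise
interpolation was chosen because it preserves the endpoint curves exactly
and keeps the interpolant monotone in E at every flow.

The per-density rate (µmol L⁻¹ per g FW L⁻¹) times a standing-stock
density gives the bulk change (`predict_bulk_change()`), and
`apply_to_background()` closes the loop chemically: the DIC drawdown is
subtracted at constant TA (photosynthetic CO₂ removal does not titrate
alkalinity) and both states are re-solved. ΔpH and ΔΩ for a water body
are therefore *derived through the carbonate system* from the predicted
ΔDIC — the thermodynamically consistent route — rather than from their
own fitted light curves, which remain available for describing the tank
experiment itself.

The shipped treatment parameter table (`default_treatment_fits()`)
carries the treatment means, SEs and n for all four response variables.
For the pH and Ω curves the published initial slopes round to 0.00 at two
decimals, so α is reconstructed as Pmax/Ek for those rows; DO and DIC
rows use the printed values.

The **amelioration threshold** is the irradiance at which the net rate
(gross light response minus a dark respiration offset) crosses zero,
found by bisection to 10⁻³. The gross model passes through the origin, so
the threshold is only meaningful with a nonzero offset; the offset is a
user input (or a fitted `rd` from the net model) because the package
takes no position on a single representative respiration rate.

Fresh and dry weight interconvert by the empirical kelp regression
DW = 0.1187 FW − 0.0086 (g), floored at zero.

## What the synthetic generators emulate

`generate_chamber_experiment()` reproduces the chamber design: 4 species
× 6 pCO₂ levels (280–1120 µatm) × 5 replicates plus one control per
level, 1 L chambers, 1.5 h incubations, T 14–16 °C, S 31, TA ≈ 2150
µmol kg⁻¹ with ±3 real variation among chambers. The initial state is
solved from the jittered target pCO₂ and TA; the *true* per-gram-per-hour
DO release and DIC uptake come from a per-species intercept + slope ×
pCO₂ truth table; DIC is removed at constant TA and the final pH follows
from the solver, so ΔpH and ΔΩ *emerge* from the chemistry rather than
being drawn independently — the four responses of any generated chamber
are mutually consistent, as in real water. Measurement noise (0.01 pH,
5 µmol kg⁻¹ TA, 2 µmol L⁻¹ DO — the instrument precisions) is added to
both time points. Default dry biomass is 0.3–0.8 g per chamber, kept
small so that the steepest DIC-uptake slope in the truth table leaves
high-pCO₂ chambers chemically feasible.

`generate_tank_experiment()` reproduces the flow-through design: 2
scenarios (ambient ~500 µatm / 11 °C; future ~1600 µatm / 13 °C) × 2
flows × 5 kelp tanks (+1 control) × 6 light steps. Each tank draws its
light-curve parameters log-normally around the treatment truth with
CV = SE·√n/mean from the treatment table (log-normal keeps Pmax and α
positive), plus a per-tank dark respiration offset (default mean 3
µmol L⁻¹) so dark steps show negative Δ. Outflow DIC, pH and Ω are again
linked through the solver.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: within-tank hydrodynamics and boundary-layer
transport, non-steady-state transients between light steps, calcifier or
nutrient alkalinity changes (TA is held constant through every
incubation), temporally correlated sensor drift, and biological
covariance between Pmax and α beyond their independent draws. One
quantitative consequence is documented here deliberately: because the
treatment-table SEs already contain curve-fitting noise, drawing
biological spread at the full SE-implied CV *and* adding
instrument-precision measurement noise double-counts variability, so
statistical power for between-flow comparisons of fitted parameters in
generated data (~30–40% for the ambient DO Pmax contrast) is well below
what the original summary statistics imply. The suite asserts the
direction and recovery of effects, not that published significance
levels reproduce.

## Problem sizes and numerical conventions

The suite fits its checks to desk scale: 1000 random states for
round-trip closure, 12 frozen states for cross-implementation
equivalence, 10,000–20,000 Monte-Carlo draws where SD bands are asserted,
200 simulated chamber experiments for slope-coverage, and 120 fits per
noise level for recovery curves. The acceptance script averages 27
representative states × 2000 draws for the uncertainty figure. All
stochastic components take explicit seeds; generators reset the RNG from
their config seed so a (seed, config) pair reproduces tables exactly.
Root-finding is bracketed and deterministic (no initial-guess
sensitivity); optimization is restarted simplex with convergence and
identifiability flagged rather than silently accepted; infeasible
chemical states throw errors carrying the offending record rather than
being clamped.

## Known limitations

* The carbonate model omits nutrient and organic alkalinity and any
  pressure dependence; it is a surface, inorganic model.
* The fixed 1.024 kg L⁻¹ density is a convention, not an equation of
  state.
* Flow interpolation is supported only inside the fitted range
  (0.5–1.4 L min⁻¹); outside it the model clamps with a warning (or
  errors in strict mode) because linearity beyond the endpoints was never
  observed.
* The prediction model assumes uniform light over the biomass, no
  self-shading, no biofouling and no air–water CO₂ exchange; it describes
  an idealized, well-mixed bed interior.
* Ecosystem predictions inherit the identifiability limits of the
  underlying light-curve fits discussed above.
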