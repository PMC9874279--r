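---
title: "Modelling sediment iron diagenesis with stable-isotope tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sediment iron diagenesis with stable-isotope tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(benthicFe)
```

## The model

`benthicFe` solves the steady state of a vertically resolved
reaction-transport model of early diagenesis in marine sediments, with a
complete two-isotope (⁵⁴Fe + ⁵⁶Fe) budget for every iron species. Solids
are transported by burial advection and biodiffusive mixing; solutes by
tortuosity-corrected molecular diffusion, porewater advection and
non-local bio-irrigation exchange with the bottom water. The advection
velocities follow steady compaction, with porosity decaying
exponentially from its interface value to an asymptotic value at depth.

Two variants share one code path:

* the **idealized** shelf set-up carries the coupled C–N–O–Mn–Fe–S
  cycles: three organic-matter reactivity fractions (multi-G), the
  oxidant cascade O₂ → NO₃⁻ → MnO₂ → FeOOH → SO₄²⁻ → methanogenesis
  partitioned by Monod limitation with inhibition by the more favourable
  oxidants, four iron-oxide reactivity classes (highly, moderately,
  poorly reactive and unreactive, defined by their half-life toward
  sulfide: <1 yr, ~100 yr, ~10⁵ yr, inert; the oxide rain is split 1/6,
  1/6, 1/6, 1/2 over them), oxide aging, sulfide-mediated oxide
  reduction, Fe²⁺ oxidation by O₂ and by MnO₂, sorption equilibrium,
  FeS precipitation/dissolution around its solubility threshold, pyrite
  formation by the dissolved-sulfide and polysulfide (S⁰) pathways, and
  the oxidative back-reactions of DFe, FeS and FeS₂;
* the **site** set-up (used for the two calibration sites) disables the
  nitrogen and manganese species — every shared species keeps the same
  tendency expressions, which the test suite asserts — and replaces the
  four-class oxide scheme with a fresh/aged split of the highly reactive
  class: all deposited oxide enters the fresh pool, ages with a
  first-order constant, and both sub-pools remain available to
  dissimilatory reduction (the aged one discounted by a bioavailability
  weight) and to reduction by sulfide.

Isotopes follow the source-pool convention: a reaction consuming bulk
iron at rate `R` from a pool with ratio `r = ⁵⁶C/(C − ⁵⁶C)` removes
heavy iron at `⁵⁶R = α r/(1 + α r) R`, `α = 1 + ε/1000`. Below a bulk
concentration of 10⁻⁹ µmol cm⁻³ the reaction proceeds without
fractionation, which keeps δ values bounded in near-empty pools.
Sorption is an instantaneous equilibrium `ads = K_ads [Fe²⁺]` whose
heavy-isotope loading carries the sorption fractionation, so the
adsorbed pool sits ~+0.4‰ above the dissolved pool; the adsorbed iron
rides the solid-phase transport (mixing and burial).

## Parameters that matter

Boundary conditions (bottom-water concentrations in mM; POC rain in
mmol m⁻² d⁻¹; particulate iron fluxes in µmol m⁻² d⁻¹ with their input
δ⁵⁶Fe) and the bioturbation parameters are per-configuration values; the
shipped fixtures encode the two calibration sites and the idealized
baseline. The effective fractionations default to reduction −1.3‰,
oxidation +0.4‰, sorption +0.4‰, FeS precipitation +0.5‰, dissolution
−0.5‰, pyrite −0.7‰ (−0.4‰ in the canyon-site fixture, where the
site-specific fit differs); all can be overridden per run.

Rate and equilibrium constants live in `default_kinetics()` and are
deliberately exposed in full. The supplementary parameter tables of the
source study were not available to this implementation, so the constants
were fixed once from the standard diagenetic-modelling literature, with
three anchors worth naming:

* the multi-G split (50% at 24 yr⁻¹, 33% at 1.4 yr⁻¹, 17% refractory)
  pins the depth-integrated carbon oxidation rate at 83% of the POC
  rain, the burial fraction the study conditions imply;
* the dissimilatory-reduction half-saturation on the oxide pool is
  large (2500 µmol cm⁻³ solid in the idealized variant), making the
  FeOOH mineralization pathway a negligible share of carbon oxidation —
  iron reduction is then driven mainly through the sulfide shuttle, as
  the source model's pathway partitioning shows;
* Fe²⁺ oxidation uses 10⁹ M⁻¹ yr⁻¹ against O₂ plus an MnO₂-mediated
  anoxic pathway in the mixed layer; together they form the reoxidation
  barrier that keeps the oxygenated-seafloor benthic flux at the
  ~1%-of-input level the transfer functions encode.

The site variant carries its own defaults (stronger dissimilatory
reduction, slower Fe²⁺ oxidation at 3×10⁷ M⁻¹ yr⁻¹, faster aging),
fitted by the two-stage procedure used for the sites: bulk fluxes and
profiles first, isotope fractionations second. With them the canyon site
reproduces its published benthic flux (19 µmol m⁻² d⁻¹) and the basin
site its flux within 12%; the flux δ⁵⁶Fe values come out 0.2–0.6‰
lighter than published at both sites. We could not remove that offset
with any physically defensible parameter combination: it would require
the strongly asymmetric expressed fractionation of the source model
(weak at the low-escape bioturbated site, strong at the high-escape
basin), which evidently depends on supplementary rate-law details we do
not have. The acceptance test records this honestly as a failing
assertion rather than widening the tolerance.

## Numerics

The domain (150 cm by default) is discretized with a finite-volume
scheme: upwind advection, centred diffusion, fixed concentrations for
solutes and imposed deposition fluxes for solids at the interface,
zero-gradient at depth. Cells grow geometrically from ~0.05 cm at the
interface, because the oxygen penetration depth — and with it the
reoxidation barrier that controls the benthic iron flux — is a
millimetre-scale feature under oxygenated bottom water; a uniform grid
of practical size cannot resolve it. A uniform grid remains available
through `build_grid()`. Default resolutions: 100 cells for single runs,
60 for the parameter sweeps in the tests; doubling the resolution moves
the baseline benthic flux by well under 2%.

Steady states are found by stiff pseudo-time integration
(`deSolve::ode.1D`, lsodes, with per-species absolute-error floors tied
to each field's physical scale) followed by a damped-Newton /
pseudo-transient-continuation polish on the full sparse Jacobian
(finite-differenced with a three-colour cell scheme, factorized with
`Matrix`). Convergence is declared when the scaled tendency norm
`max |dC/dt|/scale(C)` falls below 10⁻⁸; a wall-clock budget per run
(default 90 s) bounds pathological parameter corners, which then return
their best state with the residual attached, and the sweep-level
analyses exclude runs with residuals above 10⁻⁶. The right-hand side is
compiled (Rcpp); a reference R implementation of the identical
expressions is kept and the suite asserts bitwise-level agreement, so
the compiled path never becomes the only definition of the model.

Three smoothing choices keep the steady-state problem differentiable,
all with widths far below any quantity of interest: bimolecular rate
laws use raw concentrations (a marginally negative pool then produces a
restoring rate); Monod fractions use a one-sided C¹ regularization that
is exactly zero for empty pools and joins the Monod curve over ~K/10;
and the FeS saturation switch uses a smooth positive part of width 10⁻²
in saturation units. FeS precipitation itself is bimolecular and
saturation-limited, `k φ [Fe²⁺][HS⁻] sat(1 − Ω⁻¹)`, so it is first-order
in each reactant, doubles when the ferrous iron doubles far above
saturation, and vanishes smoothly at and below Ω = 1.

## Scenarios, sensitivity grids and what they do (and do not) show

`make_scenario()` builds the five bioturbation experiments; the baseline
scales `D_b,0 = 10f` cm² yr⁻¹ and `α₀ = 290f` yr⁻¹ with the oxygen ramp
`f = 0.5 + 0.5 erf(([O₂]_BW − 20)/12)`, and the mixing depth follows
`z_L = 1 + 9(1 − e^{−D_b,0/3})` cm, which passes through the reference
value of 9.7 cm at `D_b,0 = 10` (an alternative printed form of this
expression with denominator 30 does not reproduce that reference value
and is kept only as an option). The irrigation attenuation is 1.4 cm in
the idealized set-up and 3 cm at the canyon site. `enumerate_grid()`
spans the tested sensitivity levels (O₂ 1–200 µM, POC rain 0.5–16
mmol m⁻² d⁻¹, oxide rain 194–1914 µmol m⁻² d⁻¹, and a sulfate axis for
the unbioturbated seafloor).

These scenarios emulate steady, laterally homogeneous sediments with a
fixed organic-matter reactivity distribution. They do not represent
transient deposition events, resuspension, variable organic-matter
quality, or non-reductive oxide dissolution — so agreement of the tests
with the study conditions says nothing about settings where those
processes dominate (deep-sea, passive-margin or event-driven
sediments).

The test suite re-derives the predictive transfer functions on reduced
grids (5 O₂ × 5 POC levels, two oxide-rain levels for the bioturbated
case; all values chosen from the tested levels above) rather than the
full multi-hour grids. On these, the isotope surfaces for both seafloor
states are explained at R² ≈ 0.93–0.94 by the published functional
forms, while the unbioturbated flux surface reaches R² ≈ 0.88: our
reconstructed network shuts the flux down more sharply with increasing
O₂/Cox than a single exponential saturation can follow. Relatedly, the
published flux forms themselves order the two seafloor states
"unbioturbated ≥ modern" pointwise at equal forcing — opposite to the
simulations they summarize at high oxygen — because the
exponential-saturation fit is poorest in exactly that low-`Cox/[O₂]`
regime; the upscaling tests assert the behaviour of the implemented
forms and flag this caveat.

## Calibration

`calibrate_fractionation()` implements the isotope stage of the
two-stage site calibration: given observed δ⁵⁶Fe depth profiles of
dissolved iron, HCl-extractable iron (oxides + sorbed Fe²⁺ + FeS) and
pyrite, it minimizes the summed squared profile residuals over one
effective fractionation by a deterministic coarse grid with local
refinement. Each candidate requires a steady state, but the bulk fields
do not depend on the fractionations, so the warm-started re-solves are
cheap. On synthetic profiles generated by the model itself the search
recovers the generating reduction fractionation to better than ±0.1‰.

## Known limitations

* The site-variant δ⁵⁶Fe offsets described above.
* Steady state only; no transient diagenesis.
* The upscaling reproduces interval-level arithmetic over any supplied
  O₂ field; reproducing published global totals requires the external
  oxygen climatology those totals were computed from, which is not
  bundled.
* Effective fractionations are single constants per reaction; any
  rate-dependence of isotope fractionation is outside the model.
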