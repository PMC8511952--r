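---
title: "Kinetic and biophysical analysis of glutamyl-tRNA synthetase variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and biophysical analysis of glutamyl-tRNA synthetase variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarskin)
```

## The problem

Point mutations in aminoacyl-tRNA synthetases are a recurring cause of human
disease. Characterizing a synthetase variant *in vitro* typically combines
four assays: steady-state aminoacylation kinetics (kcat, KM), ATP–PPi
isotope exchange (the amino-acid activation step in isolation),
fluorescence-anisotropy tRNA binding (Kd), and CD thermal melting (apparent
Tm and cooperativity). `aarskin` implements the quantitative analysis of all
four, plus a mechanistic simulator that connects microscopic rate constants
to the apparent steady-state parameters, so that hypotheses such as "this
variant slows amino-acid activation 10-fold" can be tested against the
observed (kcat, KM) pattern.

The glutamyl-tRNA synthetase family poses one mechanistic particularity:
amino-acid activation requires bound tRNA. The simulator encodes this by
construction — there is no reaction path from free enzyme plus Glu and ATP
to the adenylate; activation is only reachable through the E·tRNA complex.

## The eight-step model

The scheme (see `build_eight_step_scheme()`) is the minimal elementary
decomposition satisfying the mechanistic constraints: tRNA binds first;
Glu and ATP then bind in a fixed order (tRNA → Glu → ATP); activation
(step 4) forms the enzyme-bound glutamyl-adenylate with PPi still bound;
PPi release (step 5) precedes transfer (step 6); AMP release (step 7) and
product release (step 8) complete the cycle.

Assumptions and conventions:

* **Mass action, elementary steps.** Every reaction has at most two
  reactants and two products; rates are products of concentrations.
* **Irreversibility.** Transfer (6) and product release (8) are treated as
  committed, irreversible steps; steps 1–5 and 7 are reversible. Transfer
  is the step whose commitment underlies the rate-limiting-step argument
  below; making it reversible would require thermodynamic data no assay
  here constrains.
* **Binding order.** Whether Glu and ATP bind ordered or randomly is not
  observable from the assays modeled here; a fixed order keeps the scheme
  at eight steps. Random-order binding would add states without changing
  any conclusion drawn in this package, because the co-substrates are
  saturating in all modeled designs.
* **Units.** µM and seconds everywhere inside the module; second-order
  constants in µM⁻¹s⁻¹. Conversions (nM for binding) happen at module
  boundaries only.
* **Integration.** `deSolve::ode` with `lsoda`, rtol 1e-8, atol 1e-10 µM
  (exposed via `ode_control()`). Conservation of the four invariant totals
  (enzyme, tRNA, adenine nucleotide, pyrophosphate moiety) is verified at
  every output point to 1e-6 relative; violations are errors, not warnings.
* **Initial state.** Aminoacylation assays start all-free (reactions are
  initiated by enzyme addition); exchange assays preincubate the
  enzyme–tRNA binding step to equilibrium first, matching the respective
  protocols.

For isotope exchange, the labeled and unlabeled ATP/PPi pools are duplicated
as distinct species with identical rate constants (isotopologues are
kinetically equivalent); the label travels with the β,γ-phosphates, so it
can enter ATP only via reversal of activation followed by reversal of ATP
binding. Total label is a fifth conserved quantity. At long times the label
fraction in ATP approaches the pool ratio ATP/(ATP+PPi) — a parameter-free
check used in the tests.

## Calibration of the default rate constants

`default_rates("WT")` ships one internally consistent parameterization whose
*apparent* steady-state parameters under the standard assay (20 µM Glu,
4 mM ATP, 100 nM enzyme, 0.5–16 µM tRNA) are kcat ≈ 0.167 s⁻¹ and
KM ≈ 1.62 µM. The constants are *not* measured microscopic values; they are
derived from the steady-state algebra of the scheme:

* With saturating co-substrates, the tRNA-bound enzyme pool distributes
  over E·tRNA : E·tRNA·Glu : E·tRNA·Glu·ATP with weights
  1 : [Glu]/K₂ : ([Glu]/K₂)([ATP]/K₃). With K₂ = 1 µM and K₃ = 100 µM the
  weights are 1 : 20 : 800, so the pool sits almost entirely on the
  ternary complex and the bare E·tRNA state (the only state that can lose
  tRNA) holds ~0.12% of it.
* kcat is the inverse cycle time
  1/kcat ≈ 1/(k₄ f) + 1/k₆ + 1/k₈ with f the ternary-complex fraction;
  k₄ = 0.2, k₆ = 1.45, k₈ = 8.7 s⁻¹ give kcat ≈ 0.167 s⁻¹, with
  activation ~6× faster than its own contribution would need to be if it
  were rate-limiting — so turnover is dominated by transfer.
* kcat/KM is capture-limited: once tRNA binds, the dissociation flux
  k₋₁·(E·tRNA fraction) is ~1.5% of the forward flux, so nearly every
  binding event commits. Hence kcat/KM ≈ k₁ = 0.119 µM⁻¹s⁻¹·C ≈ 0.103,
  and KM = kcat/(kcat/KM) ≈ 1.6 µM.

Slowing only step 4 ten-fold (`default_rates("P14R")`) then (i) makes
activation slower than transfer, dropping kcat ~8.8-fold; (ii) drops KM
almost proportionally; and (iii) leaves kcat/KM within ~10% of the base,
because commitment falls only from ~0.985 to ~0.87. This is the kinetic
signature that distinguishes an activation defect from a binding defect
(which would raise KM) or a uniform catalytic defect (which would lower
kcat/KM in proportion).

Two consequences of capture-limited kinetics are worth stating because they
bound what perturbation experiments can show:

* *Any* post-binding slowdown preserves kcat/KM. Slowing product release
  10-fold, for example, lowers kcat mildly (release is far from
  rate-limiting) and KM in proportion — the efficiency flag cannot
  distinguish step 8 from step 4; the *magnitude* of the kcat drop can
  (<2-fold vs ~9-fold).
* The exchange readout compresses the activation ratio. With the
  activation step slowed 10-fold, the instantaneous exchange velocity falls
  ~8-fold (the equilibrium occupancy of the activation complex shifts), and
  the 30-min label fraction falls ~6-fold, because the wild-type tracer
  curve is already bending toward its equilibrium (a two-pool tracer ratio
  (1−e^(−x/10))/(1−e^(−x)) is strictly above 1/10 for any x > 0). Tests
  assert these honest values, not the idealized 1/10.

## Steady-state fitting choices

* **Initial-rate window:** points with product ≤ 10% of total substrate and
  at least 4 qualifying points; the rate is the OLS slope with free
  intercept. The free intercept absorbs small transients; the residual
  bias of the slope is ≈ half the conversion cap (substrate depletion), so
  noiseless recovery tests use tighter caps (1–5%) where sub-percent
  accuracy matters.
* **Simulated scans** (`apparent_mm_scan()`) discard the first 35% of the
  window before the slope: reactions started from free enzyme carry a
  pre-steady-state binding transient that is material when the tRNA
  on-rate is slow, as in the shipped calibration.
* **Michaelis–Menten fit:** unweighted Levenberg–Marquardt
  (`minpack.lm::nlsLM`), initialized at KM₀ = median(S),
  kcat₀ = max(v)/E₀. Unidentifiable data (no saturation in range) make the
  gradient singular at the optimum; the fitter then falls back to the raw
  `nls.lm` optimizer and flags the fit unreliable when KM leaves
  [min(S)/100, 100·max(S)].
* **Efficiency summaries:** kcat/KM is computed per replicate and then
  averaged (mean of ratios). Low-substrate rate ratios estimate efficiency
  folds only when S ≪ KM for *both* enzymes; when a variant's KM
  approaches the assay concentration the fitted-parameter ratio must be
  used instead.
* **Fold changes** are reported to 2 significant figures.

## Binding and melting fitting choices

* The "corrected" anisotropy isotherm is the exact quadratic solution of
  the 1:1 equilibrium, evaluated in the cancellation-free form
  `f = 2P/(P+L+Kd+sqrt((P+L+Kd)²−4PL))`, which reduces smoothly to the
  hyperbola as L → 0. With 5 nM labeled tRNA and Kd ≥ ~50 nM the depletion
  correction is small (<3% on Kd) but retained. An intensity-weighted
  mixing with bound/free intensity ratio q is available; q defaults to 1
  and is fitted only when intensities are supplied, since the assays
  modeled here do not determine it.
* The melting model is the empirical Hill form applied to temperature in
  °C — apparent Tm and n are only reproducible on that scale; no
  thermodynamic (van 't Hoff) interpretation is implied. All four
  parameters (CDmin, CDmax, Tm, n) float; the signed signals are fitted
  directly so either melting direction works. (T/Tm)ⁿ is evaluated as a
  ratio power to avoid overflow at large n. A curve whose range is below
  5× the point-to-point noise estimate is rejected as transition-free, and
  a Tm at the grid boundary is flagged unreliable.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *reduced observables* of each assay on its
standard design: progress curves to ~15% conversion on the 0.5–16 µM
(100 nM enzyme) and 0.063–2 µM (10 nM) layouts; titrations of 5 nM labeled
tRNA with a 2-fold protein dilution series from Kd/10 past 30·Kd; melts
over 20–90 °C in 2 °C steps; exchange sampled every 6 min over 30 min.
Default noise magnitudes (anisotropy σ = 0.005 absolute; CD σ = 2% of
range; product σ = 5% relative; exchange σ = 3% absolute) are chosen to
resemble the scatter class of typical published figures and are otherwise
arbitrary. Draws outside physical ranges (negative concentrations,
anisotropy outside (0, 0.4]) are re-sampled seed-stably.

Passing recovery tests on these data therefore demonstrates that the
fitters are unbiased and correctly implemented under Gaussian,
independent, design-complete conditions. They do not demonstrate
robustness to what real instruments add: correlated baseline drift,
pipetting errors shared across a dilution series, scintillation counting
statistics, photobleaching, or aggregation above the melt transition.
Generation starts at the reduced-observable level by design.

## Problem sizes and determinism

The test suite validates each fitter with noiseless round-trips (recovery
to 0.5% or better), property checks over randomized inputs under fixed
seeds, and 200-seed Monte-Carlo recovery studies (median kcat within 3% at
5% relative noise; median Tm error < 0.5 °C at 2%-of-range noise; mean Kd
within 10% at σ_r = 0.005). These sizes make the whole suite run in well
under a minute while leaving Monte-Carlo standard errors far below the
asserted tolerances. All generators restore the session RNG state, and a
fixed seed reproduces any dataset byte-for-byte.

## Known limitations

* The shipped rate constants are a calibrated stand-in constrained by the
  apparent steady-state parameters, not a fitted microscopic rate set; many
  other parameterizations reproduce the same apparent values.
* No global fitting of raw experimental traces to the mechanism is
  provided, and no integrated-rate-equation (full progress curve) fitting.
* Binding is single-site and non-cooperative; melting is empirical; the
  exchange model tracks one label pool (no positional isotopomers).
* pH and temperature dependence of rate constants are out of scope; every
  simulated condition is isothermal.
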