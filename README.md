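# aarskin

Kinetic and biophysical analysis of glutamyl-tRNA synthetase (GluRS/ERS)
variants, for enzymologists characterizing disease-associated
aminoacyl-tRNA-synthetase mutations *in vitro*.

GluRS — like GlnRS, ArgRS and class I LysRS — activates its amino acid only
with tRNA already bound. `aarskin` encodes that mechanism explicitly as an
eight-step elementary mass-action scheme,

```
E + tRNA        <->  E·tRNA                       (1)  tRNA binding
E·tRNA + Glu    <->  E·tRNA·Glu                   (2)  Glu binding
E·tRNA·Glu + ATP <-> E·tRNA·Glu·ATP               (3)  ATP binding
E·tRNA·Glu·ATP  <->  E·tRNA·[Glu-AMP]·PPi         (4)  activation
E·tRNA·[Glu-AMP]·PPi <-> E·tRNA·[Glu-AMP] + PPi   (5)  PPi release
E·tRNA·[Glu-AMP] ->  E·[Glu-tRNA]·AMP             (6)  transfer
E·[Glu-tRNA]·AMP <-> E·[Glu-tRNA] + AMP           (7)  AMP release
E·[Glu-tRNA]    ->   E + Glu-tRNA                 (8)  product release
```

and integrates it with a stiff ODE solver (deSolve), exposing the two
observables of the standard assays: total charged tRNA (aminoacylation) and
the fraction of a ³²P pyrophosphate label appearing in ATP through reversal
of steps 4 and 3 (ATP–PPi exchange, run with 3′-oxidized nonchargeable tRNA
so step 6 is off).

Around the simulator, the package provides the complete analysis chain used
to characterize synthetase variants:

- **Steady-state kinetics** — initial rates from the low-conversion window
  of progress curves (OLS), nonlinear Michaelis–Menten fits
  (`v = kcat·E0·S/(KM+S)`, minpack.lm), replicate summaries and fold
  changes; plus `apparent_mm_scan()`, which extracts the apparent
  (kcat, KM) of any mechanism parameterization by simulated assay.
- **tRNA binding** — fluorescence-anisotropy titrations fit to the
  ligand-depletion ("corrected") isotherm, the exact quadratic solution of
  the 1:1 equilibrium (needed because the 5 nM labeled tRNA is not
  negligible against nM-range Kd), with optional bound/free
  intensity-ratio correction.
- **Thermal stability** — CD melts at 222 nm fit to the empirical Hill
  form `CD(T) = CDmin + (CDmax−CDmin)·Tⁿ/(Tmⁿ+Tⁿ)` for apparent Tm and
  cooperativity n, plus mean-residue-ellipticity conversion.
- **Synthetic data** — seeded generators emulating each assay design
  (progress curves, titrations, melts, exchange time courses) with
  physical-range-respecting noise, so every fitter is validated by
  parameter-recovery studies without any external data.

## Worked example

```r
library(aarskin)

# a synthetic anisotropy titration (Kd truth 83.7 nM, sigma_r = 0.005)
# and its depletion-isotherm fit
cur <- generate_titration(scenario_spec("WT", list(Kd = 83.7)),
                          noise_model("gaussian_absolute", 0.005, seed = 42))
fit_binding_curve(cur[[1]])
#> <binding_fit> WT: Kd = 90.5 +/- 14 nM (r_free = 0.054, r_bound = 0.184, q = 1)

# the central mechanistic experiment: slow only the Glu-activation step
# (step 4) 10-fold and rescan the apparent steady-state kinetics
run_variant_scenario(default_rates("WT"), step = 4, factor = 0.1)
#> <scenario_report> perturbation: step 4 x 0.1
#> <mm_fit> WT: kcat = 0.1677 +/- 0.0012 s^-1, KM = 1.638 +/- 0.04 uM, kcat/KM = 0.1024 uM^-1 s^-1
#> <mm_fit> WT[step4 x 0.1]: kcat = 0.01909 +/- 7.5e-05 s^-1, KM = 0.2072 +/- 0.0028 uM, kcat/KM = 0.09212 uM^-1 s^-1
#>   flags: kcat decreased = TRUE, KM decreased = TRUE, kcat/KM unchanged (within 20%) = TRUE
```

The single 10-fold slowdown of amino-acid activation lowers the turnover
number ~9-fold and the Michaelis constant ~8-fold while leaving catalytic
efficiency within 10% of the wild type — the kinetic signature by which an
activation defect is distinguished from binding or transfer defects: once
tRNA capture commits the enzyme to catalysis, kcat/KM is set by capture
alone, and a slower activation step depresses kcat and KM together.

A thermal melt fits the same way:

```r
melt <- generate_melting(scenario_spec("WT", list(Tm = 44.7, n = 10.7)),
                         noise_model("gaussian_absolute", 0.16, seed = 42))
fit_melting_curve(melt[[1]])
#> <melt_fit> WT: Tm = 44.71 +/- 0.22 C, n = 9.91 +/- 0.42
```

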