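# aquaflux

Quantitative analysis of aquaporin function in the yeast heterologous
expression system. `aquaflux` is for researchers who characterise water
channels (and their H2O2 permeation) by expressing them in aqy-null
*Saccharomyces cerevisiae* and measuring:

- **osmotic water permeability** — stopped-flow fluorescence traces of
  cell shrinkage after a hyperosmotic sorbitol shock, fitted to a single
  exponential and converted through
  `Pf = k (V0/A) / (Vw · osm_out)` (cm·s⁻¹), with the **activation
  energy** `Ea = −R · slope` from the Arrhenius plot of ln Pf vs 1/T;
- **H2O2 consumption kinetics** — first-order rate constants from the
  semi-logarithmic slope of electrode traces, in both the
  H2O2-electrode and the catalase/O2-release readouts;
- **relative membrane expression** — line profiles across the membrane
  of GFP-tagged channels,
  `(peak − mean background) / maximal fluorescence`;
- **oxidative-stress assays** — Bradford protein, endpoint molybdate
  catalase (U/mg), glutathione recycling, DCF ROS fold changes, all via
  linear standard curves;
- **survival statistics** — colony counts as percent of the untreated
  time-0 reference, compared with ANOVA and unpaired t-tests.

Because no raw instrument data are deposited for such experiments, the
package includes a first-class **synthetic-data module**: an osmometer
ODE simulator (conserved internal osmolyte, optional non-osmotic
volume), fluorescence transduction with dead time and noise, exponential
decay traces in both electrode modes, annulus cell images with exact
ground truth, assay plates and Poisson colony counts. Every estimator is
validated by parameter recovery against these generators.

## Worked example

Simulate a stopped-flow run at the published AQP5 permeability, then
recover it with the estimation chain:

```r
library(aquaflux)

cell  <- simCellSpec(Pf = 4.94e-3)          # ground-truth Pf, 5 um cell
trace <- simulateShrinkageTrace(cell, instrumentSpec(seed = 1))
trace
#> ShrinkageTrace: 1999 samples, t = [0.002, 2] s, T = 296.15 K
#>   synthetic (ground truth attached)

fit <- fitSingleExponential(trace)
fit
#> ExponentialFit: k = 2.03517 1/s, F0 = 1.004, Finf = 0.7978 (n = 1999, converged)

computePf(fit, computeGeometry(5), osmOut = 1.75)
#> PermeabilityEstimate: Pf = 0.005369 cm/s (k = 2.035 1/s, dEq = 5 um, osm_out = 1.75 osmol/L)
```

The recovered 5.37 × 10⁻³ cm·s⁻¹ sits ~8% above the generative
4.94 × 10⁻³: the known upward bias of the single-exponential description
at a 25% osmotic gradient (the relaxation accelerates as the cell
approaches equilibrium). The bias is measured and bounded by the test
suite, and vanishes in the small-shock limit — see the methods vignette.

Activation energy and H2O2 kinetics follow the same
generate-then-recover pattern:

```r
arr <- generateArrheniusSeries(6.52, 4.94e-3, 296.15, c(9, 16, 23, 34) + 273.15)
fitArrhenius(arr)
#> ArrheniusEstimate: Ea = 6.52 kcal/mol (slope -3281 K, n = 4, r2 = 1.0000)

decay <- generateDecayTrace(18, 4.13e-3, noiseSd = 0.3, seed = 1)
fitFirstOrder(decay)
#> RateEstimate (h2o2 mode): k = 0.00416906 1/s (n = 601, r2 = 0.9833, 0 below floor)

compareRates(c(1.6e-3, 1.7e-3, 1.74e-3), c(2.3e-3, 2.4e-3, 2.47e-3),
             labels = c("control", "AQP5"))$fold
#> [1] 1.422619
```

`aqp5ReferenceValues()` returns the published summary measurements
(Pf, Ea, rate constants, catalase, GSH, membrane expression for control
and AQP5 cells) used to parameterise the generators.

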