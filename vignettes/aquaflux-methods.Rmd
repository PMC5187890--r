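---
title: "Models and methods behind aquaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

`aquaflux` reimplements, as tested and reusable code, the quantitative
analysis chain used to characterise an aquaporin expressed in aqy-null
yeast: osmotic water permeability and its activation energy from
stopped-flow shrinkage traces, first-order hydrogen peroxide consumption
from electrode traces, relative membrane expression from fluorescence line
profiles, colorimetric assay reduction, and the survival/comparison
statistics. Because the wet-lab instruments are not available, a
synthetic-data module generates every input with known ground truth, so
each estimator in the chain is validated by parameter recovery.

## The osmometer forward model

A yeast cell loaded with carboxyfluorescein and exposed to a hyperosmotic
sorbitol shock loses water until its internal osmolarity matches the
medium. The simulator integrates the standard osmometer equation for a
sphere,

$$\frac{dV}{dt} = -P_f\,A\,V_w\,(osm_{out} - osm_{in}(V)), \qquad
osm_{in}(V) = osm_{in,0}\,\frac{V_0 - V_b}{V - V_b},$$

where $P_f$ (cm s$^{-1}$) is the osmotic water permeability, $A$ the
membrane area, $V_w = 18.05$ cm$^3$ mol$^{-1}$ the molar volume of water,
and $V_b$ a non-osmotic volume (solids and bound water). Osmolarities are
supplied in osmol L$^{-1}$ and converted to mol cm$^{-3}$ internally. The
internal osmolyte amount $osm_{in}(V)(V - V_b)$ is conserved exactly by
construction, and the test suite verifies that the numerical trajectories
preserve it to better than $10^{-6}$ relative drift. The experimental
protocol mixes equal volumes of cell suspension (1.4 osmol/L buffer) and
2.1 osmol/L buffer, so the default shock is $1.4 \to 1.75$ osmol/L.

The measurement itself never observes volume directly: the entrapped
fluorophore self-quenches as the cell shrinks, so the instrument model
applies an affine transduction $F(t) = offset + gain \cdot V(t)/V_0$ plus
i.i.d. Gaussian noise, and discards samples before the 2 ms instrument
dead time. The default non-osmotic fraction is 0, which makes the
linearised single-exponential description an exactly nested case of the
simulator — this is what lets the nonlinear simulator serve as an
independent oracle for the estimator below.

## The estimation chain

The estimator mirrors the classical stopped-flow workflow. The recorded
signal is fitted to a single exponential
$F(t) = F_\infty + (F_0 - F_\infty)e^{-kt}$ (Levenberg–Marquardt, starting
values from a log-linearisation, bounded restarts over a ladder of initial
rates), and the rate constant is converted through

$$P_f = k\,\frac{V_0/A}{V_w\,osm_{out}},$$

with the cell treated as a sphere whose diameter is the average of its
maximum and minimum measured dimensions, so $V_0/A = d_{eq}/6$. The
default fixture diameter is 5 µm — a typical yeast cell — and every
computed estimate stores the geometry it used. Replicates are aggregated
fit-first: each run is fitted on its own and $P_f$ values are averaged per
condition (mean, $n-1$ SD; a singleton group reports SD as missing rather
than 0).

The activation energy comes from ordinary least squares of $\ln P_f$ on
$1/T$: $E_a = -R \cdot slope$ with $R = 1.9872 \times 10^{-3}$
kcal mol$^{-1}$ K$^{-1}$. All temperatures are Kelvin internally; Celsius
inputs must be declared explicitly, and Kelvin-labelled values below 200
are rejected as almost certainly mislabelled Celsius.

### Bias of the linearised estimator, and the acquisition window

The single-exponential description is exact only in the small-shock limit.
At the experimental shock (1.4 → 1.75 osmol/L, a 25% gradient) the local
relaxation rate increases as the cell approaches equilibrium (by the
factor $osm_{out}/osm_{in,0}$), so the fitted $k$ — and hence the
recovered $P_f$ — is biased upward, and the bias grows with the length of
the fitted window because late, faster samples dominate. With the default
acquisition window of 2 s (about six relaxation half-times at the
aquaporin-mediated rate, signal >98% equilibrated, 1 kHz sampling) the
measured bias is about +8%; windows of 5–10 s push it to +11–12%. The
package treats this as a property of the published estimator, measured and
reported by the test suite rather than corrected: in the small-shock
regime (1% gradient) the same chain recovers $P_f$ to within 1%.

## Hydrogen peroxide consumption kinetics

Extracellular H$_2$O$_2$ decays exponentially when consumed by cells, and
both electrode readouts reduce to the same first-order rate constant. The
generator produces $C(t) = C_0 e^{-kt}$ plus Gaussian noise; in
oxygen-release mode the stored series is $C(t)/2$, the O$_2$ burst
produced when exogenous catalase dismutates the remaining peroxide
(2 H$_2$O$_2$ → 2 H$_2$O + O$_2$). The estimator is deliberately the
plot-slope method — ordinary least squares of $\ln C$ on $t$ — rather than
a nonlinear exponential fit, for fidelity to the published procedure; the
nonlinear grid fit is retained in the tests as a cross-checking oracle
(agreement within 3% on noisy traces). Points at or below a floor
(default 2% of the nominal starting concentration) are excluded from the
log transform and counted. The semi-log slope is invariant to uniform
rescaling of concentration, so electrode gain calibration cancels — this
is asserted as a property test. Background autodegradation subtraction is
available (`blankCorrectRate()`) but off by default, since the reference
measurements used intact cells only.

## Line-profile membrane expression

Relative membrane expression of the GFP-tagged channel is quantified
exactly as in the manual imaging workflow: a line is drawn across the
cell membrane, the mean background intensity measured along a cell-free
line of the same length is subtracted from the peak intensity on the
line, and the difference is divided by the maximal fluorescence:

$$value = \frac{\max(\text{profile}) - \overline{\text{background}}}
{F_{max}} \in [0, 1].$$

Design choices where the manual procedure is ambiguous: "maximal
fluorescence" is per-image (the analysed image's maximum, or a known
detector full-scale) with a per-profile alternative behind
`normalize = "profile"`; the background is a matched line, not a region
mean; the peak is the maximum sample with no sub-pixel refinement; line
sampling uses bilinear interpolation at unit-pixel spacing on 0-based
pixel-centre coordinates. Three lines per cell are averaged, and cohort
statistics (mean ± SD) are computed across cells, never across pooled
lines; fewer than 30 cells triggers a warning.

The image generator renders a hard annulus whose peak equals
$background + expression \cdot F_{max}$, so the noiseless, unblurred chain
returns the true expression exactly. Gaussian blur (the point-spread
proxy) lowers the peak and biases the estimate downward — measurably and
monotonically in the blur width. With the default geometry (radius 12 px,
ring width 5 px) a 1 px blur keeps the bias within the ±0.05 recovery
band checked by the Monte-Carlo tests; the bias, not hidden, is simply
small at realistic blur.

## Colorimetric assays

All four plate assays (Bradford protein, endpoint molybdate catalase,
glutathione recycling, DCF ROS) reduce through the same linear standard
curve: OLS of reading on concentration, inverse prediction
$(reading - intercept)/slope$, extrapolation beyond 1.1× the standard
range flagged. Catalase activity uses the unit definition directly:
µmol H$_2$O$_2$ consumed (mM × mL) over the 5 min reaction, per mg
protein; the effective assay volume is an explicit parameter (default
0.1 mL) because the published reaction volumes are incomplete, and every
result records the parameters used. The glutathione result carries its
concentration unit label verbatim from configuration — the reference
sources mix µM- and nmol-based labels, so the package refuses to guess a
conversion. DCF time courses are reduced to fold change over the
pre-treatment baseline, background-uncorrected by default, with per-time
t-tests across groups.

## Survival and the comparison layer

Acute-stress survival is the colony count at each time expressed as a
percentage of the time-0 untreated reference of the same strain and
replicate; group SD is across biological replicates. The synthetic
generator draws counts from Poisson($n_0 \cdot$ fraction), the natural
dispersion model for colony counting. The comparison layer is the
classical one: one-way ANOVA as the gate, then two-sided unpaired
t-tests — pooled-variance Student by default (Welch behind a flag), no
multiple-testing correction by default (a Bonferroni option exists), and
the conventional star mapping (* p < 0.05, ** p < 0.01, *** p < 0.001)
implemented as a single pure function used by every table and figure.
Degenerate comparisons (both groups constant and equal) report p = 1 with
a warning. The t-test's type-I error is verified on 2,000 null
simulations to land in [0.04, 0.06] at α = 0.05.

## What the synthetic data do and do not show

The generators emulate the instruments' sampling, noise and transduction,
with every random draw flowing from one explicit seed (bit-identical
regeneration is a tested contract). They do not emulate cell-to-cell
heterogeneity in size or expression, electrode drift, photobleaching,
out-of-focus light or segmentation ambiguity. Passing recovery tests
therefore demonstrate that the estimators are correct implementations
with quantified bias under the stated noise models — not that those noise
models exhaust real instrument behaviour.

Problem sizes were chosen to keep the full suite fast while leaving the
Monte-Carlo checks statistically meaningful: 2 s × 1 kHz shrinkage
traces, 600 s × 1 Hz electrode traces (200 seeds per rate constant),
64×64 px images (30-cell cohorts), 200–500 seeds for assay, survival and
power checks, and 2,000 null simulations for the type-I error band.

## Reference values

`aqp5ReferenceValues()` ships the published summary measurements (Pf, Ea,
rate constants, catalase, glutathione, membrane expression for control and
AQP5-expressing cells) that parameterise the generators and anchor the
derived-quantity checks. One printed inconsistency is worth noting: in the
source's oxygen-electrode passage the control and AQP5 labels are attached
to values contradicting the stated direction of the 1.4-fold increase; the
table follows the stated direction (control 1.68 × 10$^{-3}$ s$^{-1}$,
AQP5 2.39 × 10$^{-3}$ s$^{-1}$), and `compareRates()` always reports folds
by explicit group labels rather than reordering.

## Known limitations

Single-exponential shrinkage only (no multi-exponential or stretched
models, no hypo-osmotic swelling, no solute permeability); no
Michaelis–Menten saturation in the peroxide kinetics; no automated cell
segmentation (lines are inputs, as in the manual procedure); linear
standard curves only; no survival-curve model fitting — the chronic
spot-dilution assay is handled only as an archived dilution-series table.
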