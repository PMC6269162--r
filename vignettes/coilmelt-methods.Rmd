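---
title: "coilmelt: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coilmelt: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilmelt)
```

`coilmelt` analyses three readouts of coiled-coil tropomyosin
biochemistry: CD melting traces, actin co-sedimentation densitometry, and
the heptad structure of the sequence itself. This vignette records the
models behind each stage, the parameters that matter, and the design
choices made where the methodology was genuinely open.

## The thermal unfolding model

A melt is modelled as one or two independent two-state transitions. Each
transition has an unfolding equilibrium constant
$K_i(T) = \exp\!\left[\frac{|\Delta H_i|}{R}\left(\frac{1}{T_{m,i}} -
\frac{1}{T}\right)\right]$ (temperatures in kelvin, $R = 8.314$ J mol⁻¹
K⁻¹), giving an unfolded fraction $f_i = K_i/(1+K_i)$ that equals 1/2 at
$T_{m,i}$ and has midpoint slope $|\Delta H_i|/(4RT_{m,i}^2)$. The
observed fraction is the amplitude-weighted sum $f = \sum_i a_i f_i$ with
$\sum a_i = 1$, and the raw CD signal mixes linear folded/unfolded
baselines by $f$.

Assumptions worth stating explicitly:

* **Independence.** Biphasic melts of the acetylated destabilised mutants
  are treated as two regions of the dimer unfolding independently; no
  coupling term is fitted. Whether the two transitions are truly
  thermodynamically independent is a modelling choice, not something the
  data here can establish.
* **Pure van't Hoff.** $\Delta C_p = 0$: one enthalpy per transition,
  which is how single-wavelength CD melts of short coiled coils are
  conventionally summarised. Curvature of $\ln K$ with temperature is not
  modelled.
* **Sign convention.** Enthalpies are *stored* as magnitudes (so $K$
  increases with temperature, as an unfolding constant must) and
  *reported* negative, following the convention of the CD literature this
  package serves. `transitionTable()` accepts either sign.
* **Reversibility.** Refolding is assumed complete (as repeated melts of
  these proteins show); hysteresis is out of scope.

Interfaces use °C throughout; kelvin appears only inside the model.

## Melt analysis pipeline

**Normalization.** `normalizeMelt()` maps the 222 nm signal to fraction
unfolded over a window, 10–50 °C by default. The default `"minmax"` mode
takes the window extrema of a lightly smoothed copy of the signal as the
folded/unfolded references, with the low-temperature end as folded (the
orientation is detected, so both CD sign conventions work). A `"linear"`
mode fits baselines to the first and last 15 % of the window for data
with sloped baselines. The result is clamped to [0, 1]; a flat trace
(references equal within ~10⁻⁸ of the signal scale) is a degenerate-curve
error rather than a silent division.

**Smoothing and differentiation.** `firstDerivative()` applies a centered
moving mean — the half-window shrinks symmetrically at the edges, so
linear signals are differentiated exactly everywhere — and uses central
differences (one-sided at the endpoints). The default 1.0 °C window is a
compromise: derivatives of noisy fractions need smoothing, and 1 °C is
well below the ≳ 3 °C width of even the sharpest transitions analysed
here, so peak positions are not biased at the 0.1 °C level that matters.
The window is a configuration knob.

**Gaussian deconvolution.** `fitGaussians()` fits a sum of one or two
Gaussians (mean, sd, area) to the derivative by bounded
Levenberg–Marquardt. Starting means come from greedy peak-picking on a
re-smoothed copy of the derivative with a 2 °C exclusion radius — without
the exclusion, two noise ripples on one transition can seed both
components and strand the optimiser in a poor local minimum. Ties break
toward lower temperature, restarts are deterministic, sds are bounded
below by the grid spacing (a collapse onto one point is flagged), and
fitted areas are renormalized to sum to 1. Each component's mean is its
melting temperature; a secondary enthalpy estimate
$|\Delta H| = 4RT_m^2\,(\text{height}/\text{area})$ is derived from the
peak height.

**Model selection.** `selectNComponents()` returns 2 only if (a) the
two-component fit improves a small-sample-corrected information criterion
(AICc) by more than 10 and (b) the two means are separated by more than
twice the larger sd. Because the moving-mean smoother correlates
neighbouring derivative points, the criterion is evaluated at the
effective sample size $n_\mathrm{eff} = n/k$ ($k$ = smoothing points);
with the raw $n$, the criterion over-counts independent observations and
will happily buy a second component that absorbs smoothed noise. With
these defaults the selector picks 2 for the biphasic acetylated-mutant
parameter sets even at realistic noise, and across 100 noisy
single-transition simulations it never invents a second component (both
properties are in the test suite). Transitions closer than about twice
the transition width — e.g. 1 °C apart — are reported as a single
component: they are genuinely unresolvable from a 222 nm melt.

**Direct van't Hoff fit.** `fitVantHoff()` refines $T_m$, $\Delta H$ and
amplitudes by fitting the thermodynamic model itself to the normalized
fraction, initialized from the Gaussian stage. One subtlety matters: the
data were min-max normalized over a finite window, and for a transition
near the window edge (e.g. a $T_m$ of 43 °C against a 50 °C window edge)
the true fraction only reaches ≈ 0.98 at the window top, so the
normalized data are a slightly stretched version of the model curve. The
fitter therefore passes its prediction through the *identical*
normalization operator before forming residuals. This makes noise-free
recovery exact and removes a ~1 % enthalpy bias that fitting the raw
model would incur. |ΔH| is bounded to [50, 1500] kJ mol⁻¹; estimates
pinned at a bound are flagged, not hidden. The direct fit is the
canonical enthalpy; the Gaussian peak-height estimate is exposed for
comparison because published tables rarely state which route produced
them.

**Replicates** are averaged pointwise after linear interpolation onto the
first replicate's grid, mirroring the usual practice of averaging three
melts before analysis.

## Binding analysis

`saturationFromDensity()` converts the Tpm/actin pellet band density
ratio to fractional saturation against a full-saturation calibration
ratio. The `"auto"` calibration uses the mean ratio of the two highest
Tpm concentrations — appropriate when the titration visibly plateaus. When
the series does not reach saturation (a K50 of a few μM against a 16 μM
top concentration leaves θ ≈ 0.85), auto-calibration rescales θ upward;
if the true calibration is known (as it is for simulated data, or from an
independent gel) it should be supplied instead. θ_max is fitted, bounded
at 1.05, rather than fixed at 1, because densitometry plateaus under- and
overshoot.

`freeTpm()` applies the depletion correction
$\mathrm{free} = \mathrm{total} - \theta\,[\mathrm{actin}]/s$, floored at
zero. The stoichiometry $s$ (actin monomers per bound Tpm dimer) defaults
to 4, the span of a short yeast tropomyosin on the filament; it is a
visible configuration knob because the measurement is an apparent
affinity for a polymerising ligand, not a true single-site constant, and
the choice of $s$ propagates into K50 at high saturation. Large negative
computed free concentrations trigger a calibration warning.

`fitHill()` estimates $(K_{50}, n, \theta_{max})$ by bounded least
squares in $\log K_{50}$ and $\log n$ (positivity by construction), with
$K_{50} \le 10\times$ the largest free concentration and
$n \in [0.2, 10]$. The K50 standard error comes from the fit covariance
by the delta method. A series whose θ range never traverses a transition
is rejected as unidentifiable. The test suite pins the fit against an
exhaustive 0.001-resolution grid search on a 5-point series.

## Sequence annotation

Registers are pure cyclic arithmetic: the letter at position $i$ is
determined by the anchor and $(i - \mathrm{anchor}) \bmod 7$. With
several anchors in one segment, consistency is checked and contradictions
raise a register-conflict error naming both anchors. This is deliberate:
for Cdc8 the published register assignments at the two ends of the
protein (A18 at *d*, E129 at *g*) are mutually inconsistent under a
single continuous heptad — 18 = d forces 129 = c — and the local sequence
R128-E129-R130 (R130 at *a*) is itself unlikely to form standard coiled
coil. The package therefore supports piecewise segments, each with its
own anchor, and surfaces the conflict rather than resolving it silently.

Residues partition into charged− (D, E), charged+ (K, R, and H by a
toggle — histidine's charge is pH-dependent), hydrophobic (M, L, I, V, F,
W, Y), small (A, S, T, G) and other. Core clusters are maximal runs of
small residues along the a/d positions flanked by hydrophobic-occupied
core positions — a heptad-level rendering of hydrophobic-cluster analysis
that captures the alanine cluster (11, 15, 18, 22, 25 under an 18 = d
register) testably without drawing a 2-D helical net. Charge pairs are
enumerated at i, i+3 and i, i+4 within a helix, and between each
g-position residue and the partner chain's next e position (i+5), the
standard parallel in-register homodimer geometry. Mutation reports
classify by heptad letter first (a/d → core-packing, e/g →
interchain-bridge), then by whether any helical-turn charge pair changed
(intra-helix-pair), else surface.

## The synthetic-data generator

The generator is the package's test bed and defines its study
conditions:

* **Melts**: the forward model on a 10–50 °C grid at 0.1 °C (a 1 °C/min
  scan sampled continuously) with additive iid Gaussian noise in signal
  units; replicate $r$ is seeded `seed + r`. The reference parameter set
  (`cdc8Parameters()`) carries the ten protein × acetylation states at
  0.5 M salt, with the biphasic acetylated mutants at a 0.6/0.4 amplitude
  split. No noise magnitude is published for the source instrument;
  0.005 signal units reproduces the visual quality of typical traces and
  is a documented assumption. Low-salt parameters are excluded: the
  published low-salt entries are internally ambiguous (two values for a
  single-transition protein, and a stated shift that does not match the
  table).
* **Binding**: for each total Tpm the free concentration solves the mass
  balance $\mathrm{free} + \theta(\mathrm{free})\,[\mathrm{actin}]/s =
  \mathrm{total}$ by bisection (tolerance well below 1e-9 μM; the
  monotone objective makes failure impossible for valid inputs), and band
  densities are emitted with multiplicative Gaussian noise of configurable
  CV. Default series: 10 points log-spaced over 0.2–16 μM at 10 μM actin.
  The Hill coefficient of the source binding curves is not published;
  1.5 is used as a mildly cooperative default.
* **Sequences**: deterministic fill by heptad letter (L at a/d, E/K
  alternating at e/g, A elsewhere) with explicit placements layered on
  top, so the true annotation is known by construction.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: baseline drift and 1/f instrument noise
(residuals are iid here), aggregation or incomplete refolding, CD
spectral shape away from 222 nm, gel-lane artefacts behind the density
numbers, and any temperature dependence of binding.

## Numerical choices and problem sizes

Optimisation is bounded Levenberg–Marquardt (`minpack.lm`) everywhere,
with deterministic initialisation and restarts; no randomness enters any
fit. Degenerate inputs (flat melts, unsampled binding transitions,
contradictory anchors, synonymous mutations) produce typed errors or
flagged no-ops rather than numbers. The test suite simulates at the sizes
the analyses are designed for — 401-point melts, 100-seed noise sweeps
for the Tm-error and false-positive properties, 200-seed saturation bias
checks — and completes in well under a minute; the replica run
(`runReplica()`) covers all ten reference states noise-free and verifies
every Tm to 0.3 °C and every |ΔH| to 2 %.

## Known limitations

* Two transitions are the ceiling; melts with three resolvable phases are
  outside the model.
* The Hill treatment is phenomenological: no end-to-end polymerisation
  (Ising/McGhee–von Hippel) model of Tpm on actin, so K50 is an apparent
  half-saturation, as the assay itself warns.
* Register inference from sequence alone is out of scope; anchors are
  user knowledge.
* Salt concentration and assay temperature travel as metadata only; no
  thermodynamic salt dependence is modelled.
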