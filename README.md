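# coilmelt

Quantitative analysis of thermal stability and actin binding for
coiled-coil tropomyosins, built around the temperature-sensitive variants
of the single essential fission-yeast (*Schizosaccharomyces pombe*)
tropomyosin Cdc8. Point substitutions (A18T, E31K, E129K and the A18T/E31K
double) and N-terminal acetylation shift the protein's melting behaviour
and its affinity for actin; `coilmelt` turns the three raw readouts of
such a study — circular-dichroism (CD) melting traces at 222 nm,
co-sedimentation gel densitometry, and the protein sequence — into the
numbers that describe them.

## What it computes

**Thermal unfolding.** A melt is modelled as one or a weighted sum of two
independent two-state van't Hoff transitions. For each transition,

    K(T) = exp[ (|ΔH|/R) (1/Tm − 1/T) ],   f_i(T) = K/(1+K),
    f(T) = Σ_i a_i f_i(T),

with `T` in kelvin, `Tm` the melting temperature (`f_i(Tm) = 1/2`), `ΔH`
the van't Hoff enthalpy setting the steepness (`df/dT|Tm = ΔH/(4RTm²)`),
and amplitudes `a_i` summing to 1. The analysis pipeline normalizes the
222 nm trace to fraction unfolded over 10–50 °C, computes a smoothed first
derivative, fits one or two Gaussians to locate the midpoints, selects the
number of transitions with a corrected information criterion plus a
peak-separation guard, and refines `Tm`, `ΔH` and amplitudes by a direct
fit of the van't Hoff model. Enthalpies are reported with the negative
sign convention used for these CD melts.

**Actin binding.** Co-sedimentation band densities become fractional
saturation θ via the density ratio against a full-saturation calibration;
free tropomyosin is obtained by bound subtraction with a configurable
actin:Tpm stoichiometry (default 4 monomers per dimer); the Hill equation

    θ(free) = θmax · free^n / (K50^n + free^n)

is fitted to yield the half-saturation constant `K50` and the Hill
coefficient `n`.

**Coiled-coil annotation.** Heptad register letters (a–g) are propagated
from user-supplied anchors; residues are classified by charge and
hydrophobicity; core alanine clusters, intra-helix (i, i+3 / i, i+4)
charge pairs and inter-chain g–e′ salt bridges are detected; and each
point substitution gets a structural report (core-packing,
intra-helix-pair, interchain-bridge or surface).

**Synthetic data.** Seeded generators produce melts (forward model +
Gaussian noise), mass-balance-consistent binding series, and
register-bearing sequences with known ground truth, so every stage is
testable offline.

## Worked example

Simulate three noisy replicates of a biphasic acetylated-mutant melt
(transitions at 29.2 and 43.2 °C with a 60/40 amplitude split) and recover
its parameters, then a noisy binding series, then a mutation report:

```r
library(coilmelt)

m <- UnfoldingModel(tm = c(29.2, 43.2), dh = c(-256.8, -466.2),
                    amplitude = c(0.6, 0.4))
fitMeltCurve(simulateMelt(m, noiseSd = 0.005, seed = 2, replicates = 3))
#> MeltFitResult: 2 component(s), rss = 0.00425
#>   Tm = 29.2 C, dH = -252.2 kJ/mol, amplitude = 0.60
#>   Tm = 43.2 C, dH = -468.6 kJ/mol, amplitude = 0.40

s <- simulateBinding(2.54, densityNoiseCv = 0.03, seed = 2)
s <- saturationFromDensity(s, calibrationRatio = s@meta$truth$calibrationRatio)
s <- freeTpm(s)
fitHill(s)
#> HillFit: K50 = 2.50 +/- 0.20 uM, n = 1.55, thetaMax = 1.01

fx <- simulateSequence(35, 18, "d", placements = list("28" = "K", "31" = "E"))
annotateMutation(fx$annotation, 31, "K")
#> MutationReport: E31K (heptad c) -> intra-helix-pair
#>   local context: A30 E31 L32
```

The melt fit recovers both midpoints to within 0.1 °C and the amplitude
split; the Hill fit returns the half-saturation constant with its standard
error; the mutation report shows that E31K sits at a surface c position
but flips the K28–E31 helical-turn attraction into a repulsion.

A full simulate-and-recover run over the bundled reference parameter set
(`cdc8Parameters()`, ten protein × acetylation states) is one call:
`runReplica(outDir = "report")`.

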