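# baroshift

Pressure-resolved NMR and trajectory-dynamics analysis of protein
conformational subensembles, built around the amyloidogenic D76N variant of
β2-microglobulin (β2m).

## The problem

β2m causes dialysis-related amyloidosis, and its naturally occurring D76N
variant is markedly less stable and more aggregation-prone even though the
WT and mutant crystal structures are essentially identical. The differences
live in the *dynamics*: in how the conformational ensemble redistributes
under perturbation. Two complementary probes expose this — hydrostatic
pressure, which shifts the population balance toward otherwise invisible
excited states, and molecular-dynamics trajectories, which resolve the
subensembles directly. `baroshift` implements the full analysis chain for
both, together with synthetic-data generators that emulate each measurement
with known ground truth, so every estimator in the pipeline can be validated
end to end.

## What it computes

**Chemical-shift decomposition.** A series of ¹H–¹⁵N HSQC peak lists over
pressure is assembled into a 2R×P matrix **X** (one ¹H row and one ¹⁵N row
per traceable residue; nitrogen rows scaled by 1/5 so the row metric matches
the apparent shift difference Δδ_app = (ΔδH² + (ΔδN/5)²)^½). After
subtracting the lowest-pressure column, an SVD

&nbsp;&nbsp;&nbsp;&nbsp;X_c = U Σ Vᵀ

places each pressure point in PC space (scores ΣVᵀ). The unit secant of the
first pressure step defines the direction of **(i) mechanical compression**
(within-state compaction, linear in p); its +90° rotation defines **(ii)
thermodynamic transition** (population shift between states). Back-projecting
each direction through U gives per-residue Δδ patterns for the two
components.

**Relaxation and exchange.** Mono-exponential fits I(t) = A·e^(−kt) for R₂
series (seven delays, 17.6–228.8 ms) and H/D-exchange decays; an
aggregation correction (k_ex = k_obs/k_agg, or the additive-channel
difference) for variants that aggregate during exchange; Bai-type
nearest-neighbour prediction of intrinsic rates k_int; and protection
factors P = k_int/k_ex.

**Trajectory dynamics.** Backbone (φ, ψ) dihedral distributions on a fixed
10×10 grid of 36° bins and the χ² statistic

&nbsp;&nbsp;&nbsp;&nbsp;χ² = (1/n²) Σᵢ Σⱼ (f₁(φᵢ,ψⱼ) − f₂(φᵢ,ψⱼ))², n = 10;

RMSF and PCA modes after iterative mean-structure superposition; the dynamic
cross-correlation matrix C_ij = ⟨Δr_i·Δr_j⟩/(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)^½;
side-chain distance series (e.g. D76 Oδ2 – K41 Nζ); kernel-density
segmentation of a distance distribution into subensembles; and the
subensemble-conditioned χ² that flags residues whose backbone conformation
is coupled to the local interaction mode.

**pH-unfolding fits.** Base-10 logistic fits
S(pH) = S_f + (S_u − S_f)/(1 + 10^(m(pH − pH_mid))) of tryptophan
fluorescence titrations.

Condition presets `WT_AP`, `D76N_AP` and `WT_HP` (ambient/high pressure)
ship as plain-text parameter files and are the single source of ground truth
for all recovery tests.

## Worked example

```r
library(baroshift)

pre    <- loadPreset("WT_AP")
series <- genPressureSeries(pre$shiftModel, pre$pressures, pre$noiseSd, seed = 1)
series
#> PressureSeries: 10 pressure points (5.0-225.0 MPa), 82 traceable residues

dec <- decomposePressureSeries(series)
dec
#> ShiftDecomposition: 9 singular values above tolerance; PC1 97.8%, PC2 2.1% of variance

head(round(singularValues(dec), 4))
#> [1] 1.9411 0.2850 0.0242 0.0221 0.0216 0.0200

head(dec@patternII[order(-dec@patternII$delta_app),
                   c("residue", "dH", "dN", "delta_app")], 5)
#>  residue      dH     dN delta_app
#>        9  0.1729 -0.576     0.208
#>       10  0.1650  0.475     0.190
#>       55 -0.0928  0.808     0.186
#>       56  0.1060  0.750     0.184
#>       36  0.0830  0.791     0.179
```

The 82 traceable residues over 10 pressures give a 164×10 matrix; after
first-column centering, 9 informative singular values remain, with the
compression component carrying ~98% of the variance. The transition pattern
(`patternII`) peaks at the A-, C- and D-strand residues that the preset
plants as the pressure-responsive set — the same residues the mutation
perturbs. Refitting noisy synthetic titrations recovers the preset unfolding
midpoint:

```r
rec <- titrationRecovery(4.11, nSeeds = 100, seed = 1)
sprintf("mean refit midpoint: %.3f (sd %.3f)", rec$mean, rec$sd)
#> "mean refit midpoint: 4.109 (sd 0.009)"
```

A full simulate-and-analyse run for one condition, with a checksummed
manifest, is one call:

```r
runPipeline(runConfig("WT_AP", "out_wt", seed = 1, nFrames = 10000))
```

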