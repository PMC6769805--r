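---
title: "baroshift: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{baroshift: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroshift)
```

`baroshift` analyses two kinds of evidence about a protein's conformational
ensemble — pressure-dependent NMR chemical shifts and coordinate
trajectories — and ships synthetic-data generators that emulate both with
known ground truth. This vignette is the package's own account of the
underlying models, the estimators, the tunable parameters, and the choices
made where the design was genuinely open.

## The two-state pressure-response model

A backbone amide's observed chemical shift under pressure p (MPa) is modelled
per residue and per axis (¹H, ¹⁵N) as

$$\delta_{obs}(p) = \delta_0 + s\,p + f_E(p)\,a + \varepsilon,$$

where s is a compression slope (ppm/MPa), a is a transition amplitude (ppm),
and

$$f_E(p) = \frac{1}{1 + \exp\!\big((\Delta G_0 + p\,\Delta V)/(RT)\big)}$$

is the Boltzmann population of an excited state whose free-energy gap varies
linearly with pressure (R = 8.314 J mol⁻¹ K⁻¹; 1 MPa·mL/mol ≡ 1 J/mol, so
ΔV in mL/mol needs no unit conversion). With ΔV < 0 the excited state is
favoured by pressure and f_E rises monotonically. The linear term emulates
within-state mechanical compression; the population term emulates the
thermodynamic transition between subensembles. The preset thermodynamics are
ΔG₀ = 15 kJ/mol, ΔV = −100 mL/mol, T = 298 K, placing the transition
midpoint at 150 MPa — inside the sampled 5–225 MPa range, with the first
pressure step (5 → 29 MPa) almost purely compressive. That separation is
deliberate: the decomposition procedure identifies the compression direction
from the initial spectral change, so the study conditions must make the first
step compression-dominated, as a structured protein's low-pressure response
is expected to be.

The ten sampled pressures run evenly from 5 to 225 MPa (the lowest point is
5 MPa rather than ambient, the practical floor for avoiding bubble formation
in a pressure cell). The default measurement noise is 0.002 ppm per axis —
no noise magnitudes are stated for the original measurements, so this is a
convention of the package, chosen as a typical HSQC peak-position
uncertainty at 600 MHz; it is small against the planted amplitudes (up to
0.2 ppm ¹H, 1 ppm ¹⁵N) but not negligible against the compression steps.

Per-residue parameters for the three condition presets (`WT_AP`, `D76N_AP`,
`WT_HP`) live in plain-text tables under `inst/extdata/presets/` and are the
single source of ground truth for every recovery test. The WT preset plants
transition amplitudes on the A-, C- and D-strand residues; the mutant preset
has (near-)zero transition amplitudes and instead carries static shift
offsets on the K41/D76 contact network, so a WT-vs-mutant peak comparison and
a WT pressure decomposition highlight the same residue set. Every generator
draws each residue's noise from an independent substream seeded from
(seed, residue id), so adding residues to a model never perturbs the
existing ones.

## Shift-matrix assembly, SVD and direction identification

The traceable set is the intersection of residue ids across all pressure
points (82 of 99 residues in the presets; the N-terminus, prolines and
fast-exchanging loop positions are absent). Assembly produces a 2R×P matrix,
residue-major (¹H row then ¹⁵N row), with nitrogen rows multiplied by 1/5 so
Euclidean distance in row space equals the apparent shift difference
Δδ_app = (ΔδH² + (ΔδN/5)²)^½. The matrix-stage nitrogen scaling is this
package's choice (the display convention for Δδ patterns divides ¹⁵N by 5;
applying the same weight at assembly makes the PC metric consistent with it);
the factor is recorded in the object and undone when patterns are reported in
ppm.

**Centering.** Columns are centered by subtracting the first
(lowest-pressure) column, so the origin of the PC plane is the 5 MPa
spectrum and each score traces the displacement from the initial conditions.
Column-mean centering is available as an option. First-column centering
forces the centered rank to at most P−1, hence the expected nine informative
singular values for ten pressure points; the singular-value tolerance is
1e-10 × the largest singular value.

**Directions.** The compression direction v_i is the unit secant from the
first to the second score in the (PC1, PC2) plane — the initial spectral
change. Nothing in the source analysis specifies how "initial" is estimated,
so the secant of the two lowest pressures is the default and a least-squares
fit over the first m points is available (`nSecant`). The transition
direction v_ii is v_i rotated +90°, sign-fixed so the total change (last
minus first score) projects non-negatively onto it. PC1's sign is fixed by
requiring a non-negative PC1 score for the highest-pressure point.

**Patterns.** A direction v is back-projected as w = U[,1:2]·v and scaled by
the score range along v (max − min projection). The amplitude normalisation
of back-projected patterns is not uniquely determined by the procedure; the
score-range scaling is this package's convention, chosen so a rank-1 series
reproduces slope × pressure-range exactly. Patterns report ΔδH, ΔδN in ppm,
ΔδN/5 as conventionally plotted, and Δδ_app.

On the noiseless two-component preset the recovered compression and
transition patterns match the planted slope and amplitude loadings with
cosine similarity above 0.99; with the two loadings drawn independently in a
164-dimensional row space their residual overlap (~0.08) bounds how exactly
the orthogonality assumption can hold, which is the dominant error term.

## Peak tracking

Assignments are propagated across pressure by nearest-neighbour chaining
under the Δδ_app metric with a per-step ceiling (`maxStep`, default
0.05 ppm — about twice a typical transition-region step in the presets).
Ambiguity — two candidates within the ceiling and within 10% distance of
each other, or two tracked peaks claiming one candidate — is an error naming
the residues, never a silent tie-break; on crowded synthetic spectra (two
preset residues pass within ~0.02 ppm of each other mid-transition) the
error is the designed outcome, mirroring what a spectroscopist would have to
resolve by hand. The original study does not describe its tracing procedure;
nearest-neighbour chaining is this package's convention. Tracking is
order-stable: permuting peaks within a file cannot change the result, since
each match minimises a distance over the full candidate list.

## Relaxation, exchange and protection factors

Decays are fit as I(t) = A·e^(−kt) with the baseline fixed at zero
(single-exponential assumption), log-linear initialisation and
Levenberg–Marquardt refinement, k bounded below by zero. The R₂ preset uses
the seven-delay grid 17.6–228.8 ms (arithmetic spacing 35.2 ms). The fit is
scale-invariant in intensity, exact to 1e-6 relative on noiseless input, and
median-unbiased within 2% at 5% intensity noise.

For a variant that aggregates during H/D exchange, the observed decay
confounds amide exchange with loss of soluble protein. Two corrections are
implemented: **ratio** (k_ex = k_obs/k_agg) — the printed convention of the
source analysis, kept as the default — and **difference**
(k_ex = max(k_obs − k_agg, 0)), which is the physical expectation for
additive first-order decay channels. The ratio of two rates is
dimensionless, so the two modes are not interchangeable; the mode used is
recorded on every output and neither is asserted to be the source's intent.

Intrinsic rates use the additive nearest-neighbour model for unstructured
amides in D₂O: acid-, base- and water-catalysed channels with log-additive
side-chain corrections from the residue itself and its predecessor,
reference poly-DL-alanine rates at 20 °C, Arrhenius temperature adjustment
(activation energies 14/17/19 kcal/mol), pK_D = 15.05, and pD = reading
+ 0.4. Parameters ship as plain-text tables (`inst/extdata/hdx_*`); terminal
charge corrections are not applied (N-terminal residues and prolines are
excluded outright, as is conventional for backbone-amide analysis).
Protection factors are P = k_int/k_ex — "ratio between the observed and
intrinsic rate" is ambiguous about order, and the field convention that
protected residues have P ≫ 1 fixes it. Residues exchanging too fast to
observe are represented as missing, never as zero.

## Trajectory dynamics

**Dihedrals.** Backbone φ/ψ use the standard four-atom torsions with IUPAC
sign, reported in (−180°, 180°]. Histograms are 10×10 over fixed 36° bins
from −180°, half-open with the top edge of the last bin closed (so −180°
falls in the first bin, +180° in the last). Frequencies are fractions, not
counts — the χ² statistic

$$\chi^2 = \frac{1}{n^2}\sum_{i=1}^{n}\sum_{j=1}^{n}\big(f_1(\phi_i,\psi_j)-f_2(\phi_i,\psi_j)\big)^2,\quad n = 10$$

is then independent of frame count in expectation, which is what makes
profiles comparable across conditions with different sampling. The statistic
is validated against a brute-force double-loop oracle, exactly.

**Superposition, RMSF, PCA, DCCM.** The selection for all three is Cα,
unweighted (atom selection and mass weighting are unstated in the source;
Cα-unweighted is the common default). Frames are rigid-body fitted (Kabsch)
onto the iteratively refined mean structure, two mean–superpose rounds. The
coordinate covariance uses denominator F, so the eigenvalue sum equals the
sum of squared RMSFs exactly (the trace identity tested to 1e-6 relative).
DCCM entries are normalised displacement covariances; zero-variance atoms
yield flagged NA rows rather than silent values. The DCCM implementation is
cross-checked against an independent one (`bio3d::dccm`) in the tests.

**Subensemble segmentation.** The side-chain distance distribution is
estimated by a Gaussian KDE with Silverman's rule-of-thumb bandwidth; modes
are local maxima above 5% of the global maximum, and boundaries sit at the
density minima between consecutive modes — an automated stand-in for
boundaries that were originally drawn by eye. Frames are labelled a, b, c …
by increasing distance. The 5% threshold suppresses ripple maxima in the
tails; modes closer than about one standard deviation merge into a single
subensemble, a documented limitation of any density-based cut. On the WT
preset (states at 3/6/10 Å, sd 0.4 Å) labelling agrees with the generator's
latent states at better than 99%.

**Conditioned χ².** Per residue, the dihedral histogram is recomputed within
each subensemble and χ² evaluated for every unordered pair; the maximum is
reported alongside the full pair table, and any pair touching a subensemble
with fewer than 50 frames is flagged low-confidence. At 50 000 frames the
planted coupled residues exceed the uncoupled sampling floor by far more
than an order of magnitude, and thresholding anywhere in that gap recovers
the planted set with precision and recall of 1.

## What the generators emulate — and what they do not

The latent conformational state is a small Markov chain (three states for
WT-like presets, one for mutant/high-pressure presets, stay probability
0.995 so states persist for ~200 frames); dihedrals are state-conditional
von Mises pairs (Best–Fisher sampling); distances are state-conditional
Gaussians truncated at zero; trajectories are mean structure + orthonormal
collective modes with Gaussian amplitudes + isotropic noise, with rigid-body
components projected out of the preset mode so superposition leaves it
intact. These constructs reproduce the *statistical structure* the analyses
assume — multimodality, state-conditional coupling, low-rank collective
motion — but none of the physics: no excluded volume, no realistic
Ramachandran coupling between neighbouring residues, no solvent, no
force-field energetics. Passing recovery tests therefore demonstrates that
the estimators are correct and well-calibrated on data satisfying their
assumptions; it does not demonstrate robustness to the ways real spectra and
real trajectories violate them (peak overlap, chemical-exchange broadening,
anharmonic and correlated noise).

## Problem sizes and numerical conventions

Analyses in the tests and the acceptance script run at desk scale, chosen so
the full suite completes in a couple of minutes on one core: 82 residues ×
10 pressures for the shift decomposition; 50 000 frames for segmentation and
conditioned χ² (where the coupled/uncoupled contrast needs a low sampling
floor); 1 000–10 000 frames for RMSF/PCA/DCCM recovery; 100 replicate fits
for midpoint and rate recovery studies. The titration noise "1%" means a
noise sd of 1% of the folded–unfolded amplitude. Degenerate inputs are
handled explicitly: all-identical shift columns give zero singular values
with a warning; a constant decay fits k = 0; a constant titration signal is
an error; a single trajectory frame gives zero RMSF with a warning. Sparky
peak lists are written with 17 significant digits so write-then-read
round-trips are exact.

## Known limitations

* The compression/transition split assumes the two components are orthogonal
  in the PC1–PC2 plane and that the first pressure step is purely
  compressive; both are approximations, and the residual ground-truth
  overlap sets the recovery floor.
* Thermodynamic parameters (ΔG₀, ΔV) are not fit from score trajectories —
  the analysis stops at patterns, by design.
* The intrinsic-rate model omits terminal-charge corrections and uses a
  fixed pK_D (its temperature dependence is neglected over the narrow range
  involved).
* Nearest-neighbour peak tracking fails loudly, by design, when peaks cross
  within the step ceiling; it does not attempt global assignment
  optimisation.
* Segmentation inherits KDE bandwidth sensitivity; states separated by less
  than about one within-state standard deviation are not resolved.
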