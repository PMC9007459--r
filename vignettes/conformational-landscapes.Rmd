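---
title: "Native IM-MS conformational landscapes and Go-model folding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Native IM-MS conformational landscapes and Go-model folding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imsfold)
```

imsfold analyses the conformational landscape of a protein as seen by
native ion-mobility mass spectrometry (IM-MS), and models the same
landscape with a structure-based coarse-grained potential. This vignette
is the package's account of the methods: the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices that were genuinely open.

## Traveling-wave CCS calibration

Traveling-wave ion mobility (TWIMS) does not measure a collision cross
section (CCS) directly; drift times must be calibrated against ions of
known CCS. The package implements the standard power-law protocol:

1. The measured drift time is corrected for the instrument's
   mass-dependent enhanced-duty-cycle (EDC) delay,
   $t_d' = t_d - c\sqrt{m/z}/1000$ (ms; `correctDriftTime()`). The
   coefficient $c$ is an instrument constant, default 1.41.
2. Literature CCS values of the calibrants are scaled by charge and
   reduced mass, $\Omega' = \Omega / (z\sqrt{1/\mu})$ with
   $\mu = m\,m_{\mathrm{gas}}/(m + m_{\mathrm{gas}})$
   (`reducedMassCorrection()`). The gas entering $\mu$ is the drift gas
   (nitrogen, 28.0134 Da, by default); helium-frame literature values
   calibrated in nitrogen are labelled the usual way (CCS~N2→He~).
3. A least-squares line on $(\ln t_d', \ln \Omega')$ gives
   $\Omega' = A\,t_d'^{\,B}$ (`fitCalibration()`), applied in reverse by
   `applyCalibration()`.

The cited calibration protocol leaves two things open that we fixed as
package defaults: the EDC coefficient (1.41, standard Synapt practice,
exposed as an argument) and the absence of any second-pass mass-dependent
transfer-time correction, which is not identifiable from drift times
alone. Degenerate designs (fewer than 3 calibrants, all-equal corrected
drift times, or a fitted exponent outside $(0,2)$) are rejected; a span
of less than 1.5-fold in corrected drift time only warns, because narrow
but usable calibrations exist.

The calibrant table shipped in `inst/extdata/calibrants_synthetic.csv` is
*synthetic*: plausible native charge states and helium-frame CCS values
for the usual calibrant proteins, used as scaffolding for the generator;
no row is a measurement.

## Gaussian conformer deconvolution

A CCS profile (one intensity trace over a uniform CCS grid, class
`CCSProfile`) is decomposed into a sum of Gaussian conformers with
`fitConformers()` (Levenberg–Marquardt, bounded parameters). The
initialization mirrors manual peak-fitting practice: the dominant peak is
assigned first, subsequent components at the maxima of the running
residual, ties broken toward lower CCS for determinism. Components are
reported sorted by mean CCS and labelled I, II, … from most compact to
most extended; widths are reported as FWHM because the field reports the
half-height width of the CCS distribution (CCSD), not a standard
deviation. Replicates are averaged before fitting
(`averageProfiles()`); the per-point SD is carried for plotting only.

`selectComponentCount()` automates the add-peaks-while-they-help
protocol: the smallest $k$ for which one more component improves $R^2$ by
less than 0.005 (threshold exposed). With the generator defaults below,
this reproduces the three-versus-four conformer outcomes the synthetic
landscapes are built to have: a three-state landscape stays at $k = 3$
and a landscape with a 5% abundance fourth state is still detected
($\Delta R^2 \approx 0.006$ for that component at 1% noise).
Over-fitting is flagged rather than silently accepted: if two fitted
means fall within a quarter of the narrowest FWHM the fit carries a
`crowded` flag and a warning.

`compareLandscapes()` matches components between two fits greedily by
nearest mean, with a tolerance of 3% of the pair mean — the
replicate-to-replicate variance typical of native IM-MS — and reports
per-pair ΔCCS, ΔCCSD and Δfraction, plus gained/lost components. The 3%
figure defines "the same conformer" across conditions; it is an asserted
convention, not a fitted quantity.

## CIU fingerprints

Collision-induced unfolding (CIU) steps the trap collision voltage
(16–34 V in 2 V steps by default) and records a CCS profile at each step.
`buildFingerprint()` stacks these into a voltage × CCS matrix, each row
normalized to maximum 1 (raw totals kept in metadata). Feature detection
(`detectFeatures()`) tracks per-voltage local maxima across voltages;
maxima below 0.2 of the row maximum are ignored (this floor suppresses
noise maxima at the ~1% noise level without losing a ~5% abundance
state), and peak picking runs on a lightly smoothed copy of each row
(Gaussian kernel, ~0.1 nm² SD) because the saddle between two comparable
peaks otherwise sprouts spurious noise maxima; all quantitative outputs
use the raw rows. Tracks shorter than 2 voltage steps are discarded;
overlapping tracks closer than 1 nm² are merged.

The occupancy of a feature at a voltage is the normalized intensity
integrated within one FWHM of the feature center, renormalized across
features so occupancies sum to 1. This definition is the package's own —
the CIU literature reports transition voltages without defining the
estimator — and it makes `ciu50()` well-posed: a logistic curve is fitted
to the destination feature's occupancy versus voltage (window truncated
at the occupancy maximum so later transitions do not bias the midpoint),
with a linear 50%-crossing fallback. A transition whose occupancy never
reaches 0.5 inside the voltage window is reported as incomplete, not
extrapolated.

`fingerprintRMSD()` compares two fingerprints on their common voltage set
and overlapping CCS range: 100 × the root-mean-square element-wise
difference of the normalized matrices. It is symmetric, zero on
identical input, and its null distribution under replicate noise is easy
to simulate with the generator.

## Projection-approximation CCS

`paCCS()` implements the Monte-Carlo projection approximation (PA): for
each uniformly random orientation (Shoemake quaternion), atoms are
projected as disks of radius $r_i + r_{\mathrm{probe}}$ and the union
area is estimated by uniform point sampling in the bounding box; the CCS
is the orientation-averaged area (nm², 1 nm² = 100 Å²) with a
Monte-Carlo standard error. The defaults, 300 orientations × 50 000
points, hold the standard error below ~0.5% of the CCS for a
~300-residue protein in well under a minute on one CPU; both knobs are
arguments, and analytic checks (single disk, two-sphere quadrature) are
part of the test suite. The raw PA value is the quantity of interest
throughout — no trajectory-method recalibration is attempted, matching
the convention that raw PA compares best with experimental values for
this system.

Two radius conventions are used. All-atom mode uses a hard-sphere
element table (`defaultRadiusTable()`: H 2.2, C/N/O 2.7, S/P 3.1 Å) plus
a 1.0 Å probe; the table is deliberately swappable because "default
atomic radii" is all the upstream tools specify, and this ambiguity is
why the package quotes a ±5% band when comparing to published computed
CCS values. Cα-bead mode (`caCCS()`) uses a uniform 3.8 Å bead radius —
the mean consecutive Cα spacing — and zero probe, the convention for
coarse-grained conformers. `trajectoryCCS()` maps either mode over
trajectory frames and pools the values into a histogram on the same axis
convention as experimental profiles so the two overlay directly.

## DFG geometry

Kinase DFG state is quantified by two distances from the DFG-Phe ζ
carbon: D1 to the Cα of a conserved C-helix anchor and D2 to the Cα of
the β3 lysine (Aurora A numbering F275/Q185/K162 is the default triple).
`classifyDFG()` applies the two-distance rule: DFG-in when
$d_1 \le t_1$ and $d_2 \ge t_2$, DFG-out for the mirror-image
arrangement, DFG-up/inter otherwise. All four thresholds default to
11 Å, following the published two-distance classification scheme; the
in-rule is evaluated first, so a point exactly on every threshold is
DFG-in (documented tie rule). Cα-only structures are rejected because D1
and D2 are defined from a side-chain atom.

## The Cα Go-model

`buildGoModel()` constructs a structure-based (Go-type) potential from a
native structure: harmonic bonds ($k = 100$ kcal mol⁻¹ Å⁻²) and angles
($k = 20$ kcal mol⁻¹ rad⁻²) at native geometry, a 12-10 well per native
contact minimized at the native Cα separation,
$V(r) = \varepsilon\,[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$, and a
$(\sigma_{\mathrm{rep}}/r)^{12}$ excluded-volume repulsion
($\sigma_{\mathrm{rep}} = 4$ Å) between all other nonlocal pairs. Native
contacts are pairs at sequence separation ≥ 4 with any heavy-atom
distance below 4.5 Å (all-atom input); for Cα-only input the criterion
is a Cα distance below 8.0 Å, since 4.5 Å is below typical Cα contact
separations. The well depth is uniform, $\varepsilon = 1\,k_BT$ at 300 K
(0.592 kcal/mol) — the simplest choice consistent with how such models
are used here; contact-specific weighting is a construction-time
argument, not a different code path. Dihedral terms are omitted by
default: angles plus contacts suffice to stabilise the Cα toys, and the
12-10-6 desolvation variant was left out of scope as unprintable from
available information.

`runLangevin()` integrates with BAOAB splitting (friction 0.2 ps⁻¹ by
default — low friction accelerates conformational sampling at desk
scale; bead mass 110 amu). The timestep is capped at 15 fs, the upper
end of what this class of model tolerates; 10 fs is the default and the
equilibrium native-contact fraction agrees between the two within 0.05
on the toy bundle. Kinetic energy is checked against equipartition
($\tfrac{3}{2}Nk_BT$, within 5% over 10⁵ steps) in the test suite, and a
potential-energy divergence guard aborts with advice to reduce the
timestep.

Analysis follows the conventions of the field: `temperatureScan()`
locates the unfolding transition as the Q = 0.5 crossing of a sigmoid
fitted to mean Q versus temperature and flags lower temperatures as
production-eligible (the scan-then-simulate-below protocol);
`defineNativeContacts()` retains contacts formed (distance
< 1.2 σ — the conventional formed-contact criterion, which the
occupancy rule needs but the upstream description does not state) in at
least 80% of low-temperature frames (250 K is the conventional
reference; the toy models here are scanned around their own, lower,
transition); `trajectoryRMSF()` computes per-residue RMSF about an
iteratively re-superposed ensemble average (2 refinement passes);
`clusterConformers()` is leader clustering in frame order at a 15 Å
best-fit RMSD cutoff. Superposition uses an SVD-based Kabsch algorithm
with the determinant correction implemented in the package, because
eigendecomposition-based fitting is numerically undefined for the
rank-deficient (e.g. collinear, fully extended) conformers that
unfolding trajectories legitimately produce.

With the default $\varepsilon$ the 30-residue toy helix bundle unfolds
near 130–150 K; scans in the tests therefore cover 60–360 K. This is a
property of the toy's small contact count, not a claim about protein
thermodynamics.

## The synthetic-data generator

No raw IM-MS data are available for this system, so every input is
generated:

* **Conformer mixtures** (`genMixtureProfile()`): sums of Gaussians on a
  CCS axis plus additive Gaussian noise truncated at zero, i.i.d. per
  replicate — the simplest model consistent with averaged replicate
  traces carrying error bars. The canonical study conditions used in the
  tests are a three-conformer landscape (21.5/23.3/25.6 nm², FWHM
  1.2/1.6/1.9 nm², fractions 25/50/25%) and a four-conformer landscape
  with a 5%-abundance extended state (21/23/25.5/28 nm²), echoing the
  compact-to-extended conformer ladders seen for active and inactive
  kinase forms. The noise level is a free parameter (no published value
  exists); 0.01 of the peak maximum is the default.
* **CIU series** (`genCIUSeries()`): a ladder of states visited in
  order, with sequential logistic hand-offs; occupancies telescope to 1
  at every voltage by construction.
* **Calibrants** (`genCalibrants()`): drift times generated by inverting
  the calibration power law, with multiplicative noise.
* **Toy structures** (`genToyStructure()`): self-avoiding Cα chains
  (consecutive spacing 3.8 ± 0.01 Å) as confined random-walk globules or
  ideal-helix bundles. The `open` variant replaces a designated loop
  with an outward arc (equal-arclength resampling of a bulged curve,
  then iterative bond-length projection), standing in for closed versus
  open activation-loop models; opening a 16-residue loop on a 60-residue
  globule raises the Cα-bead CCS by well over the 2% the tests require.
* **Pseudo-trajectories** (`genPseudoTrajectory()`): chain-smooth random
  displacement fields with the rigid-body component projected out and
  the per-frame internal RMS fixed exactly at the requested amplitude.
  Frames are mutually independent — there is no kinetics here.

What passing tests on these inputs shows: the estimators recover known
parameters under the noise structure the analysis assumes. What it does
not show: robustness to baseline drift, detector saturation, correlated
(non-Gaussian) noise, charge-state interference or real solvent-mediated
dynamics — none of which the generator emulates.

## Problem sizes and reproducibility

The test suite and the acceptance script run on deliberately small
problems: 30–60-residue toys, 10-voltage CIU series, 10⁵-step Langevin
runs, 100-seed parameter-recovery loops, and Monte-Carlo budgets chosen
so the standard error is comfortably inside each stated tolerance (e.g.
2 × 10⁸ samples for the two-sphere check, whose tolerance is 1%). Every
stochastic step takes an explicit seed; fixed seeds give bit-identical
profiles, trajectories and CCS estimates.

## Known limitations

* The calibration is the TWIMS power law only; no first-principles
  Mason–Schamp conversion for drift-tube data.
* PA CCS ignores gas-molecule scattering physics by design; it is the
  raw projection approximation, and all-atom values inherit the radius
  table's ±5% ambiguity.
* The Go-model is a folded-state caricature: uniform contact strengths,
  no solvent, no dihedrals by default; transition temperatures of the
  toys are not comparable to experimental melting temperatures.
* Feature tracking in CIU fingerprints assumes features drift by less
  than the 1 nm² linking tolerance between adjacent voltages.
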