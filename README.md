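# imsfold

Native ion-mobility mass spectrometry (IM-MS) resolves the gas-phase
conformational landscape of a protein: a calibrated collision cross
section (CCS, nm²) axis, Gaussian-resolvable conformers on it, and —
under stepped collisional activation — an unfolding fingerprint.
Structure-based modelling connects those observables back to atomic
models: projection-approximation CCS of crystal structures and
trajectory snapshots, distance-based DFG-motif classification for
kinases, and Cα Go-model simulations of folding and unfolding.

imsfold implements that whole analysis chain for R, aimed at native-MS
and structural-bioinformatics practitioners:

* **CCS calibration** — the TWIMS power-law protocol: EDC drift-time
  correction `td' = td − c·√(m/z)/1000`, reduced-mass/charge scaling
  `Ω' = Ω/(z√(1/μ))`, and the ln–ln fit `Ω' = A·td'^B`
  (`fitCalibration()`, `applyCalibration()`).
* **Conformer deconvolution** — bounded nonlinear least squares of a sum
  of Gaussians with peak-wise initialization, automatic component-count
  selection (ΔR² < 0.005 stops), CCS/CCSD/area-fraction reporting and
  landscape comparison at a 3% matching tolerance (`fitConformers()`,
  `selectComponentCount()`, `compareLandscapes()`).
* **CIU fingerprints** — voltage × CCS matrices normalized per voltage,
  feature tracking, occupancy-based CIU50 transition voltages and
  fingerprint RMSD (`buildFingerprint()`, `detectFeatures()`,
  `ciu50()`, `fingerprintRMSD()`).
* **Structure CCS** — Monte-Carlo projection approximation
  (orientation-averaged projected union area) in all-atom or Cα-bead
  (3.8 Å radius) modes, over single structures or trajectories
  (`paCCS()`, `caCCS()`, `trajectoryCCS()`), plus DFG geometry
  (`dfgGeometry()`, `classifyDFG()`).
* **Go-model simulation** — native-contact 12-10 potentials built from
  structures, BAOAB Langevin dynamics (Rcpp), temperature scans for the
  unfolding transition, native-contact fractions, RMSF and leader
  clustering at an RMSD cutoff (`buildGoModel()`, `runLangevin()`,
  `temperatureScan()`, `clusterConformers()`).
* **Synthetic data** — generators for every input the pipeline consumes
  (conformer mixtures, CIU series, calibrant tables, Cα toy structures
  with closed/open loops, pseudo-trajectories), so everything above is
  testable without instrument data (`genMixtureProfile()`,
  `genCIUSeries()`, `genToyStructure()`, ...).

Central containers are S4 classes with validity checks (`CCSProfile`,
`ConformerFit`, `CIUFingerprint`, `Structure`, `Trajectory`, `GoModel`);
use the accessors (`ccsAxis()`, `components()`, `coords()`, ...) rather
than slots.

## Worked example

Calibrate, deconvolve a conformer landscape, measure a CIU transition,
and fold a toy with its own Go-model:

```r
library(imsfold)

## 1. fit the TWIMS calibration on (synthetic) calibrant drift times
tab   <- readCalibrants(system.file("extdata/calibrants_synthetic.csv",
                                    package = "imsfold"))
cal   <- genCalibrants(trueA = 2, trueB = 0.55, tab, noiseSD = 0.01, seed = 42)
model <- fitCalibration(cal)
model
#> CalibrationModel: CCS' = 2.071 * td'^0.5386  (R^2 = 0.998671, N2)

## 2. deconvolve a three-conformer CCS profile (1% replicate noise)
sp   <- MixtureSpec(data.frame(mean = c(21.5, 23.3, 25.6),
                               fwhm = c(1.2, 1.6, 1.9),
                               fraction = c(0.25, 0.50, 0.25)),
                    noiseSD = 0.01, seed = 7)
prof <- averageProfiles(genMixtureProfile(sp))
fit  <- fitConformers(prof, k = "auto")   # selects k = 3
fit
#> ConformerFit: 3 conformer(s), R^2 = 0.99969
#>  label  ccs  ccsd   area fraction
#>      I 21.5 1.196 0.2493    24.91
#>     II 23.3 1.603 0.5013    50.08
#>    III 25.6 1.907 0.2504    25.01
weightedMeanCCS(prof)
#> [1] 23.42  # nm^2
```

The fitted means, widths (CCSD, as FWHM) and area fractions recover the
generator truth; the intensity-weighted mean CCS summarises the whole
landscape in one number, the way compact versus extended protein forms
are compared.

```r
## 3. CIU: two states handing off at 25 V, stepped 16-34 V
spCIU <- CIUSeriesSpec(states = data.frame(mean = c(22, 26),
                                           fwhm = c(1.5, 2)),
                       transitions = data.frame(midpoint = 25,
                                                steepness = 1),
                       noiseSD = 0.01, seed = 3)
fp <- buildFingerprint(genCIUSeries(spCIU))
fe <- detectFeatures(fp)
ciu50(fp, fe[1, ], fe[2, ])
#> [1] 25.00  # V -- the collision voltage at which half the population unfolded

## 4. Go-model of a 30-residue toy helix bundle
bundle <- genToyStructure(ToyStructureSpec(30, "helix_bundle", seed = 1))
gm     <- buildGoModel(bundle)
gm
#> GoModel: 30 beads, 29 bonds, 28 angles, 45 native contacts
sc <- temperatureScan(gm, seq(60, 360, by = 60), stepsPerT = 40000,
                      seed = 5, saveInterval = 200)
round(sc$table$meanQ, 2)
#> [1] 0.97 0.71 0.37 0.28 0.19 0.20
sc$tTransition
#> [1] 155  # K: mean native-contact fraction Q crosses 0.5 here
caCCS(bundle, seed = 1)
#> PAResult (ca_bead): CCS = 3.6580 +/- 0.0375 nm^2 (300 orientations x 50000 points)
```

Q falls from ~1 (folded) to ~0.2 (unfolded) across the scan; production
sampling belongs below the fitted transition. `trajectoryCCS()` turns
such runs into CCS histograms directly comparable with the experimental
profiles from step 2.

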