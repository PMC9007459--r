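#' @useDynLib imsfold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.fwhm2sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
.sd2fwhm <- function(sd) sd * 2 * sqrt(2 * log(2))

#' CCSProfile: one intensity trace over a CCS axis
#'
#' Holds a single ion-mobility intensity trace on a uniform, strictly
#' increasing collision cross section (CCS) axis for one charge state,
#' together with acquisition metadata (wave height, wave velocity, trap bias,
#' pressure, trap collision voltage) and an optional per-point
#' across-replicate standard deviation.
#'
#' @slot axis numeric, CCS grid in nm^2 (uniform, strictly increasing).
#' @slot intensity numeric, nonnegative intensity per grid point.
#' @slot charge integer, charge state z.
#' @slot replicateSD numeric, per-point SD across replicates (length 0 or
#'   equal to the axis).
#' @slot metadata list of acquisition metadata.
#' @export
setClass("CCSProfile", representation(
  axis = "numeric", intensity = "numeric", charge = "integer",
  replicateSD = "numeric", metadata = "list"))

setValidity("CCSProfile", function(object) {
  a <- object@axis
  if (length(a) != length(object@intensity))
    return("axis and intensity lengths differ")
  if (length(a) < 2) return("axis needs at least 2 points")
  d <- diff(a)
  if (any(d <= 0)) return("axis must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-9 * max(abs(a)))
    return("axis must be uniform")
  if (any(object@intensity < 0)) return("intensities must be >= 0")
  if (length(object@replicateSD) &&
      length(object@replicateSD) != length(a))
    return("replicateSD length must match axis")
  TRUE
})

#' @export
setMethod("show", "CCSProfile", function(object) {
  cat("CCSProfile:", length(object@axis), "points,",
      sprintf("%.2f-%.2f nm^2,", min(object@axis), max(object@axis)),
      "charge", paste0(object@charge, "+"), "\n")
})

#' MixtureSpec: parameters of a synthetic Gaussian conformer mixture
#'
#' Describes a mixture of Gaussian conformers on a CCS axis, the way
#' conformers I-IV are parameterised from experimental profiles: per-component
#' mean CCS (nm^2), full width at half maximum (the CCS distribution width,
#' CCSD, nm^2) and area fraction, plus axis, replicate noise and seed.
#'
#' @slot components data.frame with columns `mean`, `fwhm`, `fraction`.
#' @slot axis numeric length 3: c(min, max, step) in nm^2.
#' @slot noiseSD numeric, additive Gaussian noise SD as a fraction of the
#'   maximum noiseless intensity.
#' @slot replicates integer, number of replicate profiles to generate.
#' @slot seed integer RNG seed.
#' @export
setClass("MixtureSpec", representation(
  components = "data.frame", axis = "numeric", noiseSD = "numeric",
  replicates = "integer", seed = "integer"))

setValidity("MixtureSpec", function(object) {
  cc <- object@components
  if (!all(c("mean", "fwhm", "fraction") %in% names(cc)))
    return("components needs columns mean, fwhm, fraction")
  if (abs(sum(cc$fraction) - 1) > 1e-9)
    return("area fractions must sum to 1 (within 1e-9)")
  if (any(cc$fwhm <= 0)) return("fwhm must be > 0")
  if (length(object@axis) != 3) return("axis must be c(min, max, step)")
  if (object@axis[3] <= 0) return("axis step must be > 0")
  if (object@axis[2] <= object@axis[1]) return("axis max must exceed min")
  if (any(cc$mean < object@axis[1] | cc$mean > object@axis[2]))
    return("component means must lie inside the axis range")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@replicates < 1) return("replicates must be >= 1")
  TRUE
})

#' CIUSeriesSpec: parameters of a synthetic collision-induced unfolding series
#'
#' A chain of conformational states (mean CCS, FWHM) visited in order as the
#' trap collision voltage increases, with one logistic hand-off per adjacent
#' state pair (midpoint voltage, steepness).
#'
#' @slot states data.frame with columns `mean`, `fwhm` (nm^2), ordered from
#'   native to unfolded.
#' @slot transitions data.frame with columns `midpoint` (V) and `steepness`
#'   (1/V); one row fewer than states, midpoints strictly increasing.
#' @slot voltages numeric, strictly increasing trap collision voltages (V).
#' @slot axis numeric length 3: CCS axis c(min, max, step) in nm^2.
#' @slot noiseSD numeric, noise fraction as in [MixtureSpec-class].
#' @slot seed integer RNG seed.
#' @export
setClass("CIUSeriesSpec", representation(
  states = "data.frame", transitions = "data.frame", voltages = "numeric",
  axis = "numeric", noiseSD = "numeric", seed = "integer"))

setValidity("CIUSeriesSpec", function(object) {
  st <- object@states; tr <- object@transitions
  if (!all(c("mean", "fwhm") %in% names(st)))
    return("states needs columns mean, fwhm")
  if (nrow(st) >= 2 &&
      !all(c("midpoint", "steepness") %in% names(tr)))
    return("transitions needs columns midpoint, steepness")
  if (nrow(tr) != nrow(st) - 1)
    return("need exactly one transition per adjacent state pair")
  if (nrow(tr) > 1 && any(diff(tr$midpoint) <= 0))
    return("transition midpoints must be strictly increasing")
  if (any(diff(object@voltages) <= 0))
    return("voltage grid must be strictly increasing")
  if (any(st$fwhm <= 0)) return("state fwhm must be > 0")
  if (length(object@axis) != 3 || object@axis[3] <= 0)
    return("axis must be c(min, max, step) with step > 0")
  TRUE
})

#' ToyStructureSpec: parameters of a synthetic C-alpha test structure
#'
#' Describes a self-avoiding C-alpha bead chain (compact globule or helix
#' bundle) with a designated loop that can be generated in a `closed`
#' (packed) or `open` (outward-displaced) state, standing in for closed
#' versus open activation-loop configurations.
#'
#' @slot nResidues integer in [10, 500].
#' @slot fold `"compact_globule"` or `"helix_bundle"`.
#' @slot loopState `"closed"` or `"open"`.
#' @slot loopSpan integer length 2, first and last residue of the loop.
#' @slot seed integer RNG seed.
#' @export
setClass("ToyStructureSpec", representation(
  nResidues = "integer", fold = "character", loopState = "character",
  loopSpan = "integer", seed = "integer"))

setValidity("ToyStructureSpec", function(object) {
  n <- object@nResidues
  if (n < 10 || n > 500) return("nResidues must be in [10, 500]")
  if (!object@fold %in% c("compact_globule", "helix_bundle"))
    return("fold must be compact_globule or helix_bundle")
  if (!object@loopState %in% c("closed", "open"))
    return("loopState must be closed or open")
  ls <- object@loopSpan
  if (length(ls) != 2 || ls[1] < 1 || ls[2] > n || ls[1] >= ls[2])
    return("loopSpan must be an increasing pair within [1, nResidues]")
  if (ls[1] <= 1 || ls[2] >= n)
    return("loop needs anchor residues on both sides")
  TRUE
})

#' CalibrationModel: fitted traveling-wave CCS calibration
#'
#' The power law Omega' = A * td'^B fitted on ln-ln axes to calibrant ions of
#' known literature CCS, with the enhanced-duty-cycle (EDC) drift-time
#' correction coefficient and drift-gas mass used for the reduced-mass term.
#'
#' @slot A numeric scale factor (> 0).
#' @slot B numeric exponent in (0, 2).
#' @slot edc numeric EDC delay coefficient.
#' @slot gasMass numeric drift-gas molecular mass (Da).
#' @slot gas character drift-gas label.
#' @slot r2 numeric, R-squared of the ln-ln fit.
#' @slot residuals data.frame of per-calibrant ln-space residuals.
#' @export
setClass("CalibrationModel", representation(
  A = "numeric", B = "numeric", edc = "numeric", gasMass = "numeric",
  gas = "character", r2 = "numeric", residuals = "data.frame"))

setValidity("CalibrationModel", function(object) {
  if (object@A <= 0) return("A must be > 0")
  if (object@B <= 0 || object@B >= 2) return("B must be in (0, 2)")
  if (object@r2 > 1 + 1e-12) return("r2 cannot exceed 1")
  TRUE
})

#' @export
setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: CCS' = %.4g * td'^%.4g  (R^2 = %.6f, %s)\n",
              object@A, object@B, object@r2, object@gas))
})

#' ConformerFit: Gaussian conformers fitted to a CCS profile
#'
#' @slot components data.frame with columns `label` (I, II, ...), `ccs`
#'   (mean, nm^2), `ccsd` (FWHM, nm^2), `area`, `fraction` (% of total area);
#'   rows ordered by increasing mean.
#' @slot rSquared numeric, R-squared of the summed fit against the trace.
#' @slot residuals numeric residual trace on the profile axis.
#' @slot axis numeric, the CCS axis the fit was performed on.
#' @slot crowded logical, TRUE when two fitted means fall closer than a
#'   quarter of the narrowest FWHM (over-fitting flag).
#' @export
setClass("ConformerFit", representation(
  components = "data.frame", rSquared = "numeric", residuals = "numeric",
  axis = "numeric", crowded = "logical"))

setValidity("ConformerFit", function(object) {
  cc <- object@components
  if (!all(c("label", "ccs", "ccsd", "area", "fraction") %in% names(cc)))
    return("components missing required columns")
  if (nrow(cc) > 1 && any(diff(cc$ccs) <= 0))
    return("component means must be strictly increasing")
  if (abs(sum(cc$fraction) - 100) > 1e-6)
    return("area fractions must sum to 100")
  if (object@rSquared > 1 + 1e-12) return("rSquared cannot exceed 1")
  TRUE
})

#' @export
setMethod("show", "ConformerFit", function(object) {
  cat(sprintf("ConformerFit: %d conformer(s), R^2 = %.5f%s\n",
              nrow(object@components), object@rSquared,
              if (object@crowded) " [crowded]" else ""))
  print(object@components, digits = 4, row.names = FALSE)
})

#' LandscapeDelta: matched-component comparison of two conformer fits
#'
#' @slot matched data.frame of matched component pairs with delta columns.
#' @slot gained data.frame of components present only in the second fit.
#' @slot lost data.frame of components present only in the first fit.
#' @slot tol numeric, the matching tolerance used (nm^2, per pair).
#' @export
setClass("LandscapeDelta", representation(
  matched = "data.frame", gained = "data.frame", lost = "data.frame",
  tol = "numeric"))

#' @export
setMethod("show", "LandscapeDelta", function(object) {
  cat("LandscapeDelta:", nrow(object@matched), "matched,",
      nrow(object@gained), "gained,", nrow(object@lost), "lost\n")
  if (nrow(object@matched)) print(object@matched, digits = 3,
                                  row.names = FALSE)
})

#' CIUFingerprint: column-normalized unfolding landscape
#'
#' Matrix of intensity over (trap collision voltage x CCS), each voltage row
#' scaled to maximum 1, as produced by stepped collisional activation with
#' ion-mobility readout.
#'
#' @slot voltages numeric, strictly increasing collision voltages (V).
#' @slot ccsAxis numeric CCS grid (nm^2).
#' @slot matrix numeric matrix, rows = voltages, columns = CCS grid points.
#' @slot metadata list; carries raw per-voltage totals and provenance.
#' @export
setClass("CIUFingerprint", representation(
  voltages = "numeric", ccsAxis = "numeric", matrix = "matrix",
  metadata = "list"))

setValidity("CIUFingerprint", function(object) {
  m <- object@matrix
  if (nrow(m) != length(object@voltages))
    return("matrix rows must match voltages")
  if (ncol(m) != length(object@ccsAxis))
    return("matrix columns must match ccsAxis")
  if (any(diff(object@voltages) <= 0))
    return("voltages must be strictly increasing")
  rm <- apply(m, 1, max)
  if (any(rm == 0)) return("all-zero voltage row")
  if (any(abs(rm - 1) > 1e-9)) return("rows must be normalized to max 1")
  TRUE
})

#' @export
setMethod("show", "CIUFingerprint", function(object) {
  cat(sprintf("CIUFingerprint: %d voltages (%g-%g V) x %d CCS points (%.1f-%.1f nm^2)\n",
              length(object@voltages), min(object@voltages),
              max(object@voltages), length(object@ccsAxis),
              min(object@ccsAxis), max(object@ccsAxis)))
})

#' Structure: atomic or C-alpha-bead coordinates
#'
#' @slot atoms data.frame with columns `eleno`, `elety`, `elem`, `resid`
#'   (residue name), `resno`, `insert`, `chain`, `x`, `y`, `z` (A).
#' @export
setClass("Structure", representation(atoms = "data.frame"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("eleno", "elety", "elem", "resid", "resno", "chain",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  TRUE
})

#' @export
setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      "chains:", paste(unique(a$chain), collapse = " "), "\n")
})

#' Trajectory: a series of coordinate frames over one atom set
#'
#' @slot atoms data.frame, atom bookkeeping as in [Structure-class].
#' @slot coords numeric array, dim = c(nAtoms, 3, nFrames), A.
#' @slot temperature numeric (K; NA when not from simulation).
#' @slot timestep numeric integration timestep (fs; NA when not simulated).
#' @slot saveInterval numeric steps between saved frames.
#' @slot seed integer RNG seed used to generate the trajectory.
#' @slot energies data.frame with per-frame `pe` and `ke` (kcal/mol) when
#'   produced by the Langevin integrator, else empty.
#' @export
setClass("Trajectory", representation(
  atoms = "data.frame", coords = "array", temperature = "numeric",
  timestep = "numeric", saveInterval = "numeric", seed = "integer",
  energies = "data.frame"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an nAtoms x 3 x nFrames array")
  if (d[1] != nrow(object@atoms))
    return("coords atom dimension must match atoms")
  if (d[3] < 1) return("trajectory needs at least one frame")
  if (length(object@saveInterval) && !is.na(object@saveInterval) &&
      object@saveInterval <= 0)
    return("save interval must be > 0")
  TRUE
})

#' @export
setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[3], "frames x", d[1], "atoms")
  if (!is.na(object@temperature))
    cat(sprintf(" (T = %g K, dt = %g fs)", object@temperature,
                object@timestep))
  cat("\n")
})

#' GoModel: structure-based C-alpha coarse-grained potential
#'
#' Beads at native C-alpha positions; harmonic bonds and angles at native
#' geometry; a 12-10 attractive well per native contact minimized at the
#' native C-alpha separation; excluded-volume repulsion between all other
#' nonlocal pairs.
#'
#' @slot beads data.frame with columns `resno`, `x`, `y`, `z`.
#' @slot bonds data.frame `i`, `j`, `r0`, `k` (kcal/mol/A^2).
#' @slot angles data.frame `i`, `j`, `k_`, `theta0` (rad), `kAngle`.
#' @slot dihedrals data.frame (empty by default; native-biased terms).
#' @slot contacts data.frame `i`, `j`, `sigma` (native distance, A),
#'   `epsilon` (well depth, kcal/mol).
#' @slot repSigma numeric, nonnative repulsion radius (A).
#' @slot repEps numeric, repulsion strength (kcal/mol).
#' @slot params list of construction parameters (cutoff, minSeparation, ...).
#' @export
setClass("GoModel", representation(
  beads = "data.frame", bonds = "data.frame", angles = "data.frame",
  dihedrals = "data.frame", contacts = "data.frame", repSigma = "numeric",
  repEps = "numeric", params = "list"))

setValidity("GoModel", function(object) {
  ct <- object@contacts
  ms <- object@params$minSeparation
  if (nrow(ct)) {
    if (any(ct$sigma <= 0)) return("contact sigma must be > 0")
    if (!is.null(ms) && any(abs(ct$j - ct$i) < ms))
      return("contact pair closer in sequence than minSeparation")
  }
  n <- nrow(object@beads)
  if (n > 1) {
    inBond <- sort(unique(c(object@bonds$i, object@bonds$j)))
    if (!identical(inBond, seq_len(n)))
      return("every bead must appear in at least one bonded term")
  }
  if (object@repSigma <= 0) return("repSigma must be > 0")
  TRUE
})

#' @export
setMethod("show", "GoModel", function(object) {
  cat("GoModel:", nrow(object@beads), "beads,", nrow(object@bonds), "bonds,",
      nrow(object@angles), "angles,", nrow(object@contacts),
      "native contacts\n")
})

#' Construct a CCSProfile
#'
#' @param axis uniform, strictly increasing CCS grid (nm^2).
#' @param intensity nonnegative intensities, same length as `axis`.
#' @param charge charge state (integer or NA).
#' @param replicateSD optional per-point SD across replicates.
#' @param metadata list of acquisition metadata.
#' @return a validated [CCSProfile-class].
#' @export
CCSProfile <- function(axis, intensity, charge = NA_integer_,
                       replicateSD = numeric(0), metadata = list()) {
  new("CCSProfile", axis = as.numeric(axis),
      intensity = as.numeric(intensity), charge = as.integer(charge),
      replicateSD = as.numeric(replicateSD), metadata = metadata)
}
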