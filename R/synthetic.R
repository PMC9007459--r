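#' Specify a synthetic Gaussian conformer mixture
#'
#' Constructor for [MixtureSpec-class]. Components are given as
#' `(mean CCS, FWHM, area fraction)` triples the way conformers I-IV are
#' reported from Gaussian fits of experimental CCS profiles.
#'
#' @param components data.frame (or matrix) with columns `mean`, `fwhm`
#'   (both nm^2) and `fraction` (summing to 1).
#' @param axis numeric `c(min, max, step)` CCS axis in nm^2.
#' @param noiseSD additive Gaussian noise SD as a fraction of the maximum
#'   noiseless intensity. The default 0.01 emulates the scatter of averaged
#'   replicate traces.
#' @param replicates number of replicate profiles.
#' @param seed integer RNG seed.
#' @return a validated [MixtureSpec-class].
#' @export
#' @examples
#' sp <- MixtureSpec(data.frame(mean = c(21.9, 23.2, 25.2),
#'                              fwhm = c(1.4, 1.7, 2.2),
#'                              fraction = c(0.25, 0.55, 0.20)))
#' profs <- genMixtureProfile(sp)
MixtureSpec <- function(components, axis = c(18, 30, 0.05), noiseSD = 0.01,
                        replicates = 3L, seed = 1L) {
  new("MixtureSpec", components = as.data.frame(components),
      axis = as.numeric(axis), noiseSD = noiseSD,
      replicates = as.integer(replicates), seed = as.integer(seed))
}

.mixtureCurve <- function(axis, components) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(components))) {
    s <- .fwhm2sd(components$fwhm[i])
    y <- y + components$fraction[i] * stats::dnorm(axis, components$mean[i], s)
  }
  y
}

#' Generate replicate CCS profiles from a Gaussian mixture
#'
#' Evaluates the specified sum of Gaussians on the CCS axis and adds i.i.d.
#' Gaussian noise (truncated at zero intensity) independently per replicate,
#' emulating replicate ion-mobility acquisitions of a conformer mixture.
#'
#' @param spec a [MixtureSpec-class].
#' @return list of [CCSProfile-class], one per replicate.
#' @seealso [averageProfiles()] to form the mean trace used for fitting.
#' @export
genMixtureProfile <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  axis <- seq(spec@axis[1], spec@axis[2], by = spec@axis[3])
  clean <- .mixtureCurve(axis, spec@components)
  nsd <- spec@noiseSD * max(clean)
  lapply(seq_len(spec@replicates), function(r) {
    y <- clean
    if (nsd > 0) y <- pmax(0, y + stats::rnorm(length(y), 0, nsd))
    new("CCSProfile", axis = axis, intensity = y, charge = 11L,
        replicateSD = numeric(0),
        metadata = list(replicate = r, noiseSD = spec@noiseSD,
                        seed = spec@seed, units = "nm^2"))
  })
}

#' Average replicate profiles into a mean trace with per-point SD
#'
#' @param profiles list of [CCSProfile-class] sharing one axis.
#' @return a [CCSProfile-class] whose intensity is the across-replicate mean
#'   and whose `replicateSD` slot carries the per-point SD.
#' @export
averageProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ax <- ccsAxis(profiles[[1]])
  for (p in profiles)
    if (!isTRUE(all.equal(ccsAxis(p), ax)))
      stop("profiles must share a common axis")
  ymat <- vapply(profiles, intensity, numeric(length(ax)))
  ymat <- matrix(ymat, nrow = length(ax))
  new("CCSProfile", axis = ax, intensity = rowMeans(ymat),
      charge = profiles[[1]]@charge,
      replicateSD = if (length(profiles) > 1) apply(ymat, 1, stats::sd)
                    else numeric(0),
      metadata = c(profiles[[1]]@metadata,
                   list(nReplicates = length(profiles))))
}

#' Specify a synthetic collision-induced unfolding series
#'
#' Constructor for [CIUSeriesSpec-class]: a ladder of conformational states
#' visited in order of increasing collision voltage, with logistic hand-offs
#' between consecutive states.
#'
#' @param states data.frame with columns `mean`, `fwhm` (nm^2).
#' @param transitions data.frame with columns `midpoint` (V), `steepness`
#'   (1/V); `nrow(states) - 1` rows, midpoints increasing.
#' @param voltages collision-voltage grid; the default 16-34 V in 2 V steps
#'   matches stepped trap-activation practice.
#' @param axis CCS axis `c(min, max, step)` (nm^2).
#' @param noiseSD,seed as in [MixtureSpec()].
#' @return a validated [CIUSeriesSpec-class].
#' @export
CIUSeriesSpec <- function(states, transitions = NULL,
                          voltages = seq(16, 34, by = 2),
                          axis = c(18, 36, 0.05), noiseSD = 0.01,
                          seed = 1L) {
  if (is.null(transitions))
    transitions <- data.frame(midpoint = numeric(0), steepness = numeric(0))
  new("CIUSeriesSpec", states = as.data.frame(states),
      transitions = as.data.frame(transitions),
      voltages = as.numeric(voltages), axis = as.numeric(axis),
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' State occupancies of a CIU ladder at given voltages
#'
#' Sequential logistic hand-offs: the fraction of the population that has
#' passed transition t at voltage V is `plogis(steepness * (V - midpoint))`;
#' the occupancy of state j is the population that has passed transition
#' j-1 but not yet transition j. Occupancies are clamped at zero and
#' renormalized, and sum to 1 at every voltage.
#'
#' @param spec a [CIUSeriesSpec-class].
#' @param voltages voltages at which to evaluate (default: the spec's grid).
#' @return matrix, rows = voltages, columns = states.
#' @export
stateOccupancies <- function(spec, voltages = spec@voltages) {
  nS <- nrow(spec@states)
  occ <- matrix(0, length(voltages), nS)
  for (vi in seq_along(voltages)) {
    pass <- if (nS > 1)
      stats::plogis(spec@transitions$steepness *
                    (voltages[vi] - spec@transitions$midpoint))
    else numeric(0)
    s <- c(1, pass, 0)  # s[j] - s[j+1] telescopes to occupancy of state j
    o <- s[-length(s)] - s[-1]
    o[o < 0] <- 0
    occ[vi, ] <- o / sum(o)
  }
  occ
}

#' Generate a synthetic CIU voltage series
#'
#' At each voltage of the grid the profile is the occupancy-weighted sum of
#' the state Gaussians plus replicate-style noise, emulating a stepped
#' collisional-activation experiment read out by ion mobility.
#'
#' @param spec a [CIUSeriesSpec-class].
#' @return list with one element per voltage: `list(voltage =, profile =)`.
#' @export
genCIUSeries <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  axis <- seq(spec@axis[1], spec@axis[2], by = spec@axis[3])
  occ <- stateOccupancies(spec)
  shapes <- vapply(seq_len(nrow(spec@states)), function(j)
    stats::dnorm(axis, spec@states$mean[j], .fwhm2sd(spec@states$fwhm[j])),
    numeric(length(axis)))
  peak <- max(shapes %*% t(occ))
  lapply(seq_along(spec@voltages), function(vi) {
    y <- as.numeric(shapes %*% occ[vi, ])
    if (spec@noiseSD > 0)
      y <- pmax(0, y + stats::rnorm(length(y), 0, spec@noiseSD * peak))
    prof <- new("CCSProfile", axis = axis, intensity = y, charge = 11L,
                replicateSD = numeric(0),
                metadata = list(voltage = spec@voltages[vi], units = "nm^2"))
    list(voltage = spec@voltages[vi], profile = prof)
  })
}

#' Generate synthetic calibrant drift times from a known power law
#'
#' Inverts the traveling-wave calibration power law used by
#' [fitCalibration()]: for each calibrant ion the charge/reduced-mass-scaled
#' literature CCS is converted to a corrected drift time
#' `td' = (ccs' / A)^(1/B)`, the EDC mass-dependent delay is added back, and
#' multiplicative Gaussian noise of relative SD `noiseSD` is applied.
#'
#' @param trueA,trueB the power-law scale and exponent to embed (B in (0,2)).
#' @param calibrantTable data.frame with columns `name`, `mass_da`, `charge`,
#'   `lit_ccs_nm2` (helium-frame literature CCS).
#' @param noiseSD relative drift-time noise (0 = noiseless).
#' @param edc EDC delay coefficient (default 1.41).
#' @param gasMass drift-gas mass in Da (default nitrogen, 28.0134).
#' @param seed integer RNG seed.
#' @return data.frame with columns `name`, `mass_da`, `charge`, `mz`,
#'   `drift_time_ms`, `lit_ccs_nm2`.
#' @export
genCalibrants <- function(trueA, trueB, calibrantTable, noiseSD = 0,
                          edc = 1.41, gasMass = 28.0134, seed = 1L) {
  if (trueB <= 0 || trueB >= 2) stop("trueB must lie in (0, 2)")
  tb <- as.data.frame(calibrantTable)
  if (nrow(tb) == 0) stop("calibrant table is empty")
  need <- c("name", "mass_da", "charge", "lit_ccs_nm2")
  if (!all(need %in% names(tb)))
    stop("calibrant table needs columns: ", paste(need, collapse = ", "))
  if (any(tb$charge < 1)) stop("charges must be >= 1")
  if (any(tb$lit_ccs_nm2 <= 0)) stop("literature CCS must be positive")
  set.seed(as.integer(seed))
  mz <- (tb$mass_da + tb$charge * 1.007276) / tb$charge
  ccsP <- reducedMassCorrection(tb$lit_ccs_nm2, tb$charge, tb$mass_da,
                                gasMass)
  tdPrime <- (ccsP / trueA)^(1 / trueB)
  td <- tdPrime + edc * sqrt(mz) / 1000
  if (noiseSD > 0) td <- td * (1 + stats::rnorm(nrow(tb), 0, noiseSD))
  data.frame(name = tb$name, mass_da = tb$mass_da, charge = tb$charge,
             mz = mz, drift_time_ms = td, lit_ccs_nm2 = tb$lit_ccs_nm2)
}

## ---- toy structures -------------------------------------------------------

.CA_CA <- 3.8        # consecutive C-alpha spacing, A
.SELF_AVOID <- 3.7   # minimum nonlocal bead separation, A

# iterative bond-length projection: enforce consecutive spacing exactly,
# endpoints held fixed
.equalizeSpacing <- function(path, target = .CA_CA, iters = 400L,
                             tol = 1e-4) {
  n <- nrow(path)
  for (it in seq_len(iters)) {
    worst <- 0
    for (k in seq_len(n - 1)) {
      d <- path[k + 1, ] - path[k, ]
      len <- sqrt(sum(d^2))
      err <- len - target
      worst <- max(worst, abs(err))
      corr <- d / len * err
      freeA <- k != 1
      freeB <- (k + 1) != n
      if (freeA && freeB) {
        path[k, ]     <- path[k, ]     + corr / 2
        path[k + 1, ] <- path[k + 1, ] - corr / 2
      } else if (freeA) {
        path[k, ]     <- path[k, ]     + corr
      } else if (freeB) {
        path[k + 1, ] <- path[k + 1, ] - corr
      }
    }
    if (worst < tol) break
  }
  path
}

# bulged bridge from A to B with nBeads interior beads at ~3.8 A spacing,
# bulging along unit vector u
.bridgePath <- function(A, B, nBeads, u) {
  needed <- (nBeads + 1) * .CA_CA
  dAB <- sqrt(sum((B - A)^2))
  if (dAB >= needed)
    stop("anchors too far apart for the requested bead count")
  curve <- function(h) {
    t <- seq(0, 1, length.out = 400)
    p <- outer(t, B - A) + matrix(A, length(t), 3, byrow = TRUE) +
      h * sin(pi * t) %o% u
    p
  }
  arclen <- function(h) sum(sqrt(rowSums(diff(curve(h))^2)))
  h <- tryCatch(stats::uniroot(function(h) arclen(h) - needed,
                               c(0, needed), tol = 1e-8)$root,
                error = function(e) stop("cannot bridge anchors: ",
                                         conditionMessage(e)))
  p <- curve(h)
  cs <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  sk <- seq_len(nBeads) * cs[length(cs)] / (nBeads + 1)
  out <- vapply(1:3, function(d) stats::approx(cs, p[, d], xout = sk)$y,
                numeric(nBeads))
  out <- matrix(out, nrow = nBeads)
  .equalizeSpacing(rbind(A, out, B))[seq_len(nBeads) + 1, , drop = FALSE]
}

# self-avoiding random walk confined to a sphere
.compactWalk <- function(n, maxRestarts = 60L) {
  rmax <- max(10, 3.2 * n^(1 / 3) + 2)
  for (restart in seq_len(maxRestarts)) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:300) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1, ] + .CA_CA * u
        if (sqrt(sum(cand^2)) > rmax) next
        if (i > 2) {
          d2 <- rowSums((xyz[1:(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
          if (min(d2) < .SELF_AVOID^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("could not build a self-avoiding compact walk after bounded retries")
}

# ideal helix tuned to exact 3.8 A consecutive spacing
.helixCoords <- function(n, origin = c(0, 0, 0), down = FALSE) {
  radius <- 2.3; dphi <- 100 * pi / 180
  chord <- 2 * radius * sin(dphi / 2)
  rise <- sqrt(.CA_CA^2 - chord^2)
  i <- seq_len(n) - 1
  z <- i * rise * (if (down) -1 else 1)
  cbind(radius * cos(i * dphi), radius * sin(i * dphi), z) +
    matrix(origin, n, 3, byrow = TRUE)
}

.helixBundle <- function(n) {
  nHelix <- max(2L, as.integer(round(n / 16)))
  loopLen <- 3L
  perHelix <- (n - (nHelix - 1L) * loopLen) %/% nHelix
  extra <- n - (nHelix - 1L) * loopLen - perHelix * nHelix
  lens <- rep(perHelix, nHelix)
  lens[1] <- lens[1] + extra
  xyz <- NULL
  for (h in seq_len(nHelix)) {
    down <- (h %% 2 == 0)
    ox <- (h - 1) * 9.5
    # antiparallel packing: each helix starts near the z-level where the
    # previous one ended and runs the opposite way
    oz <- if (is.null(xyz)) 0 else xyz[nrow(xyz), 3]
    hc <- .helixCoords(lens[h], origin = c(ox, 0, oz), down = down)
    if (!is.null(xyz)) {
      br <- .bridgePath(xyz[nrow(xyz), ], hc[1, ], loopLen, c(0, 1, 0))
      xyz <- rbind(xyz, br)
    }
    xyz <- rbind(xyz, hc)
  }
  xyz
}

#' Specify a synthetic C-alpha test structure
#'
#' Constructor for [ToyStructureSpec-class]; see [genToyStructure()].
#'
#' @param nResidues chain length (10-500).
#' @param fold `"compact_globule"` (self-avoiding confined walk) or
#'   `"helix_bundle"` (ideal helices joined by short loops).
#' @param loopState `"closed"` keeps the native loop; `"open"` replaces the
#'   loop with an outward bulge so the projected size increases.
#' @param loopSpan integer pair, loop residue range.
#' @param seed integer RNG seed.
#' @export
ToyStructureSpec <- function(nResidues = 60L, fold = "compact_globule",
                             loopState = "closed", loopSpan = NULL,
                             seed = 1L) {
  if (is.null(loopSpan))
    loopSpan <- c(floor(0.4 * nResidues), floor(0.65 * nResidues))
  new("ToyStructureSpec", nResidues = as.integer(nResidues), fold = fold,
      loopState = loopState, loopSpan = as.integer(loopSpan),
      seed = as.integer(seed))
}

#' Generate a self-avoiding C-alpha toy structure
#'
#' Builds a C-alpha bead chain with consecutive spacing 3.8 +/- 0.01 A.
#' `compact_globule` grows a self-avoiding walk confined to a sphere whose
#' radius scales as n^(1/3); `helix_bundle` packs ideal alpha-helices joined
#' by short loops. With `loopState = "open"` the designated loop is replaced
#' by an outward arc (anchored at the flanking residues, equal 3.8 A
#' spacing), so the projection-approximation CCS of the open variant exceeds
#' the closed one — a stand-in for closed versus open activation-loop models.
#'
#' @param spec a [ToyStructureSpec-class].
#' @return a [Structure-class] of CA atoms on one chain.
#' @export
#' @examples
#' s <- genToyStructure(ToyStructureSpec(60, seed = 3))
#' range(sqrt(rowSums(diff(coords(s))^2)))  # ~3.8 A
genToyStructure <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  xyz <- switch(spec@fold,
                compact_globule = .compactWalk(spec@nResidues),
                helix_bundle = .helixBundle(spec@nResidues))
  if (spec@loopState == "open") {
    i1 <- spec@loopSpan[1]; i2 <- spec@loopSpan[2]
    A <- xyz[i1 - 1, ]; B <- xyz[i2 + 1, ]
    core <- xyz[-(i1:i2), , drop = FALSE]
    u <- (A + B) / 2 - colMeans(core)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) u <- c(0, 0, 1) else u <- u / nu
    xyz[i1:i2, ] <- .bridgePath(A, B, i2 - i1 + 1L, u)
  }
  n <- nrow(xyz)
  new("Structure", atoms = data.frame(
    eleno = seq_len(n), elety = "CA", elem = "C", resid = "GLY",
    resno = seq_len(n), insert = "", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

#' Generate a pseudo-trajectory of spatially smooth perturbations
#'
#' Each frame is the input structure plus a random displacement field that is
#' smooth along the chain (Gaussian-kernel smoothing of i.i.d. noise over a
#' `smoothWindow`-residue scale). The rigid-body component of each field is
#' removed (Kabsch superposition of the perturbed frame back onto the input)
#' and the remainder rescaled so the per-frame RMS internal displacement
#' equals `amplitude` exactly. Frames are mutually independent. Stands in
#' for snapshots extracted from a molecular-dynamics trajectory when only
#' the magnitude of local motion matters.
#'
#' @param structure a [Structure-class].
#' @param nFrames number of frames (>= 1).
#' @param amplitude RMS displacement per frame, A (>= 0).
#' @param seed integer RNG seed.
#' @param smoothWindow kernel SD along the chain, residues.
#' @return a [Trajectory-class].
#' @export
genPseudoTrajectory <- function(structure, nFrames, amplitude, seed = 1L,
                                smoothWindow = 4) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (nFrames < 1) stop("nFrames must be >= 1")
  set.seed(as.integer(seed))
  X0 <- coords(structure)
  n <- nrow(X0)
  khalf <- max(1L, as.integer(ceiling(3 * smoothWindow)))
  kern <- stats::dnorm(seq(-khalf, khalf), sd = smoothWindow)
  arr <- array(0, dim = c(n, 3, nFrames))
  for (f in seq_len(nFrames)) {
    D <- matrix(stats::rnorm(n * 3), n, 3)
    if (amplitude > 0) {
      for (d in 1:3) {
        padded <- c(rep(D[1, d], khalf), D[, d], rep(D[n, d], khalf))
        D[, d] <- as.numeric(stats::filter(padded, kern / sum(kern),
                                           sides = 2))[khalf + seq_len(n)]
      }
      # strip the rigid-body part so `amplitude` is pure internal motion
      D <- .kabschAlign(X0, X0 + D) - X0
      rms <- sqrt(mean(rowSums(D^2)))
      D <- D * amplitude / rms
    } else D[] <- 0
    arr[, , f] <- X0 + D
  }
  new("Trajectory", atoms = atoms(structure), coords = arr,
      temperature = NA_real_, timestep = NA_real_, saveInterval = 1,
      seed = as.integer(seed),
      energies = data.frame(pe = numeric(0), ke = numeric(0)))
}
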