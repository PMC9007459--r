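.KB <- 0.0019872041  # kcal/mol/K

#' Build a structure-based C-alpha Go-like model
#'
#' Beads are placed at the native C-alpha positions. Bonded terms (harmonic
#' bonds between consecutive beads, harmonic angles over bead triples) take
#' the native geometry as equilibrium. Native contacts are residue pairs at
#' least `minSeparation` apart in sequence whose atoms approach within
#' `contactCutoff`: for all-atom input the criterion is the minimum
#' heavy-atom distance (default cutoff 4.5 A); for C-alpha-only input it is
#' the C-alpha distance (default cutoff 8.0 A, since 4.5 A is below typical
#' C-alpha contact separations). Each contact gets a 12-10 Lennard-Jones-like
#' well of depth `epsilon` minimized at the native C-alpha separation; all
#' other nonlocal pairs repel with a `(sigma/r)^12` excluded-volume term.
#'
#' @param structure a [Structure-class] with >= 10 C-alpha residues.
#' @param contactCutoff contact detection cutoff in A (`NULL` = 4.5 for
#'   all-atom input, 8.0 for C-alpha-only input).
#' @param minSeparation minimum sequence separation |i - j| of a contact.
#' @param epsilon contact well depth, kcal/mol (default 1 kT at 300 K).
#' @param kBond harmonic bond constant, kcal/mol/A^2.
#' @param kAngle harmonic angle constant, kcal/mol/rad^2.
#' @param repSigma nonnative repulsion radius, A.
#' @param repEps repulsion strength, kcal/mol (defaults to `epsilon`).
#' @return a [GoModel-class].
#' @export
#' @examples
#' s <- genToyStructure(ToyStructureSpec(30, "helix_bundle", seed = 1))
#' buildGoModel(s)
buildGoModel <- function(structure, contactCutoff = NULL,
                         minSeparation = 4L, epsilon = .KB * 300,
                         kBond = 100, kAngle = 20, repSigma = 4.0,
                         repEps = epsilon) {
  a <- atoms(structure)
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  n <- nrow(ca)
  if (n < 10) stop("structure needs at least 10 residues with C-alpha")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  consec <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                          xyz[-n, , drop = FALSE])^2))
  gaps <- which(consec > 4.5)
  if (length(gaps))
    stop("chain break(s) between residues ",
         paste(sprintf("%d-%d", ca$resno[gaps], ca$resno[gaps + 1]),
               collapse = ", "))

  allAtom <- any(a$elety != "CA")
  if (is.null(contactCutoff)) contactCutoff <- if (allAtom) 4.5 else 8.0

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= minSeparation, , drop = FALSE]
  if (allAtom) {
    heavy <- a[a$elem != "H", , drop = FALSE]
    resKey <- paste(ca$chain, ca$resno)
    heavyIdx <- split(seq_len(nrow(heavy)),
                      match(paste(heavy$chain, heavy$resno), resKey))
    hxyz <- as.matrix(heavy[, c("x", "y", "z")])
    isContact <- vapply(seq_len(nrow(pairs)), function(r) {
      hi <- heavyIdx[[as.character(pairs[r, 1])]]
      hj <- heavyIdx[[as.character(pairs[r, 2])]]
      if (is.null(hi) || is.null(hj)) return(FALSE)
      d2 <- outer(seq_along(hi), seq_along(hj), function(p, q)
        rowSums((hxyz[hi[p], , drop = FALSE] -
                 hxyz[hj[q], , drop = FALSE])^2))
      min(d2) < contactCutoff^2
    }, logical(1))
  } else {
    d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
    isContact <- d < contactCutoff
  }
  cp <- pairs[isContact, , drop = FALSE]
  sigma <- sqrt(rowSums((xyz[cp[, 1], , drop = FALSE] -
                         xyz[cp[, 2], , drop = FALSE])^2))

  angTheta <- vapply(seq_len(n - 2), function(i) {
    v1 <- xyz[i, ] - xyz[i + 1, ]
    v2 <- xyz[i + 2, ] - xyz[i + 1, ]
    acos(max(-1, min(1, sum(v1 * v2) /
                       sqrt(sum(v1^2) * sum(v2^2)))))
  }, numeric(1))

  new("GoModel",
      beads = data.frame(resno = ca$resno, x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], row.names = NULL),
      bonds = data.frame(i = seq_len(n - 1), j = 2:n, r0 = consec,
                         k = kBond),
      angles = data.frame(i = seq_len(n - 2), j = 2:(n - 1), k_ = 3:n,
                          theta0 = angTheta, kAngle = kAngle),
      dihedrals = data.frame(),
      contacts = data.frame(i = as.integer(cp[, 1]),
                            j = as.integer(cp[, 2]), sigma = sigma,
                            epsilon = rep(epsilon, nrow(cp)),
                            row.names = NULL),
      repSigma = repSigma, repEps = repEps,
      params = list(contactCutoff = contactCutoff,
                    minSeparation = minSeparation, epsilon = epsilon,
                    kBond = kBond, kAngle = kAngle,
                    contactMode = if (allAtom) "heavy_atom" else "ca"))
}

# term list in the layout the C++ kernels expect
.goTerms <- function(model) {
  n <- nrow(model@beads)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 3, , drop = FALSE]
  ckey <- paste(model@contacts$i, model@contacts$j)
  rep_ij <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% ckey), ,
                  drop = FALSE]
  list(bonds_ij = as.matrix(model@bonds[, c("i", "j")]),
       bond_r0 = model@bonds$r0, bond_k = model@bonds$k,
       angles_ijk = as.matrix(model@angles[, c("i", "j", "k_")]),
       angle_theta0 = model@angles$theta0, angle_k = model@angles$kAngle,
       contacts_ij = matrix(as.integer(
         as.matrix(model@contacts[, c("i", "j")])), ncol = 2),
       contact_sigma = as.numeric(model@contacts$sigma),
       contact_eps = as.numeric(model@contacts$epsilon),
       rep_ij = matrix(as.integer(rep_ij), ncol = 2),
       rep_sigma = model@repSigma, rep_eps = model@repEps)
}

#' Potential energy of a Go model at given coordinates
#'
#' @param model a [GoModel-class].
#' @param xyz n x 3 coordinate matrix (default: the native bead positions).
#' @return potential energy, kcal/mol.
#' @export
goEnergy <- function(model, xyz = NULL) {
  if (is.null(xyz)) xyz <- as.matrix(model@beads[, c("x", "y", "z")])
  cpp_go_energy(xyz, .goTerms(model))
}

#' Langevin dynamics of a Go model
#'
#' BAOAB-splitting Langevin integration of the Go-model potential at a
#' target temperature. Positions start from the native structure and
#' velocities from the Maxwell-Boltzmann distribution. Frames and energies
#' are recorded every `saveInterval` steps; a fixed seed gives bit-identical
#' trajectories.
#'
#' @param model a [GoModel-class].
#' @param temperature bath temperature, K.
#' @param nSteps number of integration steps (>= 1).
#' @param timestep integration timestep, fs (at most 15 fs; the 12-10
#'   contact wells destabilise beyond that).
#' @param friction Langevin friction, 1/ps (default 0.2: low friction
#'   accelerates conformational sampling).
#' @param saveInterval steps between saved frames.
#' @param seed RNG seed.
#' @param mass bead mass, amu (default 110, an average residue).
#' @return a [Trajectory-class] with per-frame potential and kinetic
#'   energies.
#' @export
runLangevin <- function(model, temperature, nSteps, timestep = 10,
                        friction = 0.2, saveInterval = 100L, seed = 1L,
                        mass = 110) {
  stopifnot(is(model, "GoModel"))
  if (timestep > 15) stop("timestep must not exceed 15 fs")
  if (nSteps < 1) stop("nSteps must be >= 1")
  saveInterval <- max(1L, as.integer(min(saveInterval, nSteps)))
  set.seed(as.integer(seed))
  xyz <- as.matrix(model@beads[, c("x", "y", "z")])
  out <- cpp_run_langevin(xyz, .goTerms(model), mass, temperature,
                          as.integer(nSteps), timestep, friction / 1000,
                          saveInterval)
  n <- nrow(xyz)
  nSaved <- nrow(out$frames)
  arr <- array(NA_real_, dim = c(n, 3, nSaved))
  for (d in 1:3) arr[, d, ] <- t(out$frames[, (d - 1) * n + seq_len(n),
                                            drop = FALSE])
  new("Trajectory",
      atoms = data.frame(eleno = seq_len(n), elety = "CA", elem = "C",
                         resid = "GLY", resno = model@beads$resno,
                         insert = "", chain = "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         stringsAsFactors = FALSE),
      coords = arr, temperature = temperature, timestep = timestep,
      saveInterval = saveInterval, seed = as.integer(seed),
      energies = data.frame(pe = out$pe, ke = out$ke))
}

#' Fraction of native contacts formed in a frame
#'
#' A contact is formed when the bead distance is below
#' `distanceFactor * sigma_ij` (default factor 1.2, the common convention).
#'
#' @param frame a [Structure-class], or an n x 3 coordinate matrix over the
#'   model beads.
#' @param referenceContacts data.frame with columns `i`, `j`, `sigma`
#'   (e.g. `contacts(model)` or [defineNativeContacts()] output).
#' @param distanceFactor formed-distance multiplier.
#' @return Q in [0, 1].
#' @export
nativeContactFraction <- function(frame, referenceContacts,
                                  distanceFactor = 1.2) {
  if (!nrow(referenceContacts)) stop("reference contact list is empty")
  xyz <- if (is.matrix(frame)) frame else coords(frame)
  d <- sqrt(rowSums((xyz[referenceContacts$i, , drop = FALSE] -
                     xyz[referenceContacts$j, , drop = FALSE])^2))
  mean(d < distanceFactor * referenceContacts$sigma)
}

#' Per-contact occupancy over a trajectory
#'
#' @param traj a [Trajectory-class] over the model beads.
#' @param contacts data.frame with columns `i`, `j`, `sigma`.
#' @param distanceFactor formed-distance multiplier.
#' @return numeric vector: fraction of frames in which each contact is
#'   formed.
#' @export
contactOccupancy <- function(traj, contacts, distanceFactor = 1.2) {
  cc <- coords(traj)
  formed <- vapply(seq_len(dim(cc)[3]), function(f) {
    d <- sqrt(rowSums((cc[contacts$i, , f, drop = FALSE] -
                       cc[contacts$j, , f, drop = FALSE])^2))
    d < distanceFactor * contacts$sigma
  }, logical(nrow(contacts)))
  rowMeans(matrix(formed, nrow = nrow(contacts)))
}

#' Define reference native contacts from a low-temperature run
#'
#' A model contact is retained when it is formed (distance below
#' `distanceFactor * sigma_ij`) in at least `occupancyThreshold` of the
#' frames of a low-temperature simulation — the 80%-occupancy-at-250-K
#' convention for defining native contact distances.
#'
#' @param trajLowT a low-temperature [Trajectory-class] of the model.
#' @param model the [GoModel-class].
#' @param occupancyThreshold occupancy in (0, 1] (default 0.8).
#' @param distanceFactor formed-distance multiplier.
#' @return data.frame of retained contacts with an `occupancy` column.
#' @export
defineNativeContacts <- function(trajLowT, model, occupancyThreshold = 0.8,
                                 distanceFactor = 1.2) {
  stopifnot(occupancyThreshold > 0, occupancyThreshold <= 1)
  occ <- contactOccupancy(trajLowT, contacts(model), distanceFactor)
  keep <- occ >= occupancyThreshold
  if (!any(keep))
    stop("no contact reaches the occupancy threshold")
  out <- contacts(model)[keep, , drop = FALSE]
  out$occupancy <- occ[keep]
  rownames(out) <- NULL
  out
}

#' Locate the unfolding transition by temperature scan
#'
#' Runs the model at each temperature (fresh start from the native
#' structure; the first `equilFraction` of frames is discarded as
#' equilibration), computes the mean native-contact fraction Q, and fits a
#' sigmoid to Q(T). The transition temperature is the fitted midpoint;
#' temperatures below it are flagged production-eligible, following the
#' scan-then-simulate-below protocol.
#'
#' @param model a [GoModel-class].
#' @param temperatures >= 3 increasing temperatures, K.
#' @param stepsPerT integration steps per temperature.
#' @param seed base RNG seed (one offset per temperature).
#' @param equilFraction fraction of frames discarded as equilibration.
#' @param distanceFactor formed-distance multiplier for Q.
#' @param ... passed to [runLangevin()] (timestep, friction, ...).
#' @return list with `tTransition` (K), `table` (data.frame `temperature`,
#'   `meanQ`, `production`).
#' @export
temperatureScan <- function(model, temperatures, stepsPerT, seed = 1L,
                            equilFraction = 0.5, distanceFactor = 1.2,
                            ...) {
  if (length(temperatures) < 3 || any(diff(temperatures) <= 0))
    stop("need >= 3 strictly increasing temperatures")
  ref <- contacts(model)
  meanQ <- vapply(seq_along(temperatures), function(ti) {
    traj <- runLangevin(model, temperatures[ti], stepsPerT,
                        seed = as.integer(seed) + ti, ...)
    cc <- coords(traj)
    nf <- dim(cc)[3]
    useFrames <- seq(floor(nf * equilFraction) + 1, nf)
    mean(vapply(useFrames, function(f)
      nativeContactFraction(cc[, , f], ref, distanceFactor), numeric(1)))
  }, numeric(1))
  if (min(meanQ) >= 0.5)
    stop("no transition in range: Q never drops below 0.5")
  q0 <- max(meanQ); qf <- min(meanQ)
  tm0 <- temperatures[which.min(abs(meanQ - (q0 + qf) / 2))]
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(tm = tm0, w = diff(range(temperatures)) / 10,
            q0 = q0, qf = qf),
    fn = function(p) meanQ - (p["qf"] + (p["q0"] - p["qf"]) *
                                stats::plogis(-(temperatures - p["tm"]) /
                                                p["w"])),
    lower = c(min(temperatures) - 100, 1e-3, 0, 0),
    upper = c(max(temperatures) + 100, diff(range(temperatures)), 1.2,
              1.2),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tTrans <- if (!is.null(fit) && fit$info %in% 1:4) {
    # report the temperature where the fitted sigmoid crosses Q = 0.5 (the
    # same definition the 0.5-crossing error rule uses), not the inflection
    p <- (0.5 - fit$par[["qf"]]) / (fit$par[["q0"]] - fit$par[["qf"]])
    if (p > 0 && p < 1)
      fit$par[["tm"]] - fit$par[["w"]] * stats::qlogis(p)
    else unname(fit$par["tm"])
  } else {
    # fallback: linear interpolation of the 0.5 crossing
    iBelow <- which(meanQ < 0.5)[1]
    stats::approx(meanQ[(iBelow - 1):iBelow],
                  temperatures[(iBelow - 1):iBelow], xout = 0.5,
                  ties = "ordered")$y
  }
  list(tTransition = tTrans,
       table = data.frame(temperature = temperatures, meanQ = meanQ,
                          production = temperatures < tTrans))
}

#' Per-residue RMSF about the ensemble-averaged structure
#'
#' Iterative scheme: all frames are superposed (SVD-based Kabsch) on the
#' running ensemble-average structure, the average is recomputed, and the
#' procedure repeats `passes` times; RMSF is then the per-residue
#' root-mean-square deviation about the final average.
#'
#' @param traj a [Trajectory-class] with >= 2 frames.
#' @param passes refinement passes (default 2).
#' @return numeric vector, one RMSF (A) per residue.
#' @export
trajectoryRMSF <- function(traj, passes = 2L) {
  if (nFrames(traj) < 2) stop("need at least 2 frames")
  cc <- coords(traj)
  n <- dim(cc)[1]; nf <- dim(cc)[3]
  frames <- lapply(seq_len(nf), function(f) cc[, , f])
  avg <- frames[[1]]
  for (pass in seq_len(passes + 1L)) {
    frames <- lapply(frames, function(fr) .kabschAlign(avg, fr))
    avg <- Reduce(`+`, frames) / nf
  }
  dev2 <- vapply(frames, function(fr) rowSums((fr - avg)^2), numeric(n))
  sqrt(rowMeans(matrix(dev2, nrow = n)))
}

#' Leader clustering of trajectory frames at an RMSD cutoff
#'
#' Frames are visited in order; each frame joins the first existing cluster
#' whose representative (founding frame) lies within `rmsdCutoff` best-fit
#' C-alpha RMSD, otherwise it founds a new cluster. The default 15 A cutoff
#' separates folded from globally rearranged conformers.
#'
#' @param traj a [Trajectory-class].
#' @param rmsdCutoff cluster radius, A (> 0).
#' @return list with `assignments` (integer per frame), `representatives`
#'   (frame index founding each cluster), `nClusters`.
#' @export
clusterConformers <- function(traj, rmsdCutoff = 15) {
  stopifnot(rmsdCutoff > 0)
  cc <- coords(traj)
  n <- dim(cc)[1]; nf <- dim(cc)[3]
  mat <- t(vapply(seq_len(nf), function(f) as.numeric(t(cc[, , f])),
                  numeric(3 * n)))
  reps <- 1L
  assignments <- integer(nf)
  assignments[1] <- 1L
  for (f in seq_len(nf)[-1]) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- rmsdKabsch(mat[reps[ci], ], mat[f, ])
      if (r <= rmsdCutoff) {
        assignments[f] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, f)
      assignments[f] <- length(reps)
    }
  }
  list(assignments = assignments, representatives = reps,
       nClusters = length(reps))
}

#' Jensen-Shannon divergence between two binned distributions
#'
#' Used to quantify run-to-run reproducibility of pooled trajectory CCS
#' histograms: counts are normalized to probabilities on a common support
#' and the JS divergence (natural log) is returned.
#'
#' @param p,q nonnegative count/probability vectors of equal length.
#' @return JS divergence in nats (0 = identical, log(2) = disjoint).
#' @export
jsDivergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Best-fit (Kabsch) C-alpha RMSD between two conformers
#'
#' Superposes `b` onto `a` with the SVD-based Kabsch algorithm (proper
#' rotation enforced via the determinant correction, so reflections are
#' never used) and returns the RMSD. Unlike eigendecomposition-based
#' fitting this remains well-defined for degenerate, e.g. collinear,
#' conformers such as fully extended chains.
#'
#' @param a,b n x 3 coordinate matrices (or length-3n xyz vectors).
#' @return RMSD in A.
#' @export
rmsdKabsch <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, byrow = TRUE)
  stopifnot(nrow(a) == nrow(b))
  aligned <- .kabschAlign(a, b)
  sqrt(mean(rowSums((a - aligned)^2)))
}

# superpose `mobile` onto `fixed` (both n x 3); SVD-based Kabsch with the
# determinant correction, stable for rank-deficient configurations
.kabschAlign <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  A <- sweep(fixed, 2, cf)
  B <- sweep(mobile, 2, colMeans(mobile))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(B %*% R, 2, cf, `+`)
}
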