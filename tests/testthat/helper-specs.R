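# canonical study conditions used across the suite: a three-conformer
# landscape (active-kinase-like) and a four-conformer landscape with a
# low-abundance extended state (inactive-kinase-like)

wtMixtureSpec <- function(noiseSD = 0.01, seed = 1L, replicates = 3L) {
  MixtureSpec(data.frame(mean = c(21.5, 23.3, 25.6),
                         fwhm = c(1.2, 1.6, 1.9),
                         fraction = c(0.25, 0.50, 0.25)),
              noiseSD = noiseSD, replicates = replicates, seed = seed)
}

d274nMixtureSpec <- function(noiseSD = 0.01, seed = 7L, replicates = 3L) {
  MixtureSpec(data.frame(mean = c(21.0, 23.0, 25.5, 28.0),
                         fwhm = c(1.2, 1.6, 1.9, 2.0),
                         fraction = c(0.30, 0.45, 0.20, 0.05)),
              noiseSD = noiseSD, replicates = replicates, seed = seed)
}

twoStateCIUSpec <- function(midpoint = 25, steepness = 1, noiseSD = 0.01,
                            seed = 1L) {
  CIUSeriesSpec(states = data.frame(mean = c(22, 26), fwhm = c(1.5, 2)),
                transitions = data.frame(midpoint = midpoint,
                                         steepness = steepness),
                noiseSD = noiseSD, seed = seed)
}

fourStateCIUSpec <- function(noiseSD = 0.01, seed = 1L) {
  CIUSeriesSpec(states = data.frame(mean = c(22, 24.5, 27.5, 32),
                                    fwhm = c(1.5, 1.8, 2.0, 2.5)),
                transitions = data.frame(midpoint = c(21, 25, 29),
                                         steepness = c(1, 1, 1)),
                noiseSD = noiseSD, seed = seed)
}

# generator-truth feature rows for the two-state CIU ladder (center, width,
# span), used when testing the CIU50 estimator in isolation
twoStateFeatures <- function() {
  data.frame(center = c(22, 26), width = c(1.5, 2.0),
             vStart = c(16, 24), vEnd = c(26, 34))
}

toyBundle <- function(n = 30L, seed = 1L) {
  genToyStructure(ToyStructureSpec(n, "helix_bundle", "closed",
                                   c(round(n / 3), round(n / 2)),
                                   seed = seed))
}

caStructure <- function(xyz, resno = seq_len(nrow(xyz))) {
  new("Structure", atoms = data.frame(
    eleno = seq_len(nrow(xyz)), elety = "CA", elem = "C", resid = "GLY",
    resno = resno, insert = "", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

extendedChain <- function(n) {
  caStructure(cbind(3.8 * seq_len(n), 0, 0))
}

# stack two trajectories over the same atom set into one
concatTrajectories <- function(t1, t2) {
  a1 <- coords(t1); a2 <- coords(t2)
  arr <- array(c(a1, a2), dim = c(dim(a1)[1], 3, dim(a1)[3] + dim(a2)[3]))
  new("Trajectory", atoms = atoms(t1), coords = arr,
      temperature = NA_real_, timestep = NA_real_, saveInterval = 1,
      seed = NA_integer_,
      energies = data.frame(pe = numeric(0), ke = numeric(0)))
}

# deterministic quadrature oracle for the two-sphere projected union area:
# spheres of radius r, centers s0 apart; orientation average over a uniform
# grid in cos(theta) of the union area of two disks
twoSphereUnionCCS <- function(r = 1, s0 = 2, nGrid = 10000) {
  u <- (seq_len(nGrid) - 0.5) / nGrid      # cos(angle to viewing axis)
  s <- s0 * sqrt(1 - u^2)                  # projected center separation
  overlap <- ifelse(s >= 2 * r, 0,
                    2 * r^2 * acos(s / (2 * r)) -
                      (s / 2) * sqrt(pmax(4 * r^2 - s^2, 0)))
  mean(2 * pi * r^2 - overlap) / 100       # A^2 -> nm^2
}

# synthetic kinase-like arrangement: a C-alpha chain plus a Phe CZ atom at
# controlled distances from the C-helix anchor and beta3 Lys C-alphas
syntheticKinase <- function(d1 = 8, d2 = 15) {
  helix <- imsfold:::.helixCoords(40)
  a <- data.frame(eleno = seq_len(40), elety = "CA", elem = "C",
                  resid = "GLY", resno = seq(200, 239), insert = "",
                  chain = "A", x = helix[, 1], y = helix[, 2],
                  z = helix[, 3], stringsAsFactors = FALSE)
  # anchors placed 12 A apart; CZ solved in-plane at the requested
  # distances (d1 to the C-helix anchor, d2 to the beta3 Lys)
  qca <- c(30, 0, 0)
  kca <- c(42, 0, 0)
  L <- 12
  xproj <- (d1^2 - d2^2 + L^2) / (2 * L)
  hperp <- sqrt(max(d1^2 - xproj^2, 0.01))
  cz <- qca + c(xproj, hperp, 0)
  extra <- data.frame(eleno = 41:43, elety = c("CA", "CA", "CZ"),
                      elem = "C", resid = c("GLN", "LYS", "PHE"),
                      resno = c(185L, 162L, 275L), insert = "",
                      chain = "A",
                      x = c(qca[1], kca[1], cz[1]),
                      y = c(qca[2], kca[2], cz[2]),
                      z = c(qca[3], kca[3], cz[3]),
                      stringsAsFactors = FALSE)
  new("Structure", atoms = rbind(a, extra))
}
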