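test_that("contact maps match a brute-force pair scan on an ideal helix", {
  helix <- caStructure(imsfold:::.helixCoords(20))
  gm <- buildGoModel(helix)
  # brute-force oracle
  xyz <- coords(helix)
  want <- which(outer(1:20, 1:20, function(i, j) j - i >= 4) &
                as.matrix(stats::dist(xyz)) < 8.0, arr.ind = TRUE)
  want <- want[want[, 1] < want[, 2], , drop = FALSE]
  got <- as.matrix(contacts(gm)[, c("i", "j")])
  expect_equal(got[order(got[, 1], got[, 2]), ],
               want[order(want[, 1], want[, 2]), ], ignore_attr = TRUE)
  expect_true(all(contacts(gm)$j - contacts(gm)$i == 4))

  expect_identical(nrow(contacts(buildGoModel(extendedChain(20)))), 0L)

  broken <- coords(helix)
  broken[11:20, 1] <- broken[11:20, 1] + 50
  expect_error(buildGoModel(caStructure(broken)), "chain break")
})

test_that("the native structure is the energy minimum of its own model", {
  gm <- buildGoModel(toyBundle(30))
  xyz <- as.matrix(beads(gm)[, c("x", "y", "z")])
  e0 <- goEnergy(gm)
  set.seed(4)
  perturbed <- vapply(1:1000, function(i)
    goEnergy(gm, xyz + matrix(stats::rnorm(length(xyz), 0, 0.3),
                              ncol = 3)),
    numeric(1))
  expect_true(all(perturbed > e0))
})

test_that("Langevin dynamics is deterministic, bounded and thermalized", {
  gm <- buildGoModel(toyBundle(30))
  t1 <- runLangevin(gm, 300, 5000, saveInterval = 50, seed = 7)
  t2 <- runLangevin(gm, 300, 5000, saveInterval = 50, seed = 7)
  expect_identical(coords(t1), coords(t2))
  expect_identical(energies(t1), energies(t2))

  expect_error(runLangevin(gm, 300, 100, timestep = 20), "15 fs")

  # frozen limit: at 1 K the fold never leaves the native basin
  cold <- runLangevin(gm, 1, 20000, saveInterval = 200, seed = 1)
  last <- coords(cold)[, , nFrames(cold)]
  r <- rmsdKabsch(as.matrix(beads(gm)[, c("x", "y", "z")]), last)
  expect_lt(r, 1)

  # equipartition at 300 K over 1e5 steps
  hot <- runLangevin(gm, 300, 100000, saveInterval = 100, seed = 2)
  keBar <- mean(energies(hot)$ke[-(1:100)])
  expect_lt(abs(keBar / (1.5 * 30 * 0.0019872041 * 300) - 1), 0.05)
})

test_that("equilibrium Q agrees between the two admissible timesteps", {
  gm <- buildGoModel(toyBundle(30))
  meanQ <- function(dt) {
    tr <- runLangevin(gm, 120, 60000, timestep = dt, saveInterval = 200,
                      seed = 11)
    cc <- coords(tr)
    mean(vapply(seq(dim(cc)[3] / 2, dim(cc)[3]), function(f)
      nativeContactFraction(cc[, , f], contacts(gm)), numeric(1)))
  }
  expect_lt(abs(meanQ(10) - meanQ(15)), 0.05)
})

test_that("native-contact fraction hits its exact limits", {
  gm <- buildGoModel(toyBundle(30))
  native <- as.matrix(beads(gm)[, c("x", "y", "z")])
  expect_identical(nativeContactFraction(native, contacts(gm)), 1)
  expect_identical(nativeContactFraction(coords(extendedChain(30)),
                                         contacts(gm)), 0)
  # constructed frame with exactly half the contacts broken: contact
  # (i, i+4) has distance 5 (formed) for i = 1,2 and 50 (broken) for 3,4
  ct <- data.frame(i = 1:4, j = 5:8, sigma = rep(5, 4))
  frame <- matrix(0, 8, 3)
  frame[1:4, 2] <- (1:4) * 1000
  frame[5:8, 2] <- (1:4) * 1000
  frame[5:8, 1] <- c(5, 5, 50, 50)
  expect_identical(nativeContactFraction(frame, ct), 0.5)
})

test_that("reference contacts follow occupancy thresholds exactly", {
  gm <- buildGoModel(toyBundle(30))
  native <- caStructure(as.matrix(beads(gm)[, c("x", "y", "z")]))
  frozen <- genPseudoTrajectory(native, 10, 0, seed = 1)
  ref <- defineNativeContacts(frozen, gm, 0.8)
  expect_identical(nrow(ref), nrow(contacts(gm)))

  noisy <- genPseudoTrajectory(native, 50, 1.5, seed = 2)
  strict <- tryCatch(defineNativeContacts(noisy, gm, 1.0),
                     error = function(e) contacts(gm)[0, ])
  loose <- defineNativeContacts(noisy, gm, 0.8)
  expect_true(all(paste(strict$i, strict$j) %in%
                  paste(loose$i, loose$j)))

  # one contact broken in exactly 30% of frames: occupancy 0.7
  cc <- coords(frozen)
  pick <- contacts(gm)[1, ]
  for (f in 1:3) cc[pick$j, , f] <- cc[pick$j, , f] + c(40, 0, 0)
  tweaked <- new("Trajectory", atoms = atoms(frozen), coords = cc,
                 temperature = NA_real_, timestep = NA_real_,
                 saveInterval = 1, seed = 1L,
                 energies = data.frame(pe = numeric(0), ke = numeric(0)))
  occ <- contactOccupancy(tweaked, contacts(gm))
  expect_identical(occ[1], 0.7)
  kept <- defineNativeContacts(tweaked, gm, 0.8)
  expect_false(any(kept$i == pick$i & kept$j == pick$j))
  kept7 <- defineNativeContacts(tweaked, gm, 0.7)
  expect_true(any(kept7$i == pick$i & kept7$j == pick$j))
})

test_that("temperature scan flags production temperatures below the transition", {
  gm <- buildGoModel(toyBundle(30))
  sc <- temperatureScan(gm, seq(60, 360, by = 60), stepsPerT = 40000,
                        seed = 4, saveInterval = 200)
  expect_true(sc$tTransition > 60 && sc$tTransition < 360)
  expect_true(all(diff(sc$table$meanQ[c(1, nrow(sc$table))]) < 0))
  expect_true(sc$table$production[1])
  expect_false(sc$table$production[nrow(sc$table)])

  expect_error(temperatureScan(gm, c(1, 2, 3), stepsPerT = 4000,
                               saveInterval = 100, seed = 1),
               "no transition in range")
})

test_that("RMSF vanishes for static or rigidly rotated ensembles", {
  s <- toyBundle(30)
  frozen <- genPseudoTrajectory(s, 5, 0, seed = 1)
  expect_true(all(trajectoryRMSF(frozen) < 1e-9))
  expect_error(trajectoryRMSF(genPseudoTrajectory(s, 1, 0, seed = 1)),
               "2 frames")

  xyz <- coords(s)
  arr <- array(NA_real_, dim = c(nrow(xyz), 3, 6))
  set.seed(8)
  for (f in 1:6) {
    th <- stats::runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
               c(0, 0, 1))
    arr[, , f] <- xyz %*% R + matrix(stats::rnorm(3, 0, 5), nrow(xyz), 3,
                                     byrow = TRUE)
  }
  rot <- new("Trajectory", atoms = atoms(s), coords = arr,
             temperature = NA_real_, timestep = NA_real_,
             saveInterval = 1, seed = 1L,
             energies = data.frame(pe = numeric(0), ke = numeric(0)))
  expect_true(all(trajectoryRMSF(rot) < 0.05))

  wob <- genPseudoTrajectory(s, 300, 2, seed = 3)
  expect_lt(abs(stats::median(trajectoryRMSF(wob)) - 2), 0.5)
})

test_that("leader clustering matches the exhaustive RMSD oracle on two basins", {
  folded <- toyBundle(30)
  unfolded <- extendedChain(30)
  mix <- concatTrajectories(genPseudoTrajectory(folded, 8, 1, seed = 1),
                            genPseudoTrajectory(unfolded, 8, 1, seed = 2))
  cl <- clusterConformers(mix, 15)
  expect_identical(cl$nClusters, 2L)
  expect_identical(cl$assignments, rep(1:2, each = 8))

  # exhaustive pairwise oracle: within-basin < cutoff < across-basin
  cc <- coords(mix)
  vecs <- lapply(1:16, function(f) as.numeric(t(cc[, , f])))
  pm <- outer(1:16, 1:16, Vectorize(function(a, b)
    rmsdKabsch(vecs[[a]], vecs[[b]])))
  expect_lt(max(pm[1:8, 1:8]), 15)
  expect_lt(max(pm[9:16, 9:16]), 15)
  expect_gt(min(pm[1:8, 9:16]), 15)

  same <- genPseudoTrajectory(folded, 6, 0, seed = 1)
  expect_identical(clusterConformers(same, 15)$nClusters, 1L)
  expect_identical(clusterConformers(mix, 1e9)$nClusters, 1L)
  expect_identical(clusterConformers(mix, 1e-9)$nClusters, 16L)
})

test_that("independent seeds reproduce the same CCS landscape", {
  gm <- buildGoModel(toyBundle(30))
  pooled <- function(seed) {
    tr <- runLangevin(gm, 120, 40000, saveInterval = 800, seed = seed)
    trajectoryCCS(tr, nOrientations = 40, nSamplePoints = 4000,
                  seed = seed)$perFrame$ccs
  }
  a <- pooled(1); b <- pooled(2)
  breaks <- seq(floor(min(a, b) * 10) / 10 - 0.1,
                ceiling(max(a, b) * 10) / 10 + 0.1, by = 0.1)
  ha <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts
  hb <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts
  expect_lt(jsDivergence(ha + 0.5, hb + 0.5), 0.05)
})

test_that("Go models serialize to JSON and back", {
  gm <- buildGoModel(toyBundle(30))
  f <- tempfile(fileext = ".json")
  writeGoModel(gm, f)
  gm2 <- readGoModel(f)
  expect_equal(contacts(gm2), contacts(gm))
  expect_equal(beads(gm2), beads(gm))
  expect_equal(goEnergy(gm2), goEnergy(gm))
})
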