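test_that("noiseless mixture profiles peak at the component mean and conserve area", {
  sp <- MixtureSpec(data.frame(mean = 23, fwhm = 1, fraction = 1),
                    noiseSD = 0, replicates = 1L, seed = 1L)
  p <- genMixtureProfile(sp)[[1]]
  expect_equal(ccsAxis(p)[which.max(intensity(p))], 23, tolerance = 1e-12)

  sp3 <- MixtureSpec(data.frame(mean = c(20, 24, 28),
                                fwhm = c(0.8, 0.8, 0.8),
                                fraction = c(0.2, 0.55, 0.25)),
                     axis = c(16, 32, 0.01), noiseSD = 0, replicates = 1L)
  p3 <- genMixtureProfile(sp3)[[1]]
  y <- intensity(p3); ax <- ccsAxis(p3)
  total <- sum(y) * 0.01
  expect_equal(total, 1, tolerance = 1e-6)
  # well-separated components: windowed integrals recover the fractions
  shares <- vapply(c(20, 24, 28), function(m)
    sum(y[abs(ax - m) <= 2]) * 0.01, numeric(1))
  expect_equal(shares, c(0.2, 0.55, 0.25), tolerance = 1e-6)
})

test_that("mixture generation is reproducible and validates its spec", {
  sp <- wtMixtureSpec(seed = 5L)
  a <- genMixtureProfile(sp)
  b <- genMixtureProfile(sp)
  expect_identical(lapply(a, intensity), lapply(b, intensity))
  expect_length(a, 3)

  expect_error(MixtureSpec(data.frame(mean = 23, fwhm = 1,
                                      fraction = 0.9)),
               "fractions")
  expect_error(MixtureSpec(data.frame(mean = 23, fwhm = -1,
                                      fraction = 1)), "fwhm")
  expect_error(MixtureSpec(data.frame(mean = 50, fwhm = 1, fraction = 1)),
               "inside the axis range")
})

test_that("CIU series follows logistic hand-offs with unit total occupancy", {
  sp <- twoStateCIUSpec(midpoint = 25, steepness = 1, noiseSD = 0)
  series <- genCIUSeries(sp)
  expect_length(series, 10)  # 16-34 V in 2 V steps
  occ <- stateOccupancies(sp, seq(16, 34, by = 0.5))
  expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
  expect_equal(stateOccupancies(sp, 25)[1, 2], 0.5, tolerance = 1e-9)

  single <- CIUSeriesSpec(states = data.frame(mean = 23, fwhm = 1.5),
                          noiseSD = 0, seed = 1L)
  profs <- genCIUSeries(single)
  for (e in profs[-1])
    expect_equal(intensity(e$profile), intensity(profs[[1]]$profile))

  expect_error(CIUSeriesSpec(states = data.frame(mean = c(22, 26),
                                                 fwhm = c(1, 1)),
                             transitions = data.frame(midpoint = 25,
                                                      steepness = 1),
                             voltages = c(20, 18, 16)),
               "strictly increasing")
})

test_that("calibrant generator validates inputs", {
  tab <- data.frame(name = "x", mass_da = 12000, charge = 7,
                    lit_ccs_nm2 = 17)
  expect_s3_class(genCalibrants(2, 0.55, tab), "data.frame")
  expect_error(genCalibrants(2, 0.55, tab[0, ]), "empty")
  expect_error(genCalibrants(2, 2.5, tab), "\\(0, 2\\)")
  tab$lit_ccs_nm2 <- -1
  expect_error(genCalibrants(2, 0.55, tab), "positive")
})

test_that("toy structures have exact C-alpha spacing and are reproducible", {
  for (fold in c("compact_globule", "helix_bundle")) {
    s <- genToyStructure(ToyStructureSpec(48, fold, "closed", c(20, 32),
                                          seed = 3))
    d <- sqrt(rowSums(diff(coords(s))^2))
    expect_true(all(abs(d - 3.8) <= 0.01), label = fold)
  }
  s1 <- genToyStructure(ToyStructureSpec(40, seed = 9))
  s2 <- genToyStructure(ToyStructureSpec(40, seed = 9))
  expect_identical(coords(s1), coords(s2))

  expect_error(ToyStructureSpec(5), "nResidues")
  expect_error(ToyStructureSpec(40, loopSpan = c(30, 20)), "loopSpan")
})

test_that("opening the loop increases the C-alpha-bead CCS by more than 2%", {
  closed <- genToyStructure(ToyStructureSpec(60, "compact_globule",
                                             "closed", c(25, 40), seed = 5))
  open <- genToyStructure(ToyStructureSpec(60, "compact_globule", "open",
                                           c(25, 40), seed = 5))
  d <- sqrt(rowSums(diff(coords(open))^2))
  expect_true(all(abs(d - 3.8) <= 0.01))
  ratio <- caCCS(open, 100, 10000, seed = 1)@ccs /
    caCCS(closed, 100, 10000, seed = 1)@ccs
  expect_gt(ratio, 1.02)
})

test_that("pseudo-trajectories realise the requested internal RMS amplitude", {
  s <- toyBundle(30)
  t0 <- genPseudoTrajectory(s, 5, 0, seed = 1)
  for (f in 1:5) expect_equal(coords(t0)[, , f], coords(s))

  tr <- genPseudoTrajectory(s, 100, 2, seed = 2)
  rmsd <- vapply(1:100, function(f)
    sqrt(mean(rowSums((coords(tr)[, , f] - coords(s))^2))), numeric(1))
  expect_equal(mean(rmsd), 2, tolerance = 0.2)

  expect_error(genPseudoTrajectory(s, 10, -1), "amplitude")
  expect_error(genPseudoTrajectory(s, 0, 1), "nFrames")
})
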