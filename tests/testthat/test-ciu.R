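test_that("fingerprints are row-normalized and invariant to input scaling", {
  series <- genCIUSeries(twoStateCIUSpec(seed = 3L))
  fp <- buildFingerprint(series)
  expect_identical(nrow(fingerprintMatrix(fp)), 10L)
  expect_true(all(abs(apply(fingerprintMatrix(fp), 1, max) - 1) < 1e-12))

  scaled <- series
  scaled[[4]]$profile@intensity <- scaled[[4]]$profile@intensity * 5
  expect_equal(fingerprintMatrix(buildFingerprint(scaled)),
               fingerprintMatrix(fp))

  # normalization is idempotent
  renorm <- lapply(seq_along(series), function(i)
    list(voltage = series[[i]]$voltage,
         profile = CCSProfile(ccsAxis(fp), fingerprintMatrix(fp)[i, ])))
  expect_equal(fingerprintMatrix(buildFingerprint(renorm)),
               fingerprintMatrix(fp))
})

test_that("fingerprint assembly rejects bad input and resamples mixed axes", {
  series <- genCIUSeries(twoStateCIUSpec(seed = 3L))
  expect_error(buildFingerprint(series[1:2]), "at least 3")
  zeroed <- series
  zeroed[[5]]$profile@intensity[] <- 0
  expect_error(buildFingerprint(zeroed), "24")

  mixed <- series
  p <- mixed[[2]]$profile
  mixed[[2]]$profile <- CCSProfile(ccsAxis(p) + 0.013, intensity(p))
  fp <- buildFingerprint(mixed)
  expect_false(any(is.na(fingerprintMatrix(fp))))
})

test_that("feature detection recovers the generator's state ladder", {
  fp4 <- buildFingerprint(genCIUSeries(fourStateCIUSpec(seed = 5L)))
  fe <- detectFeatures(fp4)
  expect_identical(nrow(fe), 4L)
  expect_lt(max(abs(fe$center - c(22, 24.5, 27.5, 32))), 0.3)

  single <- CIUSeriesSpec(states = data.frame(mean = 23, fwhm = 1.5),
                          noiseSD = 0.005, seed = 2L)
  fp1 <- buildFingerprint(genCIUSeries(single))
  fe1 <- detectFeatures(fp1)
  expect_identical(nrow(fe1), 1L)
  expect_identical(c(fe1$vStart, fe1$vEnd), c(16, 34))

  expect_identical(nrow(detectFeatures(fp4, minPersistence = 99L)), 0L)
})

test_that("feature count is stable under rescaling and axis-resolution doubling", {
  for (seed in 1:10) {
    sp <- fourStateCIUSpec(seed = seed)
    n1 <- nrow(detectFeatures(buildFingerprint(genCIUSeries(sp))))
    spFine <- CIUSeriesSpec(states = sp@states,
                            transitions = sp@transitions,
                            voltages = sp@voltages,
                            axis = c(sp@axis[1], sp@axis[2],
                                     sp@axis[3] / 2),
                            noiseSD = sp@noiseSD, seed = seed)
    n2 <- nrow(detectFeatures(buildFingerprint(genCIUSeries(spFine))))
    expect_identical(n1, n2)
  }
})

test_that("CIU50 recovers the generator midpoint and honours its window", {
  fp <- buildFingerprint(genCIUSeries(twoStateCIUSpec(midpoint = 25,
                                                      seed = 11L)))
  fe <- twoStateFeatures()
  expect_lt(abs(ciu50(fp, fe[1, ], fe[2, ]) - 25), 0.2)

  # midpoint outside the stepped window: transition never completes
  fpOut <- buildFingerprint(genCIUSeries(twoStateCIUSpec(midpoint = 45,
                                                         seed = 11L)))
  expect_error(ciu50(fpOut, fe[1, ], fe[2, ]), "incomplete")

  # near-step transition: estimate within one 2 V grid step
  fpStep <- buildFingerprint(genCIUSeries(
    twoStateCIUSpec(midpoint = 25, steepness = 1000, seed = 11L)))
  est <- ciu50(fpStep, fe[1, ], fe[2, ])
  expect_lt(abs(est - 25), 2 + 1e-9)
})

test_that("fingerprint RMSD is a symmetric pseudometric that separates real shifts", {
  fpA <- buildFingerprint(genCIUSeries(twoStateCIUSpec(midpoint = 24,
                                                       seed = 21L)))
  expect_identical(fingerprintRMSD(fpA, fpA), 0)

  fpB <- buildFingerprint(genCIUSeries(twoStateCIUSpec(midpoint = 26,
                                                       seed = 22L)))
  expect_lt(abs(fingerprintRMSD(fpA, fpB) - fingerprintRMSD(fpB, fpA)),
            1e-12)

  # replicate-noise null: same midpoint, different seeds
  null <- vapply(1:10, function(s) {
    a <- buildFingerprint(genCIUSeries(twoStateCIUSpec(24, seed = 100 + s)))
    b <- buildFingerprint(genCIUSeries(twoStateCIUSpec(24, seed = 200 + s)))
    fingerprintRMSD(a, b)
  }, numeric(1))
  expect_gt(fingerprintRMSD(fpA, fpB), max(null))

  fpHigh <- buildFingerprint(genCIUSeries(
    CIUSeriesSpec(states = data.frame(mean = 23, fwhm = 1.5),
                  voltages = seq(50, 60, 2), seed = 1L)))
  expect_error(fingerprintRMSD(fpA, fpHigh), "disjoint")
})
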