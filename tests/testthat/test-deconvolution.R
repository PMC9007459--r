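test_that("a single noiseless Gaussian is recovered exactly", {
  sp <- MixtureSpec(data.frame(mean = 23, fwhm = 1.2, fraction = 1),
                    noiseSD = 0, replicates = 1L)
  fit <- fitConformers(genMixtureProfile(sp)[[1]], 1)
  expect_lt(abs(components(fit)$ccs - 23), 1e-6)
  expect_lt(abs(components(fit)$ccsd - 1.2), 1e-5)
  expect_equal(components(fit)$fraction, 100)
  expect_gt(rSquared(fit), 1 - 1e-9)
})

test_that("a four-conformer landscape with a 5% extended state is recovered", {
  sp <- d274nMixtureSpec(noiseSD = 0.01, seed = 7L)
  prof <- averageProfiles(genMixtureProfile(sp))
  fit <- fitConformers(prof, 4)
  expect_lt(max(abs(components(fit)$ccs - sp@components$mean)), 0.15)
  expect_lt(max(abs(components(fit)$fraction -
                    100 * sp@components$fraction)), 3)
})

test_that("over-fitting is flagged or starved of area", {
  sp <- wtMixtureSpec(noiseSD = 0.01, seed = 3L)
  prof <- averageProfiles(genMixtureProfile(sp))
  fit <- suppressWarnings(fitConformers(prof, 4))
  expect_true(fit@crowded || any(components(fit)$fraction < 2))
})

test_that("fit quality is non-decreasing in the component count", {
  for (seed in c(2L, 11L)) {
    prof <- averageProfiles(genMixtureProfile(wtMixtureSpec(seed = seed)))
    r2 <- vapply(1:4, function(k)
      rSquared(suppressWarnings(fitConformers(prof, k))), numeric(1))
    expect_true(all(diff(r2) > -1e-6))
  }
})

test_that("component count selection matches the generator truth", {
  single <- MixtureSpec(data.frame(mean = 23, fwhm = 1.5, fraction = 1),
                        noiseSD = 0.01, replicates = 1L, seed = 2L)
  expect_identical(selectComponentCount(genMixtureProfile(single)[[1]]), 1L)
  wt <- averageProfiles(genMixtureProfile(wtMixtureSpec(seed = 4L)))
  expect_identical(selectComponentCount(wt), 3L)
  mut <- averageProfiles(genMixtureProfile(d274nMixtureSpec(seed = 4L)))
  expect_identical(selectComponentCount(mut), 4L)
})

test_that("weighted mean CCS is exact on symmetric cases and closed forms", {
  sp <- MixtureSpec(data.frame(mean = 23.9, fwhm = 1.5, fraction = 1),
                    axis = c(16, 32, 0.01), noiseSD = 0, replicates = 1L)
  expect_lt(abs(weightedMeanCCS(genMixtureProfile(sp)[[1]]) - 23.9), 1e-6)

  two <- MixtureSpec(data.frame(mean = c(21, 25), fwhm = c(1.5, 1.5),
                                fraction = c(0.5, 0.5)),
                     axis = c(14, 32, 0.01), noiseSD = 0, replicates = 1L)
  expect_lt(abs(weightedMeanCCS(genMixtureProfile(two)[[1]]) - 23), 1e-6)

  sp3 <- wtMixtureSpec(noiseSD = 0, replicates = 1L)
  analytic <- sum(sp3@components$fraction * sp3@components$mean)
  expect_lt(abs(weightedMeanCCS(genMixtureProfile(sp3)[[1]]) - analytic),
            0.02)

  empty <- CCSProfile(seq(20, 21, 0.1), rep(0, 11))
  expect_error(weightedMeanCCS(empty), "zero total intensity")
})

test_that("area fractions are canonical and sum to 100", {
  sp <- wtMixtureSpec(seed = 6L)
  prof <- averageProfiles(genMixtureProfile(sp))
  fit <- fitConformers(prof, 3)
  fr <- areaFractions(fit)
  expect_equal(sum(fr), 100, tolerance = 1e-9)
  expect_lt(max(abs(fr - 100 * sp@components$fraction)), 3)
  expect_identical(names(fr), c("I", "II", "III"))
  # permuting the initial component order leaves the sorted result unchanged
  init <- imsfold:::.pickInits(ccsAxis(prof), intensity(prof), 3)
  fit2 <- fitConformers(prof, 3, init = init[c(3, 1, 2), ])
  expect_equal(components(fit2)$ccs, components(fit)$ccs, tolerance = 1e-4)
})

test_that("landscape comparison matches, gains and loses components correctly", {
  wt <- fitConformers(averageProfiles(genMixtureProfile(
    wtMixtureSpec(seed = 8L))), 3)
  delta <- compareLandscapes(wt, wt)
  expect_identical(nrow(delta@matched), 3L)
  expect_true(all(abs(delta@matched$dCCS) < 1e-12))
  expect_identical(nrow(delta@gained), 0L)
  expect_identical(nrow(delta@lost), 0L)

  mut <- fitConformers(averageProfiles(genMixtureProfile(
    d274nMixtureSpec(seed = 8L))), 4)
  d2 <- compareLandscapes(wt, mut)
  expect_identical(nrow(d2@gained), 1L)
  expect_gt(d2@gained$ccs, 27)  # the conformer IV analogue

  # a 7% shift exceeds the 3% matching tolerance: lost + gained, not matched
  oneAt <- function(m) {
    sp <- MixtureSpec(data.frame(mean = m, fwhm = 1.5, fraction = 1),
                      noiseSD = 0, replicates = 1L)
    fitConformers(genMixtureProfile(sp)[[1]], 1)
  }
  d3 <- compareLandscapes(oneAt(23), oneAt(23 * 1.07))
  expect_identical(nrow(d3@matched), 0L)
  expect_identical(nrow(d3@lost), 1L)
  expect_identical(nrow(d3@gained), 1L)
})
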