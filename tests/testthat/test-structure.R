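test_that("PDB writer/reader round-trips coordinates to 3 decimals", {
  s <- genToyStructure(ToyStructureSpec(60, seed = 3))
  f <- tempfile(fileext = ".pdb")
  writePDB(s, f)
  s2 <- readPDB(f)
  expect_identical(nrow(atoms(s2)), 60L)
  expect_equal(coords(s2), round(coords(s), 3), ignore_attr = TRUE)

  traj <- genPseudoTrajectory(s, 5, 1, seed = 1)
  writePDB(traj, f)
  t2 <- readPDB(f)
  expect_s4_class(t2, "Trajectory")
  expect_identical(nFrames(t2), 5L)

  expect_error(readPDB(tempfile()), "no such file")
})

test_that("PDB filters drop heteroatoms and resolve altLoc by occupancy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), f)
  s <- readPDB(f)
  expect_identical(nrow(atoms(s)), 2L)          # waters out, one altLoc kept
  expect_equal(atoms(s)$x[1], 1.0)              # highest occupancy wins

  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(readPDB(f), "zero atoms")
})

test_that("projection approximation reproduces the analytic disk", {
  one <- caStructure(matrix(0, 1, 3))
  pa <- paCCS(one, nOrientations = 100, nSamplePoints = 40000,
              probeRadius = 0, radiusTable = c(C = 1), seed = 2)
  expect_lt(abs(pa@ccs - pi / 100), 3 * pa@stderr + 1e-6)

  # coincident spheres add nothing
  two <- caStructure(matrix(0, 2, 3))
  pa2 <- paCCS(two, nOrientations = 100, nSamplePoints = 40000,
               probeRadius = 0, radiusTable = c(C = 1), seed = 2)
  expect_lt(abs(pa2@ccs - pa@ccs), 3 * sqrt(pa@stderr^2 + pa2@stderr^2))
})

test_that("two-sphere union area matches the quadrature oracle within 1%", {
  s <- caStructure(rbind(c(0, 0, 0), c(2, 0, 0)))
  pa <- paCCS(s, nOrientations = 4000, nSamplePoints = 10000,
              probeRadius = 0, radiusTable = c(C = 1), seed = 5)
  expect_lt(abs(pa@ccs - twoSphereUnionCCS()) / twoSphereUnionCCS(), 0.01)
})

test_that("PA CCS is invariant to rigid motion and mirroring, monotone in atoms", {
  s <- toyBundle(30)
  base <- caCCS(s, 150, 20000, seed = 3)
  xyz <- coords(s)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- caStructure(xyz %*% R + matrix(c(5, -3, 11), nrow(xyz), 3,
                                        byrow = TRUE))
  pa <- caCCS(rot, 150, 20000, seed = 4)
  expect_lt(abs(pa@ccs - base@ccs),
            3 * sqrt(pa@stderr^2 + base@stderr^2))

  mir <- caStructure(xyz %*% diag(c(-1, 1, 1)))
  pm <- caCCS(mir, 150, 20000, seed = 5)
  expect_lt(abs(pm@ccs - base@ccs),
            3 * sqrt(pm@stderr^2 + base@stderr^2))

  grown <- caStructure(rbind(xyz, xyz[30, ] + c(25, 0, 0)))
  pg <- caCCS(grown, 150, 20000, seed = 6)
  expect_gt(pg@ccs - base@ccs,
            -3 * sqrt(pg@stderr^2 + base@stderr^2))
})

test_that("Monte-Carlo standard error shrinks as sqrt(orientations)", {
  s <- toyBundle(30)
  ratios <- vapply(1:25, function(seed) {
    a <- caCCS(s, 60, 4000, seed = seed)
    b <- caCCS(s, 120, 4000, seed = 1000 + seed)
    a@stderr / b@stderr
  }, numeric(1))
  expect_lt(abs(mean(ratios) - sqrt(2)), 0.2 * sqrt(2))
})

test_that("C-alpha-bead mode uses the 3.8 A radius convention", {
  one <- caStructure(matrix(0, 1, 3))
  pa <- caCCS(one, 100, 40000, seed = 7)
  expect_lt(abs(pa@ccs - pi * 0.38^2), 3 * pa@stderr + 1e-6)
  expect_identical(pa@mode, "ca_bead")

  # on a mixed all-atom structure, caCCS uses only the CA positions
  sk <- syntheticKinase()
  caOnly <- atoms(sk)[atoms(sk)$elety == "CA", ]
  direct <- caCCS(new("Structure", atoms = caOnly), 80, 10000, seed = 8)
  mixed <- caCCS(sk, 80, 10000, seed = 8)
  expect_equal(mixed@ccs, direct@ccs)

  noCA <- new("Structure", atoms = within(atoms(one), elety <- "CB"))
  expect_error(caCCS(noCA), "C-alpha")
  expect_error(paCCS(toyBundle(12), radiusTable = c(H = 1)),
               "no radius defined .*C")
})

test_that("DFG distances are exact on constructed geometry", {
  a <- data.frame(eleno = 1:3, elety = c("CZ", "CA", "CA"), elem = "C",
                  resid = c("PHE", "GLN", "LYS"),
                  resno = c(275L, 185L, 162L), insert = "", chain = "A",
                  x = c(0, 11, 5), y = 0, z = 0)
  g <- dfgGeometry(new("Structure", atoms = a))
  expect_identical(round(g$d1, 3), 11)
  expect_identical(round(g$d2, 3), 5)
  expect_identical(g$label, "DFG_out")

  # chain order must not matter
  b <- new("Structure", atoms = a[c(3, 1, 2), ])
  g2 <- dfgGeometry(b)
  expect_identical(c(g2$d1, g2$d2), c(g$d1, g$d2))

  expect_error(dfgGeometry(new("Structure", atoms = a[-1, ])), "275")
  caOnlyPhe <- a
  caOnlyPhe$elety[1] <- "CA"
  expect_error(dfgGeometry(new("Structure", atoms = caOnlyPhe)),
               "C-alpha-only")
})

test_that("DFG classification follows the two-distance rule with closed ties", {
  expect_identical(classifyDFG(8, 15), "DFG_in")
  expect_identical(classifyDFG(15, 8), "DFG_out")
  expect_identical(classifyDFG(14, 14), "DFG_inter")
  expect_identical(classifyDFG(11, 11), "DFG_in")     # tie rule
  # swapping d1 and d2 for an in-region point gives DFG_out
  expect_identical(classifyDFG(15, 8),
                   ifelse(classifyDFG(8, 15) == "DFG_in", "DFG_out", NA))
  expect_error(classifyDFG(8, 15, c(t1 = 12, t1p = 11, t2 = 11,
                                    t2p = 11)), "inconsistent")
  expect_error(classifyDFG(-1, 5), "positive")
})

test_that("trajectory CCS strides frames and separates open from closed toys", {
  s <- toyBundle(30)
  frozen <- genPseudoTrajectory(s, 100, 0, seed = 1)
  res <- trajectoryCCS(frozen, stride = 10, nOrientations = 60,
                       nSamplePoints = 6000, seed = 2)
  expect_identical(nrow(res$perFrame), 10L)
  static <- caCCS(s, 60, 6000, seed = 3)
  expect_true(all(abs(res$perFrame$ccs - static@ccs) <
                  3 * sqrt(res$perFrame$stderr^2 + static@stderr^2)))

  closed <- genToyStructure(ToyStructureSpec(60, "compact_globule",
                                             "closed", c(25, 40), seed = 5))
  open <- genToyStructure(ToyStructureSpec(60, "compact_globule", "open",
                                           c(25, 40), seed = 5))
  tc <- trajectoryCCS(genPseudoTrajectory(closed, 30, 1, seed = 1),
                      nOrientations = 60, nSamplePoints = 6000, seed = 4)
  to <- trajectoryCCS(genPseudoTrajectory(open, 30, 1, seed = 2),
                      nOrientations = 60, nSamplePoints = 6000, seed = 5)
  pooledSD <- sqrt((stats::var(tc$perFrame$ccs) +
                    stats::var(to$perFrame$ccs)) / 2)
  expect_gt(mean(to$perFrame$ccs) - mean(tc$perFrame$ccs), 2 * pooledSD)
})

test_that("structures group by DFG class with per-group mean CCS", {
  dirIn <- tempfile(); dir.create(dirIn)
  fIn <- file.path(dirIn, "in_model.pdb")
  fOut <- file.path(dirIn, "out_model.pdb")
  writePDB(syntheticKinase(d1 = 8, d2 = 15), fIn)
  writePDB(syntheticKinase(d1 = 15, d2 = 8), fOut)
  res <- groupCCSByDFG(c(fIn, fOut), resnoRange = c(122, 403),
                       nOrientations = 40, nSamplePoints = 4000)
  expect_setequal(res$perStructure$group, c("DFG_in", "DFG_out"))
  expect_identical(nrow(res$groupMeans), 2L)
  expect_true(all(res$groupMeans$mean_ccs_nm2 > 0))
})
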