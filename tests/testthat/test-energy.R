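test_that("the shifted kernels match an independent force-integration oracle", {
  rs <- c(0.3, 0.5275, 0.8, 0.95, 1.1, 1.19)
  expect_equal(shiftedLJ(rs, 3.5, 0.47),
               shiftedLJOracle(rs, 3.5, 0.47), tolerance = 1e-9)
  coul <- shiftedCoulomb(rs, 1, -1, epsR = 15)
  oracle <- (138.935485 * -1 / 15) * shiftedKernelOracle(rs, 1, 0, 1.2)
  expect_equal(coul, oracle, tolerance = 1e-9)
})

test_that("the potential vanishes beyond the cutoff and is continuous at it", {
  expect_identical(shiftedLJ(c(1.2000001, 1.5, 10), 3.5, 0.47), c(0, 0, 0))
  expect_lt(abs(shiftedLJ(1.2 - 1e-9, 3.5, 0.47)), 1e-6)
  expect_identical(shiftedCoulomb(1.21, 1, 1), 0)
})

test_that("below the shift onset the LJ well keeps its -epsilon depth up to a constant", {
  eps <- 3.5; sigma <- 0.47
  rmin <- sigma * 2^(1 / 6)
  raw <- function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  expect_equal(raw(rmin), -eps, tolerance = 1e-12)
  # for r < rShift the shifted form differs from the raw LJ by the same
  # constant everywhere
  off1 <- shiftedLJ(rmin, eps, sigma) - raw(rmin)
  off2 <- shiftedLJ(0.6, eps, sigma) - raw(0.6)
  expect_equal(off1, off2, tolerance = 1e-12)
})

test_that("cell-list energies equal the brute-force double loop", {
  nb <- buildNonbondedMatrix()
  fr <- buildBilayer(tinyComp(20, 30, 10, box = 8), phaseLayout("mixed"),
                     seed = 21)
  fast <- pairEnergy(fr, nb)
  slow <- bruteForceEnergy(fr, nb)
  key <- paste(fast$pairs$speciesA, fast$pairs$speciesB, sep = "|")
  expect_setequal(key, slow$key)
  m <- match(slow$key, key)
  expect_equal(fast$pairs$total[m], slow$total, tolerance = 1e-10)
  # also on a larger frame near the stated bound
  fr2 <- buildBilayer(tinyComp(35, 45, 20, box = 10),
                      phaseLayout("separated"), seed = 22)
  fast2 <- pairEnergy(fr2, nb)
  slow2 <- bruteForceEnergy(fr2, nb)
  m2 <- match(slow2$key, paste(fast2$pairs$speciesA, fast2$pairs$speciesB,
                               sep = "|"))
  expect_equal(fast2$pairs$total[m2], slow2$total, tolerance = 1e-10)
})

test_that("energies are invariant under rigid translation and re-wrapping", {
  nb <- buildNonbondedMatrix()
  fr <- buildBilayer(tinyComp(15, 20, 8, box = 7), phaseLayout("mixed"),
                     seed = 23)
  base <- pairEnergy(fr, nb)
  sh <- fr
  sh@unwrapped[, 1] <- sh@unwrapped[, 1] + 3.17
  sh@unwrapped[, 2] <- sh@unwrapped[, 2] - 1.41
  sh@coords <- cgraft:::.wrapXY(sh@unwrapped, sh@box)
  moved <- pairEnergy(sh, nb)
  expect_equal(moved$pairs$total, base$pairs$total, tolerance = 1e-9)
  expect_equal(moved$perSpecies$total, base$perSpecies$total,
               tolerance = 1e-9)
})

test_that("isolated bead pairs reproduce hand-computed energies", {
  nb <- buildNonbondedMatrix()
  # two single-bead molecules: an uncharged C1 pair at the LJ minimum
  rmin <- 0.47 * 2^(1 / 6)
  df <- data.frame(molecule = c(1, 2), species = c("DPPC", "DUPC"),
                   beadIndex = 1, type = "C1", role = "chain", charge = 0,
                   leaflet = "upper",
                   x = c(2, 2 + rmin), y = 2, z = 2)
  en <- pairEnergy(toyFrame(df, box = c(8, 8)), nb)
  expect_equal(en$pairs$total, shiftedLJ(rmin, 3.5, 0.47), tolerance = 1e-12)
  # charged pair adds the shifted Coulomb term
  df$charge <- c(1, -1)
  df$type <- c("Q0", "Qa")
  en2 <- pairEnergy(toyFrame(df, box = c(8, 8)), nb)
  expected <- shiftedLJ(rmin, vdwEpsilon(nb, "Q0", "Qa"), 0.47) +
    shiftedCoulomb(rmin, 1, -1)
  expect_equal(en2$pairs$total, expected, tolerance = 1e-12)
  # beads beyond the cutoff contribute exactly nothing
  df$x <- c(1, 2.5); df$charge <- 0; df$type <- "C1"
  en3 <- pairEnergy(toyFrame(df, box = c(8, 8)), nb)
  expect_true(nrow(en3$pairs) == 0 || all(en3$pairs$total == 0))
})

test_that("minimum-image interactions cross the periodic boundary", {
  nb <- buildNonbondedMatrix()
  df <- data.frame(molecule = c(1, 2), species = c("DPPC", "DPPC"),
                   beadIndex = 1, type = "C1", role = "chain", charge = 0,
                   leaflet = "upper",
                   x = c(0.1, 7.9), y = 2, z = 2)   # 0.2 nm through the wall
  en <- pairEnergy(toyFrame(df, box = c(8, 8)), nb)
  # one interaction between two DPPC molecules, normalised per molecule
  expect_equal(en$pairs$total, shiftedLJ(0.2, 3.5, 0.47) / 2,
               tolerance = 1e-10)
  # missing bead types are diagnosed
  df$type <- "ZZ"
  expect_error(pairEnergy(toyFrame(df, box = c(8, 8)), nb), "missing")
})
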