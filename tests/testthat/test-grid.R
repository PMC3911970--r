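test_that("grid densities conserve molecule counts per leaflet", {
  fr <- buildBilayer(tinyComp(), phaseLayout("separated"), seed = 2)
  mt <- moleculeTable(fr)
  for (leaf in c("upper", "lower")) for (sp in c("DPPC", "DUPC", "CHOL")) {
    g <- gridDensity(fr, leaf, sp, 1.5)
    expect_equal(sum(gridValues(g)),
                 sum(mt$species == sp & mt$leaflet == leaf))
  }
  expect_error(gridDensity(fr, "upper", "DPPC", cellSize = 50), "cellSize")
})

test_that("a single molecule occupies exactly one cell", {
  df <- data.frame(molecule = 1, species = "DPPC", beadIndex = 1,
                   type = "Q0", role = "head", charge = 1,
                   leaflet = "upper", x = 3.2, y = 7.7, z = 2)
  g <- gridDensity(toyFrame(df), "upper", "DPPC", 1.5)
  expect_equal(sum(gridValues(g) != 0), 1)
  expect_equal(sum(gridValues(g)), 1)
})

test_that("stripe layouts leave the complementary region empty", {
  comp <- tinyComp(40, 60, 20, box = 11)
  fr <- buildBilayer(comp, phaseLayout("separated", registration = 1),
                     seed = 3)
  bd <- beadData(fr)
  heads <- bd$species == "DPPC" & bd$role == "head" & bd$leaflet == "upper"
  maxX <- max(coords(fr)[heads, 1])
  # all DPPC sits in the low-x stripe; cells clearly beyond it are empty
  g <- gridValues(gridDensity(fr, "upper", "DPPC", 1.5))
  cellEdge <- boxXY(fr)[1] / nrow(g)
  emptyCols <- which(seq_len(nrow(g)) * cellEdge - cellEdge > maxX + 0.5)
  if (length(emptyCols)) expect_true(all(g[emptyCols, ] == 0))
  expect_lt(maxX, boxXY(fr)[1] * 0.75)
})

test_that("interleaflet correlation hits the exact bounds on constructed fields", {
  v <- matrix(rpois(64, 3), 8, 8)
  mk <- function(values) new("GridField", values = values,
                             cellSize = c(1.5, 1.5), box = c(12, 12),
                             label = "test")
  expect_equal(interleafletCorrelation(mk(v), mk(v)), 1)
  anti <- 2 * mean(v) - v   # reflection about the mean
  expect_equal(interleafletCorrelation(mk(v), mk(anti)), -1)
  flat <- mk(matrix(2, 8, 8))
  r <- interleafletCorrelation(mk(v), flat)
  expect_true(is.na(r))
  expect_true(isTRUE(attr(r, "constantField")))
  expect_error(interleafletCorrelation(mk(v),
               new("GridField", values = matrix(0, 4, 4),
                   cellSize = c(3, 3), box = c(12, 12), label = "x")),
               "mismatch")
  # independent random fields decorrelate
  set.seed(99)
  rs <- replicate(50, {
    a <- matrix(rpois(169, 4), 13, 13)
    b <- matrix(rpois(169, 4), 13, 13)
    abs(interleafletCorrelation(
      new("GridField", values = a, cellSize = c(1.5, 1.5),
          box = c(19.5, 19.5), label = "a"),
      new("GridField", values = b, cellSize = c(1.5, 1.5),
          box = c(19.5, 19.5), label = "b")))
  })
  expect_lt(median(rs), 3 / sqrt(169))
})

test_that("the bilayer-center map recovers flat and tilted midplanes", {
  fr <- buildBilayer(tinyComp(), phaseLayout("mixed"),
                     orderTargets(S = c(DPPC = 0.9, DUPC = 0.9, CHOL = 0.9),
                                  interdigitationGap = 0.4), seed = 4)
  cm <- bilayerCenterMap(fr)
  expect_true(all(abs(gridValues(cm)) < 0.25))
  # impose a linear tilt on the whole frame and recover it per cell
  tilt <- 0.05
  sh <- fr
  sh@coords[, 3] <- sh@coords[, 3] + tilt * sh@coords[, 1]
  sh@unwrapped[, 3] <- sh@unwrapped[, 3] + tilt * sh@unwrapped[, 1]
  cm2 <- bilayerCenterMap(sh)
  v <- gridValues(cm2)
  centers <- (seq_len(nrow(v)) - 0.5) * cellSize(cm2)[1]
  expected <- tilt * centers
  expect_equal(rowMeans(v), expected, tolerance = 0.12)
})

test_that("excluded species do not bias the center map", {
  base <- buildBilayer(tinyComp(30, 40, 0, box = 10), phaseLayout("mixed"),
                       seed = 5)
  # append upper-leaflet-only mimic molecules whose short tails sit well
  # above the midplane (their one-sided contribution would bias the map)
  mim <- buildBilayer(compositionSpec(c(DPPC_3b = 20), boxXY = 10),
                      phaseLayout("mixed"),
                      orderTargets(S = c(DPPC_3b = 0.9),
                                   interdigitationGap = 0.4), seed = 6)
  keepUp <- beadData(mim)$leaflet == "upper"
  bdM <- beadData(mim)[keepUp, ]
  bdM$molecule <- bdM$molecule + max(beadData(base)$molecule)
  rownames(bdM) <- NULL
  joint <- new("CGFrame",
               coords = rbind(coords(base), coords(mim)[keepUp, ]),
               unwrapped = rbind(unwrappedCoords(base),
                                 unwrappedCoords(mim)[keepUp, ]),
               box = boxXY(base), time = 0,
               beadData = rbind(beadData(base), bdM))
  cmBase <- bilayerCenterMap(base, exclude = "DPPC_3b")
  cmJoint <- bilayerCenterMap(joint, exclude = "DPPC_3b")
  expect_equal(gridValues(cmJoint), gridValues(cmBase))
  # without the exclusion the mimic's short tails shift the centers
  cmBiased <- bilayerCenterMap(joint, exclude = character())
  expect_false(isTRUE(all.equal(gridValues(cmBiased), gridValues(cmBase))))
})

test_that("z profiles report construction heights and ignore global shifts", {
  ot <- orderTargets(S = c(DPPC = 0.9, DUPC = 0.9, CHOL = 0.9),
                     interdigitationGap = 0.4)
  fr <- buildBilayer(tinyComp(), phaseLayout("mixed"), ot, seed = 7)
  zp <- zProfile(fr)
  expect_equal(zp$tailZ[zp$species == "DPPC"], 0.2, tolerance = 0.1)
  expect_false(zp$interdigitated[zp$species == "DPPC"])
  sh <- fr
  sh@coords[, 3] <- sh@coords[, 3] + 4.2
  sh@unwrapped[, 3] <- sh@unwrapped[, 3] + 4.2
  zp2 <- zProfile(sh)
  expect_equal(zp2$tailZ, zp$tailZ, tolerance = 1e-9)
  # interdigitated construction flags negative tail heights
  oti <- orderTargets(S = c(DPPC = 0.9, DUPC = 0.9, CHOL = 0.9),
                      interdigitationGap = -0.2)
  fri <- buildBilayer(tinyComp(), phaseLayout("mixed"), oti, seed = 8)
  zpi <- zProfile(fri)
  expect_true(zpi$interdigitated[zpi$species == "DPPC"])
})

test_that("interdigitation reports the constructed signed gap", {
  ot <- orderTargets(S = c(DPPC = 0.9, DUPC = 0.9, CHOL = 0.9),
                     interdigitationGap = 0.4)
  fr <- buildBilayer(tinyComp(), phaseLayout("mixed"), ot, seed = 9)
  gap <- interdigitation(fr, "DPPC")
  expect_equal(as.numeric(gap), 0.4, tolerance = 1e-9)
  expect_equal(attr(gap, "sigma"), 0.47)
  # mirror symmetry: gap equals twice the tail height
  zp <- zProfile(fr)
  expect_equal(as.numeric(gap), 2 * zp$tailZ[zp$species == "DPPC"],
               tolerance = 0.15)
  # asymmetric bilayer: species missing from a leaflet is not applicable
  fra <- buildBilayer(tinyComp(), phaseLayout("mixed"), ot,
                      asymmetric = TRUE, seed = 10)
  na <- interdigitation(fra, "DPPC")
  expect_true(is.na(na))
  expect_true(isTRUE(attr(na, "notApplicable")))
})

test_that("domain detection matches brute-force flood fill with periodic wrap", {
  mk <- function(values) new("GridField", values = values,
                             cellSize = c(1, 1),
                             box = c(nrow(values), ncol(values)),
                             label = "test")
  stripe <- matrix(0, 10, 10); stripe[3:5, ] <- 2
  d <- detectDomains(mk(stripe), 1)
  expect_equal(length(d$sizes), 1)
  expect_equal(d$largestFraction, 1)
  empty <- detectDomains(mk(matrix(0, 6, 6)), 1)
  expect_equal(empty$sizes, integer())
  expect_equal(empty$largestFraction, 0)
  two <- matrix(0, 12, 12)
  two[2:4, 2:4] <- 1; two[8:10, 8:10] <- 1
  expect_equal(length(detectDomains(mk(two), 1)$sizes), 2)
  # wrap-around component crosses the boundary
  wrap <- matrix(0, 8, 8); wrap[c(1, 8), 4] <- 1
  expect_equal(length(detectDomains(mk(wrap), 1)$sizes), 1)
  set.seed(123)
  for (rep_ in 1:10) {
    v <- matrix(rbinom(144, 1, 0.4), 12, 12)
    expect_equal(detectDomains(mk(v), 1)$sizes, floodFillSizes(v, 1))
  }
})
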