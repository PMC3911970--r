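# order parameters on hand-constructed geometries with known P2 values

.lipidRegistry <- function() {
  # minimal single-chain species for geometric fixtures
  beads <- data.frame(index = 1:4, type = "C1",
                      role = c("head", "chain", "chain", "tail"), charge = 0)
  bonds <- data.frame(i = 1:3, j = 2:4, length = 0.47, k = 1250,
                      constraint = FALSE)
  angles <- data.frame(a = 1, b = 2, c = 3, theta0 = 180, k = 25)
  list(TEST = new("MoleculeSpec", name = "TEST", beads = beads,
                  bonds = bonds, angles = angles, chains = list(2:4)))
}

.chainFixture <- function(dirList) {
  rows <- chainMoleculeRows(1, "TEST", c(5, 5, 2), dirList)
  rows$role <- c("head", "chain", "chain", "tail")[seq_len(nrow(rows))]
  toyFrame(rows)
}

test_that("analytic bond geometries give the exact P2 values", {
  reg <- .lipidRegistry()
  ez <- c(0, 0, 1); ex <- c(1, 0, 0)
  # head->bead2 bond is a linker bond and must be excluded; chain bonds
  # are 2->3 and 3->4
  up <- .chainFixture(list(ez, ez, ez))
  expect_equal(orderParameter(up, "TEST", registry = reg)$S, 1.0)
  flat <- .chainFixture(list(ez, ex, ex))
  expect_equal(orderParameter(flat, "TEST", registry = reg)$S, -0.5)
  half <- .chainFixture(list(ez, ez, ex))   # chain bonds: cos^2 = {1, 0}
  expect_equal(orderParameter(half, "TEST", registry = reg)$S, 0.25)
})

test_that("the sterol order axis runs through ring beads 3 and 5", {
  chol <- buildStandardSpecies()$CHOL
  place <- function(axis) {
    n <- nrow(beads(chol))
    pos <- t(vapply(seq_len(n), function(k) c(3, 3, 2) + (k - 1) * 0.3 * axis,
                    numeric(3)))
    df <- data.frame(molecule = 1, species = "CHOL",
                     beadIndex = seq_len(n), type = beads(chol)$type,
                     role = beads(chol)$role, charge = 0,
                     leaflet = "upper",
                     x = pos[, 1], y = pos[, 2], z = pos[, 3])
    toyFrame(df)
  }
  expect_equal(orderParameter(place(c(0, 0, -1)), "CHOL")$S, 1.0)
  expect_equal(orderParameter(place(c(1, 0, 0)), "CHOL")$S, -0.5)
})

test_that("species order is the exact mean of per-molecule values within bounds", {
  fr <- buildBilayer(tinyComp(), phaseLayout("separated"), seed = 8)
  for (sp in c("DPPC", "DUPC", "CHOL")) {
    res <- orderParameter(fr, sp)
    expect_true(all(res$perMolecule >= -0.5 & res$perMolecule <= 1))
    expect_identical(res$S, mean(res$perMolecule))
  }
})

test_that("species without chains or rings are rejected", {
  beads <- data.frame(index = 1, type = "Q0", role = "head", charge = 1)
  none <- list(BARE = new("MoleculeSpec", name = "BARE", beads = beads,
                          bonds = data.frame(i = integer(), j = integer(),
                                             length = numeric(), k = numeric(),
                                             constraint = logical()),
                          angles = data.frame(a = integer(), b = integer(),
                                              c = integer(), theta0 = numeric(),
                                              k = numeric()),
                          chains = list()))
  df <- data.frame(molecule = 1, species = "BARE", beadIndex = 1,
                   type = "Q0", role = "head", charge = 1,
                   leaflet = "upper", x = 1, y = 1, z = 1)
  expect_error(orderParameter(toyFrame(df), "BARE", registry = none),
               "chain definition")
})

test_that("leaflet assignment splits by head position and survives translation", {
  fr <- buildBilayer(tinyComp(), phaseLayout("mixed"), seed = 6)
  fr@beadData$leaflet <- NA_character_
  fr2 <- assignLeaflets(fr)
  mt <- moleculeTable(fr2)
  expect_equal(sum(mt$leaflet == "upper"), sum(mt$leaflet == "lower"))
  # invariance under a global z translation
  sh <- fr
  sh@coords[, 3] <- sh@coords[, 3] + 7.3
  sh@unwrapped[, 3] <- sh@unwrapped[, 3] + 7.3
  expect_identical(moleculeTable(assignLeaflets(sh))$leaflet, mt$leaflet)
  # degenerate single-leaflet input is flagged, not an error
  up <- fr
  keep <- beadData(fr)$leaflet == "upper"
  up@coords <- up@coords[keep, ]
  up@unwrapped <- up@unwrapped[keep, ]
  up@beadData <- beadData(fr)[keep, ]
  up@beadData$leaflet <- NA_character_
  res <- assignLeaflets(up)
  expect_true(isTRUE(attr(res, "degenerate")))
})
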