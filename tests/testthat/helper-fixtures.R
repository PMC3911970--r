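# Fixture builders and independent brute-force oracles used across tests.

# a small ternary composition in a box sparse enough that lattice-built
# chains do not clash (>= ~0.8 nm per site)
tinyComp <- function(nD = 20, nU = 30, nC = 10, box = 8) {
  compositionSpec(c(DPPC = nD, DUPC = nU, CHOL = nC), boxXY = box)
}

# assemble a CGFrame directly from a bead table with x/y/z columns;
# molecules/species/roles are taken verbatim
toyFrame <- function(df, box = c(10, 10), time = 0) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  bd <- df[, setdiff(names(df), c("x", "y", "z"))]
  if (is.null(bd$charge)) bd$charge <- 0
  if (is.null(bd$leaflet)) bd$leaflet <- NA_character_
  if (is.null(bd$type)) bd$type <- "C1"
  rownames(bd) <- NULL
  new("CGFrame", coords = xyz, unwrapped = xyz, box = box, time = time,
      beadData = bd)
}

# one straight-chain pseudo-lipid molecule along a given bond direction;
# returns rows for toyFrame. dirList: list of unit 3-vectors, one per bond.
chainMoleculeRows <- function(mol, species, origin, dirList, bondLen = 0.47) {
  n <- length(dirList) + 1L
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- origin
  for (k in seq_along(dirList)) {
    pos[k + 1L, ] <- pos[k, ] + bondLen * dirList[[k]]
  }
  data.frame(molecule = mol, species = species, beadIndex = seq_len(n),
             type = "C1",
             role = c(rep("chain", n - 1L), "tail"),
             charge = 0, leaflet = NA_character_,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

# O(N^2) pair-energy oracle: full distance matrix, no neighbor search
bruteForceEnergy <- function(frame, nb, cutoff = 1.2, rShift = 0.9,
                             epsR = 15) {
  bd <- beadData(frame)
  xyz <- coords(frame)
  n <- nrow(xyz)
  box <- boxXY(frame)
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  sameMol <- outer(bd$molecule, bd$molecule, "==")
  use <- upper.tri(r) & !sameMol & r <= cutoff
  idx <- which(use, arr.ind = TRUE)
  r <- r[use]
  eps <- vdwEpsilon(nb, bd$type[idx[, 1]], bd$type[idx[, 2]])
  vdw <- shiftedLJ(r, eps, vdwSigma(nb), rShift, cutoff)
  q <- bd$charge[idx[, 1]] * bd$charge[idx[, 2]]
  elec <- ifelse(q != 0, shiftedCoulomb(r, bd$charge[idx[, 1]],
                                        bd$charge[idx[, 2]], epsR, cutoff), 0)
  spA <- bd$species[idx[, 1]]
  spB <- bd$species[idx[, 2]]
  key <- paste(pmin(spA, spB), pmax(spA, spB), sep = "|")
  molTab <- moleculeTable(frame)
  nOf <- table(molTab$species)
  agg <- tapply(vdw + elec, key, sum)
  out <- data.frame(key = names(agg), raw = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$speciesA <- sub("\\|.*$", "", out$key)
  out$total <- out$raw / as.numeric(nOf[out$speciesA])
  out
}

# exhaustive per-sterol umbrella oracle with explicit geometry loops
umbrellaOracle <- function(frame, sideOne = 0.25, sideTwo = 0.47) {
  bd <- beadData(frame)
  xyz <- coords(frame)
  box <- boxXY(frame)
  reg <- allSpecies()
  sterols <- names(reg)[vapply(reg, function(m) any(beads(m)$role == "ring"),
                               TRUE)]
  sIdx <- which(bd$species %in% sterols & bd$beadIndex == 1L)
  lIdx <- which(!(bd$species %in% sterols) & bd$role == "head" &
                !duplicated(bd$molecule))
  covered <- logical(length(sIdx))
  for (s in seq_along(sIdx)) {
    i <- sIdx[s]
    nOne <- 0L; nTwo <- 0L
    for (j in lIdx) {
      if (bd$leaflet[j] != bd$leaflet[i]) next
      ddx <- xyz[j, 1] - xyz[i, 1]
      ddx <- abs(ddx - box[1] * round(ddx / box[1]))
      ddy <- xyz[j, 2] - xyz[i, 2]
      ddy <- abs(ddy - box[2] * round(ddy / box[2]))
      above <- if (bd$leaflet[i] == "upper") xyz[j, 3] > xyz[i, 3]
               else xyz[j, 3] < xyz[i, 3]
      if (!above) next
      if (ddx <= sideOne / 2 && ddy <= sideOne / 2) nOne <- nOne + 1L
      if (ddx <= sideTwo / 2 && ddy <= sideTwo / 2) nTwo <- nTwo + 1L
    }
    covered[s] <- nOne >= 1L || nTwo >= 2L
  }
  mean(covered)
}

# plain flood-fill connected components on a periodic lattice
floodFillSizes <- function(values, threshold = 1) {
  occ <- values >= threshold
  nx <- nrow(values); ny <- ncol(values)
  seen <- matrix(FALSE, nx, ny)
  sizes <- integer()
  for (i0 in seq_len(nx)) for (j0 in seq_len(ny)) {
    if (!occ[i0, j0] || seen[i0, j0]) next
    queue <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- ((p[1] - 1L + d[1]) %% nx) + 1L
        jj <- ((p[2] - 1L + d[2]) %% ny) + 1L
        if (occ[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# shifted-potential oracle: determine the force-shift polynomial
# coefficients numerically from the smoothness conditions at the cutoff
# (F(rc) = 0, F'(rc) = 0) and integrate the force to get the potential
shiftedKernelOracle <- function(r, alpha, r1, rc) {
  # force kernel: f(s) = alpha/s^(alpha+1) + A (s-r1)^2 + B (s-r1)^3
  # solve [ (rc-r1)^2  (rc-r1)^3 ] [A]   [ -alpha/rc^(alpha+1) ]
  #       [ 2(rc-r1)   3(rc-r1)^2] [B] = [ (alpha+1) alpha/rc^(alpha+2) ]
  M <- rbind(c((rc - r1)^2, (rc - r1)^3),
             c(2 * (rc - r1), 3 * (rc - r1)^2))
  rhs <- c(-alpha / rc^(alpha + 1), (alpha + 1) * alpha / rc^(alpha + 2))
  AB <- solve(M, rhs)
  force <- function(s) {
    out <- alpha / s^(alpha + 1)
    on_ <- s > r1
    out[on_] <- out[on_] + AB[1] * (s[on_] - r1)^2 + AB[2] * (s[on_] - r1)^3
    out
  }
  vapply(r, function(ri) {
    if (ri >= rc) return(0)
    stats::integrate(force, ri, rc, rel.tol = 1e-12)$value
  }, 0)
}

shiftedLJOracle <- function(r, eps, sigma, rShift = 0.9, rCut = 1.2) {
  4 * eps * (sigma^12 * shiftedKernelOracle(r, 12, rShift, rCut) -
             sigma^6 * shiftedKernelOracle(r, 6, rShift, rCut))
}
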