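## Pairwise nonbonded energies with shifted potentials.
##
## Both the van der Waals and the electrostatic terms use the classic
## GROMACS shift function: for a term 1/r^alpha the potential is modified by
## a cubic/quartic polynomial switched on at r_shift so that potential and
## force go smoothly to zero at the cutoff.  Defaults follow the CG
## convention: cutoff 1.2 nm, vdW shift from 0.9 nm, Coulomb shifted from
## 0 with relative permittivity 15.
##
## f_elec = 138.935485 kJ mol^-1 nm e^-2 (Coulomb constant).

.F_ELEC <- 138.935485

## shifted 1/r^alpha kernel: returns phi(r) with phi(rc) = 0
.shiftPhi <- function(r, alpha, r1, rc) {
  ## A, B solve F(rc) = 0 and F'(rc) = 0 for the shifted force
  ## F(r) = alpha/r^(alpha+1) + A (r-r1)^2 + B (r-r1)^3
  A <- -alpha * ((alpha + 4) * rc - (alpha + 1) * r1) /
    (rc^(alpha + 2) * (rc - r1)^2)
  B <- alpha * ((alpha + 3) * rc - (alpha + 1) * r1) /
    (rc^(alpha + 2) * (rc - r1)^3)
  C <- 1 / rc^alpha - (A / 3) * (rc - r1)^3 - (B / 4) * (rc - r1)^4
  out <- 1 / r^alpha - C
  on_ <- r > r1
  out[on_] <- out[on_] - (A / 3) * (r[on_] - r1)^3 - (B / 4) * (r[on_] - r1)^4
  out[r > rc] <- 0
  out
}

#' Shifted Lennard-Jones potential
#'
#' `4 eps (sigma^12 phi12(r) - sigma^6 phi6(r))` with the shift polynomial
#' applied to each inverse-power term from `rShift` to `rCut`; identically
#' zero beyond the cutoff, with continuous value and force.
#'
#' @param r distances, nm.
#' @param eps well depth, kJ/mol.
#' @param sigma nm.
#' @param rShift shift onset, nm.
#' @param rCut cutoff, nm.
#' @return energies, kJ/mol.
#' @export
shiftedLJ <- function(r, eps, sigma, rShift = 0.9, rCut = 1.2) {
  4 * eps * (sigma^12 * .shiftPhi(r, 12, rShift, rCut) -
             sigma^6 * .shiftPhi(r, 6, rShift, rCut))
}

#' Shifted Coulomb potential
#'
#' `f q1 q2 / (eps_r r)` with the shift polynomial applied over the whole
#' range (onset 0), vanishing at the cutoff.
#'
#' @param r distances, nm.
#' @param q1,q2 charges, e.
#' @param epsR relative permittivity.
#' @param rCut cutoff, nm.
#' @return energies, kJ/mol.
#' @export
shiftedCoulomb <- function(r, q1, q2, epsR = 15, rCut = 1.2) {
  (.F_ELEC * q1 * q2 / epsR) * .shiftPhi(r, 1, 0, rCut)
}

## candidate bead pairs within cutoff via a cell list over the periodic
## x/y plane; returns a 2-column matrix of bead row indices (i < j)
.cellPairs <- function(xy, box, cutoff) {
  n <- nrow(xy)
  ncell <- pmax(1L, floor(box / cutoff))
  cw <- box / ncell
  ix <- pmin(floor((xy[, 1] %% box[1]) / cw[1]), ncell[1] - 1L)
  iy <- pmin(floor((xy[, 2] %% box[2]) / cw[2]), ncell[2] - 1L)
  cellId <- ix + ncell[1] * iy
  byCell <- split(seq_len(n), cellId)
  ids <- as.integer(names(byCell))
  out <- vector("list", 0L)
  lookup <- new.env(hash = TRUE)
  for (k in seq_along(byCell)) assign(as.character(ids[k]), k, envir = lookup)
  neighborOffsets <- expand.grid(dx = -1:1, dy = -1:1)
  for (k in seq_along(byCell)) {
    cx <- ids[k] %% ncell[1]
    cy <- ids[k] %/% ncell[1]
    a <- byCell[[k]]
    for (o in seq_len(nrow(neighborOffsets))) {
      nx <- (cx + neighborOffsets$dx[o]) %% ncell[1]
      ny <- (cy + neighborOffsets$dy[o]) %% ncell[2]
      nid <- as.character(nx + ncell[1] * ny)
      k2 <- if (exists(nid, envir = lookup, inherits = FALSE)) {
        get(nid, envir = lookup)
      } else next
      if (k2 < k) next
      b <- byCell[[k2]]
      if (k2 == k) {
        if (length(a) < 2L) next
        pr <- t(utils::combn(a, 2L))
      } else {
        pr <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
      }
      out[[length(out) + 1L]] <- pr
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  unique(do.call(rbind, out))
}

#' Intermolecular pair energies by species pair
#'
#' Sums the shifted Lennard-Jones and shifted Coulomb interactions over all
#' intermolecular bead pairs within the cutoff (minimum image in x/y, open
#' in z), bookkept per unordered species pair and normalised per molecule
#' of the first species of each pair.  A grid (cell-list) neighbor search
#' keeps the cost near-linear; it is exactly equivalent to the brute-force
#' double loop.
#'
#' @param frame a [CGFrame-class].
#' @param nb a [NonbondedMatrix-class].
#' @param cutoff nm.
#' @param rShift vdW shift onset, nm.
#' @param epsR relative permittivity for the Coulomb term.
#' @return list with `pairs` (data.frame: `speciesA`, `speciesB`, `vdw`,
#'   `elec`, `total` in kJ/mol per molecule of `speciesA`) and `perSpecies`
#'   (data.frame: `species`, `total`, kJ/mol per molecule, summed over all
#'   partners).
#' @export
pairEnergy <- function(frame, nb = buildNonbondedMatrix(), cutoff = 1.2,
                       rShift = 0.9, epsR = 15) {
  stopifnot(is(frame, "CGFrame"), is(nb, "NonbondedMatrix"))
  bd <- beadData(frame)
  bad <- setdiff(unique(bd$type), rownames(nb@epsilon))
  if (length(bad)) stop("bead types missing from the nonbonded matrix: ",
                        paste(bad, collapse = ", "))
  xyz <- coords(frame)
  pr <- .cellPairs(xyz[, 1:2, drop = FALSE], frame@box, cutoff)
  if (nrow(pr)) {
    keep <- bd$molecule[pr[, 1]] != bd$molecule[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
  }
  dx <- .minImage(xyz[pr[, 1], 1] - xyz[pr[, 2], 1], frame@box[1])
  dy <- .minImage(xyz[pr[, 1], 2] - xyz[pr[, 2], 2], frame@box[2])
  dz <- xyz[pr[, 1], 3] - xyz[pr[, 2], 3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  inCut <- r <= cutoff
  pr <- pr[inCut, , drop = FALSE]
  r <- r[inCut]
  eps <- vdwEpsilon(nb, bd$type[pr[, 1]], bd$type[pr[, 2]])
  vdw <- shiftedLJ(r, eps, vdwSigma(nb), rShift, cutoff)
  q1 <- bd$charge[pr[, 1]]
  q2 <- bd$charge[pr[, 2]]
  elec <- numeric(length(r))
  hasQ <- q1 != 0 & q2 != 0
  if (any(hasQ)) {
    elec[hasQ] <- shiftedCoulomb(r[hasQ], q1[hasQ], q2[hasQ], epsR, cutoff)
  }
  spA <- bd$species[pr[, 1]]
  spB <- bd$species[pr[, 2]]
  ## unordered species pair key
  lo <- pmin(spA, spB); hi <- pmax(spA, spB)
  key <- paste(lo, hi, sep = "|")
  aggV <- tapply(vdw, key, sum)
  aggE <- tapply(elec, key, sum)
  molTab <- moleculeTable(frame)
  nOf <- table(molTab$species)
  pairs <- NULL
  if (length(aggV)) {
    ks <- strsplit(names(aggV), "|", fixed = TRUE)
    pairs <- do.call(rbind, lapply(seq_along(ks), function(i) {
      a <- ks[[i]][1]; b <- ks[[i]][2]
      data.frame(speciesA = a, speciesB = b,
                 vdw = unname(aggV[i]) / nOf[[a]],
                 elec = unname(aggE[i]) / nOf[[a]],
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(pairs)) {
    pairs <- data.frame(speciesA = character(), speciesB = character(),
                        vdw = numeric(), elec = numeric())
  }
  pairs$total <- pairs$vdw + pairs$elec
  ## per-species totals from the unnormalised pair sums (each unordered
  ## pair contributes once to each participating species)
  perSpecies <- do.call(rbind, lapply(names(nOf), function(s) {
    hit <- which(pairs$speciesA == s | pairs$speciesB == s)
    tot <- sum(aggV[hit]) + sum(aggE[hit])
    data.frame(species = s, total = tot / nOf[[s]], stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, perSpecies = perSpecies)
}
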