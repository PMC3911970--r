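## Synthetic bilayer construction.
##
## The generator is phenomenological: it realises the statistical structure
## the observables consume (composition, leaflet asymmetry, stripe/disc
## domain layouts with a cross-leaflet registration target, per-species P2
## chain order, head/tail z placement with tunable interdigitation) without
## any force-field dynamics.  Molecules are placed on a square lattice per
## leaflet; chain bond vectors are drawn at the deterministic polar angle
## that realises the requested order parameter, with uniform azimuth.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Bilayer composition
#'
#' Per-leaflet molecule counts, lateral box size and a temperature label.
#' The default reproduces the reference ternary system: 510 DPPC, 810 DUPC
#' and 238 cholesterol in total (half per leaflet) in a 20 nm box, i.e.
#' mole fractions 0.34:0.51:0.15.
#'
#' @param counts named integer vector of molecules per leaflet.
#' @param boxXY lateral box edge, nm (square box).
#' @param temperature label in K (metadata only; nothing is thermostatted).
#' @return list of class `CompositionSpec`.
#' @export
compositionSpec <- function(counts = c(DPPC = 255, DUPC = 405, CHOL = 119),
                            boxXY = 20, temperature = 295) {
  stopifnot(length(counts) >= 1, !is.null(names(counts)), all(counts >= 0),
            boxXY > 0)
  structure(list(counts = counts, boxXY = boxXY, temperature = temperature),
            class = "CompositionSpec")
}

#' Phase layout
#'
#' @param state `"mixed"`, `"separated"` or `"gel"`.
#' @param registration cross-leaflet registration target in `[-1, 1]`;
#'   1 places the ordered domains of the two leaflets congruently, 0 offsets
#'   them by a quarter box, -1 by half a box (anti-registered).  Ignored for
#'   mixed layouts.
#' @param geometry `"stripe"` (default; minimal interface in a periodic
#'   square) or `"disc"`.
#' @return list of class `PhaseLayout`.
#' @export
phaseLayout <- function(state = c("mixed", "separated", "gel"),
                        registration = 1, geometry = c("stripe", "disc")) {
  state <- match.arg(state)
  geometry <- match.arg(geometry)
  stopifnot(registration >= -1, registration <= 1)
  structure(list(state = state, registration = registration,
                 geometry = geometry), class = "PhaseLayout")
}

#' Order and z-placement targets
#'
#' Target P2 order parameter per species, head-bead height, and the signed
#' tail-tail z separation across leaflets.  A positive gap separates the
#' terminal beads of opposing leaflets; a negative gap interdigitates them.
#' Unless given, per-species tail heights are `gap/2`, except for the
#' shortened `DPPC_3b`, whose tails sit 0.4 nm further from the midplane.
#'
#' @param S named numeric vector of per-species targets in `[-0.5, 1]`.
#' @param headZ named numeric vector, nm above the midplane (defaults:
#'   2.0 for lipids, 1.4 for sterols).
#' @param tailZ optional named numeric vector, nm, overriding `gap/2`.
#' @param interdigitationGap signed tail-tail z separation, nm.
#' @return list of class `OrderTargets`.
#' @export
orderTargets <- function(S = c(DPPC = 0.35, DUPC = 0.25, CHOL = 0.45),
                         headZ = NULL, tailZ = NULL,
                         interdigitationGap = 0.4) {
  stopifnot(!is.null(names(S)), all(S >= -0.5), all(S <= 1))
  structure(list(S = S, headZ = headZ, tailZ = tailZ,
                 gap = interdigitationGap), class = "OrderTargets")
}

#' State-dependent default order targets
#'
#' Convenience defaults for the three canonical states: a mixed fluid state
#' (moderate order, slightly interdigitated tails), a phase-separated Lo/Ld
#' state (ordered saturated/sterol domain, ~0.4 nm tail separation) and a
#' gel state (order near 0.9 for every species, ~0.7 nm tail separation).
#'
#' @param state `"mixed"`, `"separated"` or `"gel"`.
#' @param species character vector of species names to cover.
#' @return an [orderTargets()] object.
#' @export
defaultOrderTargets <- function(state = c("mixed", "separated", "gel"),
                                species = c("DPPC", "DUPC", "CHOL")) {
  state <- match.arg(state)
  base <- switch(state,
    mixed     = c(lipidSat = 0.35, lipidUnsat = 0.25, sterol = 0.45),
    separated = c(lipidSat = 0.61, lipidUnsat = 0.30, sterol = 0.70),
    gel       = c(lipidSat = 0.92, lipidUnsat = 0.90, sterol = 0.92))
  gap <- switch(state, mixed = -0.1, separated = 0.4, gel = 0.7)
  cls <- function(s) {
    if (grepl("^DU", s)) "lipidUnsat"
    else if (grepl("^CHOL", s)) "sterol"
    else "lipidSat"
  }
  S <- vapply(species, function(s) base[[cls(s)]], 0)
  names(S) <- species
  orderTargets(S = S, interdigitationGap = gap)
}

.defaultHeadZ <- function(species) {
  vapply(species, function(s) if (grepl("^CHOL", s)) 1.4 else 2.0, 0)
}

.defaultTailZ <- function(species, gap) {
  z <- rep(gap / 2, length(species))
  names(z) <- species
  z[grepl("^DPPC_3b", species)] <- z[grepl("^DPPC_3b", species)] + 0.4
  z
}

#' Sample chain bond orientations at a target order parameter
#'
#' Draws unit bond vectors whose P2 statistic against the z axis equals
#' `sTarget`: the polar angle is the deterministic solution of
#' `cos^2(theta) = (2 S + 1)/3` and the azimuth is uniform, so the measured
#' order parameter of the returned set matches the target up to rounding.
#'
#' @param sTarget order parameter in `[-0.5, 1]`.
#' @param n number of bond vectors.
#' @param seed optional RNG seed (azimuths only).
#' @return numeric matrix n x 3 of unit vectors with non-negative z.
#' @examples
#' u <- sampleChainOrientation(0.5, 100, seed = 1)
#' mean((3 * u[, 3]^2 - 1) / 2)  # 0.5
#' @export
sampleChainOrientation <- function(sTarget, n = 1L, seed = NULL) {
  if (sTarget < -0.5 || sTarget > 1) {
    stop("sTarget must lie in [-0.5, 1], got ", sTarget)
  }
  .withSeed(seed, {
    cz <- sqrt((2 * sTarget + 1) / 3)
    sz <- sqrt(max(0, 1 - cz^2))
    phi <- stats::runif(n, 0, 2 * pi)
    cbind(sz * cos(phi), sz * sin(phi), rep(cz, n))
  })
}

## place one molecule; returns nbeads x 3 matrix in bead-index order.
## leafletSign +1 = upper, -1 = lower (geometry mirrored in z).
.placeMolecule <- function(mol, x0, y0, leafletSign, S, headZ, tailZ,
                           bondLen = 0.47) {
  b <- beads(mol)
  n <- nrow(b)
  pos <- matrix(NA_real_, n, 3)
  heads <- b$index[b$role == "head"]
  rings <- b$index[b$role == "ring"]
  chains_ <- chains(mol)
  if (length(rings)) {
    ## sterol-like: beads strung along a rigid axis from head to tail
    u <- sampleChainOrientation(S, 1)
    cz <- u[1, 3]
    body <- sort(setdiff(b$index, heads))
    spacing <- (headZ - tailZ) / (max(length(body), 2) * max(cz, 0.3))
    spacing <- min(max(spacing, 0.15), 0.40)
    for (k in seq_along(body)) {
      pos[body[k], ] <- c(x0 + k * spacing * u[1, 1],
                          y0 + k * spacing * u[1, 2],
                          leafletSign * (headZ - k * spacing * cz))
    }
    for (k in seq_along(heads)) {
      pos[heads[k], ] <- c(x0, y0, leafletSign * (headZ + 0.3 * (k - 1)))
    }
    return(pos)
  }
  ## lipid-like: chains built upward from the terminal tail bead.  Bond
  ## azimuths alternate by pi (random phase per chain) so the chain stays
  ## within half a bond length of its lattice site laterally while the
  ## polar angle still realises the order target exactly.
  zTopChain <- tailZ
  for (ch in chains_) {
    nb <- length(ch) - 1L
    cz <- sqrt((2 * S + 1) / 3)
    sz <- sqrt(max(0, 1 - cz^2))
    phi <- stats::runif(1, 0, 2 * pi) + pi * (seq_len(nb) - 1L)
    u <- cbind(sz * cos(phi), sz * sin(phi), rep(cz, nb))
    zTop <- tailZ + nb * bondLen * cz
    zTopChain <- max(zTopChain, zTop)
    p <- c(x0, y0, zTop)
    pos[ch[1], ] <- c(p[1], p[2], leafletSign * p[3])
    for (k in seq_len(nb)) {
      p <- p + c(bondLen * u[k, 1], bondLen * u[k, 2], -bondLen * cz)
      pos[ch[k + 1L], ] <- c(p[1], p[2], leafletSign * p[3])
    }
  }
  for (k in seq_along(heads)) {
    pos[heads[k], ] <- c(x0, y0, leafletSign * (headZ + 0.3 * (k - 1)))
  }
  linkers <- b$index[b$role == "linker"]
  if (length(linkers)) {
    zs <- seq(headZ, zTopChain, length.out = length(linkers) + 2L)
    for (k in seq_along(linkers)) {
      pos[linkers[k], ] <- c(x0, y0, leafletSign * zs[k + 1L])
    }
  }
  pos
}

## assign species to lattice sites for one leaflet.
## Returns character vector along sites (row-major over the lattice),
## plus the ordered-domain mask.  Ordered species = saturated lipid +
## sterols (everything not matching ^DU).
.assignSites <- function(siteXY, counts, layout, box, shift = 0) {
  nMol <- sum(counts)
  species <- names(counts)
  isOrd <- !grepl("^DU", species)
  ordSpecies <- species[isOrd]
  disSpecies <- species[!isOrd]
  lab <- character(nMol)
  if (layout$state == "mixed") {
    lab <- sample(rep(species, counts))
    mask <- rep(FALSE, nMol)
    return(list(species = lab, ordered = mask))
  }
  nOrd <- sum(counts[isOrd])
  x <- (siteXY[, 1] - shift) %% box
  if (layout$geometry == "stripe") {
    score <- x
  } else {
    cy <- box / 2
    score <- sqrt(.minImage(siteXY[, 1] - shift - box / 2, box)^2 +
                  (siteXY[, 2] - cy)^2)
  }
  ordIdx <- order(score)[seq_len(nOrd)]
  mask <- rep(FALSE, nMol)
  mask[ordIdx] <- TRUE
  ## deterministic interleaving of ordered species so that congruent
  ## stripes in the two leaflets carry identical per-cell densities:
  ## every species is spread evenly along the domain by a fractional key
  ordLabels <- character(nOrd)
  ranks <- order(score[ordIdx])
  pool <- rep(ordSpecies, counts[ordSpecies])
  key <- unlist(lapply(ordSpecies, function(s) {
    (seq_len(counts[[s]]) - 0.5) / counts[[s]]
  }))
  pool <- pool[order(key)]
  ordLabels[ranks] <- pool
  lab[ordIdx] <- ordLabels
  disPool <- rep(disSpecies, counts[disSpecies])
  lab[!mask] <- disPool
  list(species = lab, ordered = mask)
}

#' Build a synthetic bilayer frame
#'
#' Places two leaflets of molecules on per-leaflet square lattices in a
#' periodic x/y box about the midplane z = 0.  In separated and gel layouts
#' the saturated lipid and sterols occupy one contiguous domain per leaflet
#' (stripe or disc), with the lower-leaflet domain displaced according to
#' the registration target; with `asymmetric = TRUE` the lower leaflet is
#' replaced by pure DUPC at matched area.  Chain bond vectors realise the
#' per-species order targets exactly (deterministic polar angle); heads and
#' tails sit at the requested z heights.
#'
#' @param comp a [compositionSpec()].
#' @param layout a [phaseLayout()].
#' @param order an [orderTargets()]; defaults to
#'   [defaultOrderTargets()] for the layout state.
#' @param asymmetric replace the lower leaflet by pure DUPC.
#' @param seed RNG seed; the frame is bit-reproducible under a fixed seed.
#' @return a [CGFrame-class] with leaflet labels assigned and an `ordered`
#'   column marking molecules of the ordered domain.
#' @examples
#' fr <- buildBilayer(compositionSpec(c(DPPC = 20, DUPC = 30, CHOL = 10),
#'                                    boxXY = 7),
#'                    phaseLayout("mixed"), seed = 1)
#' @export
buildBilayer <- function(comp, layout = phaseLayout("mixed"),
                         order = defaultOrderTargets(layout$state,
                                                     names(comp$counts)),
                         asymmetric = FALSE, seed = NULL) {
  stopifnot(inherits(comp, "CompositionSpec"), inherits(layout, "PhaseLayout"),
            inherits(order, "OrderTargets"))
  registry <- allSpecies()
  unknown <- setdiff(names(comp$counts), names(registry))
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  box <- rep(comp$boxXY, 2)
  aplLipid <- 0.64
  aplSterol <- 0.32
  isSterol <- grepl("^CHOL|^DPPC_3b", names(comp$counts))
  areaNeeded <- sum(comp$counts[!isSterol]) * aplLipid +
    sum(comp$counts[isSterol]) * aplSterol
  .withSeed(seed, {
    leafletCounts <- list(upper = comp$counts, lower = comp$counts)
    if (asymmetric) {
      nLower <- round(areaNeeded / aplLipid)
      leafletCounts$lower <- c(DUPC = nLower)
    }
    allPos <- list(); allBd <- list()
    molId <- 0L
    for (leaf in c("upper", "lower")) {
      counts <- leafletCounts[[leaf]]
      counts <- counts[counts > 0]
      nMol <- sum(counts)
      side <- ceiling(sqrt(nMol))
      spacing <- comp$boxXY / side
      if (spacing^2 < aplSterol) {
        stop("overfull box: ", nMol, " molecules in a ", comp$boxXY,
             " nm box leaves ", signif(spacing^2, 3), " nm^2 per molecule")
      }
      sites <- expand.grid(ix = seq_len(side) - 1L, iy = seq_len(side) - 1L)
      sites <- as.matrix(sites[seq_len(nMol), , drop = FALSE]) * spacing +
        spacing / 2
      sign_ <- if (leaf == "upper") 1 else -1
      shift <- if (leaf == "lower" && layout$state != "mixed") {
        (1 - layout$registration) * comp$boxXY / 4
      } else 0
      asg <- .assignSites(sites, counts, layout, comp$boxXY, shift = shift)
      headZ <- order$headZ
      if (is.null(headZ)) headZ <- .defaultHeadZ(unique(asg$species))
      tailZ <- order$tailZ
      if (is.null(tailZ)) tailZ <- .defaultTailZ(unique(asg$species), order$gap)
      Svec <- order$S
      for (m in seq_len(nMol)) {
        sp <- asg$species[m]
        mol <- registry[[sp]]
        s_ <- if (sp %in% names(Svec)) Svec[[sp]] else 0.3
        hz <- if (sp %in% names(headZ)) headZ[[sp]] else 2.0
        tz <- if (sp %in% names(tailZ)) tailZ[[sp]] else order$gap / 2
        jx <- stats::runif(1, -0.02, 0.02) * spacing
        jy <- stats::runif(1, -0.02, 0.02) * spacing
        pos <- .placeMolecule(mol, sites[m, 1] + jx, sites[m, 2] + jy,
                              sign_, s_, hz, tz)
        molId <- molId + 1L
        b <- beads(mol)
        allPos[[length(allPos) + 1L]] <- pos
        allBd[[length(allBd) + 1L]] <- data.frame(
          molecule = molId, species = sp, beadIndex = b$index,
          type = b$type, role = b$role, charge = b$charge,
          leaflet = leaf, ordered = asg$ordered[m],
          stringsAsFactors = FALSE)
      }
    }
    un <- do.call(rbind, allPos)
    bd <- do.call(rbind, allBd)
    rownames(bd) <- NULL
    new("CGFrame", coords = .wrapXY(un, box), unwrapped = un,
        box = box, time = 0, beadData = bd)
  })
}
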