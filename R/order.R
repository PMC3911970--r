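## Leaflet assignment and P2 chain order parameters.

#' Assign molecules to leaflets
#'
#' Labels every molecule `"upper"` or `"lower"` by the sign of its head-bead
#' z coordinate relative to the global midplane, the mean z of all tail
#' beads.  Labels are invariant under a global translation of the frame.
#' A degenerate single-leaflet input is labelled and flagged (attribute
#' `degenerate`) rather than rejected.
#'
#' @param frame a [CGFrame-class].
#' @return the frame with `beadData$leaflet` filled; the per-molecule labels
#'   are available via [moleculeTable()].
#' @export
assignLeaflets <- function(frame) {
  stopifnot(is(frame, "CGFrame"))
  bd <- beadData(frame)
  z <- unwrappedCoords(frame)[, 3]
  mid <- mean(z[bd$role == "tail"])
  headRows <- which(bd$role == "head")
  ## one head z per molecule (first head bead)
  hr <- headRows[!duplicated(bd$molecule[headRows])]
  lab <- ifelse(z[hr] - mid >= 0, "upper", "lower")
  names(lab) <- bd$molecule[hr]
  bd$leaflet <- unname(lab[as.character(bd$molecule)])
  frame@beadData <- bd
  if (length(unique(lab)) < 2L) {
    attr(frame, "degenerate") <- TRUE
  }
  frame
}

## bond vectors between consecutive chain beads of one molecule, using
## unwrapped coordinates with an x/y minimum-image fallback so that frames
## read back from wrapped files still yield intact bonds
.chainBondVectors <- function(xyz, rows, box) {
  d <- xyz[rows[-1], , drop = FALSE] - xyz[rows[-length(rows)], , drop = FALSE]
  d[, 1] <- .minImage(d[, 1], box[1])
  d[, 2] <- .minImage(d[, 2], box[2])
  d
}

#' Chain order parameter of a species
#'
#' Per bond, `S = (3 <cos^2 theta_z> - 1) / 2` with `theta_z` the angle
#' between the bond and the bilayer normal (z).  A lipid's order parameter
#' is the mean over the bonds between consecutive chain beads of both its
#' chains (glycerol-linker bonds excluded); for sterols the single vector
#' through ring beads 3 and 5 is used.  Values lie in `[-0.5, 1]` and the
#' species value is the exact mean of the retained per-molecule values.
#'
#' @param frame a [CGFrame-class].
#' @param species species name present in the frame.
#' @param registry named list of [MoleculeSpec-class]; default [allSpecies()].
#' @param leaflet optionally restrict to `"upper"` or `"lower"`.
#' @return list with `S` (species mean), `perMolecule` (named numeric), and
#'   `species`.
#' @examples
#' fr <- buildBilayer(compositionSpec(c(DPPC = 9, DUPC = 9, CHOL = 7),
#'                                    boxXY = 5),
#'                    phaseLayout("mixed"),
#'                    orderTargets(S = c(DPPC = 1, DUPC = 1, CHOL = 1)),
#'                    seed = 1)
#' orderParameter(fr, "DPPC")$S  # 1
#' @export
orderParameter <- function(frame, species, registry = NULL, leaflet = NULL) {
  stopifnot(is(frame, "CGFrame"))
  reg <- .registryFor(frame, registry)
  if (!species %in% names(reg)) stop("species not present: ", species)
  mol <- reg[[species]]
  sterol <- any(beads(mol)$role == "ring")
  ch <- chains(mol)
  if (!sterol && !length(ch)) {
    stop("species ", species, " has no chain definition and is not a sterol")
  }
  bd <- beadData(frame)
  xyz <- unwrappedCoords(frame)
  keep <- bd$species == species
  if (!is.null(leaflet)) keep <- keep & bd$leaflet == leaflet
  mols <- unique(bd$molecule[keep])
  perMol <- vapply(mols, function(m) {
    rows <- which(bd$molecule == m)
    idx <- bd$beadIndex[rows]
    if (sterol) {
      a <- rows[match(3L, idx)]
      b <- rows[match(5L, idx)]
      d <- xyz[b, ] - xyz[a, ]
      d[1] <- .minImage(d[1], frame@box[1])
      d[2] <- .minImage(d[2], frame@box[2])
      c2 <- (d[3]^2) / sum(d^2)
      (3 * c2 - 1) / 2
    } else {
      sb <- unlist(lapply(ch, function(chain) {
        r <- rows[match(chain, idx)]
        d <- .chainBondVectors(xyz, r, frame@box)
        c2 <- d[, 3]^2 / rowSums(d^2)
        (3 * c2 - 1) / 2
      }))
      mean(sb)
    }
  }, 0)
  perMol <- pmin(pmax(perMol, -0.5), 1)
  names(perMol) <- mols
  list(species = species, S = mean(perMol), perMolecule = perMol)
}
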