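## Umbrella-model headgroup coverage.
##
## A sterol head (bead 1) counts as covered when at least one lipid head
## bead lies above it (larger |z| toward the water phase of its leaflet)
## within an axis-aligned square of side 0.25 nm centered on the sterol
## head's x/y, or when at least two lipid heads lie within the 0.47 nm
## square.  Lateral distances are minimum-image under the periodic box.

#' Umbrella coverage of sterol heads
#'
#' @param frame a [CGFrame-class] with leaflets assigned.
#' @param sterolSpecies character vector of sterol-like species to assess;
#'   defaults to every species in the frame that has ring beads.
#' @param sideOne side of the one-lipid square, nm.
#' @param sideTwo side of the two-lipid square, nm.
#' @return list with `fraction` (covered sterols over all sterols),
#'   `perSterol` (data.frame: `molecule`, `coveredOne`, `coveredTwo`,
#'   `covered`).
#' @export
umbrellaCoverage <- function(frame, sterolSpecies = NULL,
                             sideOne = 0.25, sideTwo = 0.47) {
  stopifnot(is(frame, "CGFrame"))
  bd <- beadData(frame)
  if (all(is.na(bd$leaflet))) stop("assign leaflets first (assignLeaflets)")
  reg <- .registryFor(frame)
  if (is.null(sterolSpecies)) {
    sterolSpecies <- names(reg)[vapply(reg, function(m) {
      any(beads(m)$role == "ring")
    }, TRUE)]
  }
  if (!length(sterolSpecies) ||
      !any(bd$species %in% sterolSpecies)) {
    stop("no sterol-like species present in the frame")
  }
  xyz <- coords(frame)
  ## sterol heads: bead 1 of each sterol molecule
  selS <- bd$species %in% sterolSpecies & bd$beadIndex == 1L
  ## lipid heads: head-role beads of non-sterol molecules, one per molecule
  selL <- !(bd$species %in% sterolSpecies) & bd$role == "head" &
    !duplicated(bd$molecule)
  sIdx <- which(selS)
  lIdx <- which(selL)
  box <- frame@box
  res <- data.frame(molecule = bd$molecule[sIdx],
                    coveredOne = FALSE, coveredTwo = FALSE)
  if (length(lIdx)) {
    for (r in seq_along(sIdx)) {
      i <- sIdx[r]
      dx <- abs(.minImage(xyz[lIdx, 1] - xyz[i, 1], box[1]))
      dy <- abs(.minImage(xyz[lIdx, 2] - xyz[i, 2], box[2]))
      up <- if (bd$leaflet[i] == "upper") {
        xyz[lIdx, 3] > xyz[i, 3]
      } else {
        xyz[lIdx, 3] < xyz[i, 3]
      }
      sameLeaflet <- bd$leaflet[lIdx] == bd$leaflet[i]
      nOne <- sum(up & sameLeaflet & dx <= sideOne / 2 & dy <= sideOne / 2)
      nTwo <- sum(up & sameLeaflet & dx <= sideTwo / 2 & dy <= sideTwo / 2)
      res$coveredOne[r] <- nOne >= 1L
      res$coveredTwo[r] <- nTwo >= 2L
    }
  }
  res$covered <- res$coveredOne | res$coveredTwo
  list(fraction = mean(res$covered), perSterol = res)
}
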