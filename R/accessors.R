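#' Accessors for cgraft S4 objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x a cgraft object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))
#' @rdname accessors
#' @export
setMethod("speciesName", "MoleculeSpec", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))
#' @rdname accessors
#' @export
setMethod("beads", "MoleculeSpec", function(x) x@beads)

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setMethod("bonds", "MoleculeSpec", function(x) x@bonds)

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setMethod("angles", "MoleculeSpec", function(x) x@angles)

#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))
#' @rdname accessors
#' @export
setMethod("chains", "MoleculeSpec", function(x) x@chains)

#' Look up one angle term by its bead-index triple
#'
#' @param mol a [MoleculeSpec-class].
#' @param a,b,c bead indices of the angle (order-insensitive: the reversed
#'   triple matches the same term).
#' @return one-row data.frame with `theta0` (degrees) and `k` (kJ/mol).
#' @export
angleTerm <- function(mol, a, b, c) {
  an <- angles(mol)
  hit <- (an$a == a & an$b == b & an$c == c) |
         (an$a == c & an$b == b & an$c == a)
  if (!any(hit)) {
    stop("no angle term over beads ", a, "-", b, "-", c, " in ", speciesName(mol))
  }
  an[hit, , drop = FALSE]
}

#' @rdname accessors
#' @export
setGeneric("beadData", function(x) standardGeneric("beadData"))
#' @rdname accessors
#' @export
setMethod("beadData", "CGFrame", function(x) x@beadData)
#' @rdname accessors
#' @export
setMethod("beadData", "CGTrajectory", function(x) x@beadData)

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "CGFrame", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("unwrappedCoords", function(x) standardGeneric("unwrappedCoords"))
#' @rdname accessors
#' @export
setMethod("unwrappedCoords", "CGFrame", function(x) x@unwrapped)
#' @rdname accessors
#' @export
setMethod("unwrappedCoords", "CGTrajectory", function(x) x@unwrapped)

#' @rdname accessors
#' @export
setGeneric("boxXY", function(x) standardGeneric("boxXY"))
#' @rdname accessors
#' @export
setMethod("boxXY", "CGFrame", function(x) x@box)
#' @rdname accessors
#' @export
setMethod("boxXY", "CGTrajectory", function(x) x@box)
#' @rdname accessors
#' @export
setMethod("boxXY", "GridField", function(x) x@box)

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "CGTrajectory", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("frameTimes", "CGFrame", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "CGTrajectory", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setMethod("gridValues", "GridField", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setMethod("cellSize", "GridField", function(x) x@cellSize)

#' Extract one frame of a trajectory
#'
#' @param traj a [CGTrajectory-class].
#' @param i frame number.
#' @return a [CGFrame-class].
#' @export
getFrame <- function(traj, i) {
  stopifnot(is(traj, "CGTrajectory"))
  n <- nFrames(traj)
  if (i < 1L || i > n) stop("frame index out of range 1..", n)
  new("CGFrame",
      coords    = traj@coords[, , i, drop = TRUE],
      unwrapped = traj@unwrapped[, , i, drop = TRUE],
      box       = traj@box,
      time      = traj@times[i],
      beadData  = traj@beadData)
}

#' Per-molecule summary table of a frame
#'
#' One row per molecule: id, species and leaflet label.
#'
#' @param frame a [CGFrame-class] or [CGTrajectory-class].
#' @return data.frame with columns `molecule`, `species`, `leaflet`.
#' @export
moleculeTable <- function(frame) {
  bd <- beadData(frame)
  first <- !duplicated(bd$molecule)
  data.frame(molecule = bd$molecule[first],
             species  = bd$species[first],
             leaflet  = bd$leaflet[first],
             stringsAsFactors = FALSE)
}
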