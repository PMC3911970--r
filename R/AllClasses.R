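#' @import methods
NULL

#' Coarse-grained molecule specification
#'
#' A `MoleculeSpec` describes one CG molecule: its ordered beads (index,
#' MARTINI bead type, structural role, partial charge), bonded terms (bonds
#' and angles), and the covalent ordering of its acyl chains.  Bead roles are
#' one of `head`, `linker`, `chain`, `ring`, `tail`; exactly the beads with
#' role `tail` enter bilayer-center and interdigitation calculations.
#'
#' @slot name single character token, e.g. `"DPPC"`, `"DUas"`.
#' @slot beads data.frame with columns `index` (1-based integer), `type`
#'   (bead-type token), `role`, `charge` (elementary charges).
#' @slot bonds data.frame with columns `i`, `j` (bead indices), `length`
#'   (nm), `k` (kJ/mol/nm^2; `NA` for constrained bonds), `constraint`
#'   (logical).
#' @slot angles data.frame with columns `a`, `b`, `c` (bead indices),
#'   `theta0` (degrees), `k` (kJ/mol).
#' @slot chains list of integer vectors, the consecutive chain/tail beads of
#'   each acyl chain in covalent order (first entry closest to the glycerol
#'   linker).
#' @exportClass MoleculeSpec
setClass("MoleculeSpec",
  representation(
    name   = "character",
    beads  = "data.frame",
    bonds  = "data.frame",
    angles = "data.frame",
    chains = "list"
  )
)

.validMoleculeSpec <- function(object) {
  msg <- character()
  b <- object@beads
  need <- c("index", "type", "role", "charge")
  if (!all(need %in% names(b))) {
    return(paste("beads must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(b$index)) msg <- c(msg, "bead indices must be unique")
  ok_roles <- c("head", "linker", "chain", "ring", "tail")
  if (!all(b$role %in% ok_roles)) {
    msg <- c(msg, paste("bead roles must be in", paste(ok_roles, collapse = "/")))
  }
  idx <- b$index
  bd <- object@bonds
  if (nrow(bd) && !all(c(bd$i, bd$j) %in% idx)) {
    msg <- c(msg, "bond indices must resolve to beads")
  }
  an <- object@angles
  if (nrow(an) && !all(c(an$a, an$b, an$c) %in% idx)) {
    msg <- c(msg, "angle indices must resolve to beads")
  }
  if (nrow(an) && (any(an$theta0 <= 0) || any(an$theta0 > 180))) {
    msg <- c(msg, "theta0 must lie in (0, 180] degrees")
  }
  if (nrow(an) && any(an$k <= 0)) msg <- c(msg, "angle force constants must be > 0")
  for (ch in object@chains) {
    if (!all(ch %in% idx)) {
      msg <- c(msg, "chain indices must resolve to beads")
      next
    }
    roles <- b$role[match(ch, b$index)]
    if (!all(roles %in% c("chain", "tail"))) {
      msg <- c(msg, "chains may contain only chain/tail-role beads")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("MoleculeSpec", .validMoleculeSpec)

setMethod("show", "MoleculeSpec", function(object) {
  cat("MoleculeSpec", object@name, "\n")
  cat(" ", nrow(object@beads), "beads (",
      paste(object@beads$type, collapse = " "), ")\n")
  cat(" ", nrow(object@bonds), "bonds,", nrow(object@angles), "angles,",
      length(object@chains), "chains\n")
  invisible(NULL)
})

#' Nonbonded van der Waals interaction matrix
#'
#' Symmetric lookup of Lennard-Jones well depths over registered bead types,
#' with a single sigma for the bead family.  Ring (`SCx`) types interact
#' among themselves at 0.75 times the strength of the corresponding `Cx-Cy`
#' pair; a ring type against a regular type keeps the full parent strength.
#'
#' @slot epsilon symmetric numeric matrix (kJ/mol) with bead-type dimnames.
#' @slot sigma single numeric, nm.
#' @exportClass NonbondedMatrix
setClass("NonbondedMatrix",
  representation(epsilon = "matrix", sigma = "numeric")
)

setValidity("NonbondedMatrix", function(object) {
  e <- object@epsilon
  msg <- character()
  if (is.null(dimnames(e)) || !identical(rownames(e), colnames(e))) {
    msg <- c(msg, "epsilon must have matching row/col type names")
  }
  if (!isTRUE(all.equal(e, t(e)))) msg <- c(msg, "epsilon must be symmetric")
  if (length(object@sigma) != 1L || object@sigma <= 0) {
    msg <- c(msg, "sigma must be a single positive value")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "NonbondedMatrix", function(object) {
  cat("NonbondedMatrix over", nrow(object@epsilon), "bead types, sigma =",
      object@sigma, "nm\n")
  invisible(NULL)
})

#' Single bilayer frame
#'
#' Per-bead coordinates of one configuration.  `coords` are wrapped into the
#' periodic x/y box; `unwrapped` carry the continuous trajectory (equal to
#' `coords` for a freshly built frame).  z is unbounded; the bilayer midplane
#' is near z = 0 by construction.
#'
#' @slot coords numeric matrix n x 3 (nm), wrapped in x/y.
#' @slot unwrapped numeric matrix n x 3 (nm).
#' @slot box numeric length-2, x/y box lengths (nm).
#' @slot time single numeric, ns.
#' @slot beadData data.frame with one row per bead: `molecule` (integer id),
#'   `species`, `beadIndex`, `type`, `role`, `charge`, `leaflet` (`"upper"`,
#'   `"lower"` or `NA` before assignment).
#' @exportClass CGFrame
setClass("CGFrame",
  representation(
    coords    = "matrix",
    unwrapped = "matrix",
    box       = "numeric",
    time      = "numeric",
    beadData  = "data.frame"
  )
)

setValidity("CGFrame", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (!identical(dim(object@coords), dim(object@unwrapped))) {
    msg <- c(msg, "unwrapped must match coords dimensions")
  }
  if (length(object@box) != 2L || any(object@box <= 0)) {
    msg <- c(msg, "box must be two positive lengths")
  }
  if (nrow(object@beadData) != n) msg <- c(msg, "beadData must have one row per bead")
  need <- c("molecule", "species", "beadIndex", "type", "role", "charge", "leaflet")
  if (!all(need %in% names(object@beadData))) {
    msg <- c(msg, paste("beadData needs columns", paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CGFrame", function(object) {
  bd <- object@beadData
  cat("CGFrame:", nrow(bd), "beads,", length(unique(bd$molecule)),
      "molecules, box", paste(signif(object@box, 4), collapse = " x "),
      "nm, t =", object@time, "ns\n")
  print(table(bd$species[!duplicated(bd$molecule)]))
  invisible(NULL)
})

#' Multi-frame bilayer trajectory
#'
#' Dense per-bead trajectory with wrapped and unwrapped coordinates.  Bead
#' metadata are stored once (molecule identity never changes along a
#' trajectory).
#'
#' @slot coords numeric array n_beads x 3 x n_frames, wrapped (nm).
#' @slot unwrapped numeric array of the same shape (nm).
#' @slot times numeric vector, ns, one per frame.
#' @slot box numeric length-2 (nm).
#' @slot beadData data.frame as in [CGFrame-class].
#' @exportClass CGTrajectory
setClass("CGTrajectory",
  representation(
    coords    = "array",
    unwrapped = "array",
    times     = "numeric",
    box       = "numeric",
    beadData  = "data.frame"
  )
)

setValidity("CGTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) msg <- c(msg, "coords must be n x 3 x frames")
  if (!identical(dim(object@unwrapped), d)) {
    msg <- c(msg, "unwrapped must match coords shape")
  }
  if (length(object@times) != d[3]) msg <- c(msg, "one time per frame required")
  if (is.unsorted(object@times, strictly = TRUE)) {
    msg <- c(msg, "times must be strictly increasing")
  }
  if (nrow(object@beadData) != d[1]) msg <- c(msg, "beadData must have one row per bead")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CGTrajectory", function(object) {
  d <- dim(object@coords)
  cat("CGTrajectory:", d[1], "beads x", d[3], "frames, t =",
      min(object@times), "-", max(object@times), "ns\n")
  invisible(NULL)
})

#' 2D scalar field over the bilayer plane
#'
#' A per-cell scalar quantity (molecule counts, local midplane z, ...) on a
#' regular grid tiling the periodic x/y box.  The requested cell size is
#' rescaled so that an integer number of cells tiles the box exactly.
#'
#' @slot values numeric matrix n_x x n_y.
#' @slot cellSize numeric length-2, the actual (rescaled) cell edge lengths (nm).
#' @slot box numeric length-2 (nm).
#' @slot label single character describing the quantity.
#' @exportClass GridField
setClass("GridField",
  representation(
    values   = "matrix",
    cellSize = "numeric",
    box      = "numeric",
    label    = "character"
  )
)

setValidity("GridField", function(object) {
  msg <- character()
  if (length(object@cellSize) != 2L || any(object@cellSize <= 0)) {
    msg <- c(msg, "cellSize must be two positive lengths")
  }
  if (length(object@box) != 2L) msg <- c(msg, "box must be length 2")
  nx <- nrow(object@values); ny <- ncol(object@values)
  if (nx < 1L || ny < 1L) msg <- c(msg, "grid must be at least 1 x 1")
  if (abs(nx * object@cellSize[1] - object@box[1]) > 1e-6 ||
      abs(ny * object@cellSize[2] - object@box[2]) > 1e-6) {
    msg <- c(msg, "cells must tile the box exactly")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GridField", function(object) {
  cat("GridField", sQuote(object@label), ":", nrow(object@values), "x",
      ncol(object@values), "cells of",
      paste(signif(object@cellSize, 4), collapse = " x "), "nm\n")
  invisible(NULL)
})
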