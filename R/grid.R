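## Grid-based observables: per-leaflet density fields, interleaflet domain
## correlation, local bilayer-center maps, z-profiles relative to the local
## midplane, tail interdigitation and connected-component domain detection.
##
## Grid convention: the number of cells per axis is round(box/cellSize)
## (at least 1) and the actual cell edge is rescaled so the cells tile the
## periodic box exactly; a nominal 1.5 or 3.0 nm cell cannot tile an
## arbitrary box.

.gridShape <- function(box, cellSize) {
  n <- pmax(1L, as.integer(round(box / cellSize)))
  list(n = n, cell = box / n)
}

.cellOf <- function(xy, box, n) {
  ix <- pmin(floor((xy[, 1] %% box[1]) / (box[1] / n[1])), n[1] - 1L)
  iy <- pmin(floor((xy[, 2] %% box[2]) / (box[2] / n[2])), n[2] - 1L)
  cbind(ix + 1L, iy + 1L)
}

#' Per-cell molecule density of a species in one leaflet
#'
#' Counts molecules (by wrapped head-bead position) in square cells tiling
#' the bilayer plane.  The counts over all cells sum exactly to the number
#' of molecules of the species in the leaflet.
#'
#' @param frame a [CGFrame-class] with leaflets assigned.
#' @param leaflet `"upper"` or `"lower"`.
#' @param species species name.
#' @param cellSize nominal cell edge, nm (default 1.5).
#' @return a [GridField-class] of counts.
#' @export
gridDensity <- function(frame, leaflet, species, cellSize = 1.5) {
  stopifnot(is(frame, "CGFrame"))
  if (any(cellSize > frame@box)) {
    stop("cellSize exceeds the box: ", cellSize, " nm")
  }
  bd <- beadData(frame)
  if (all(is.na(bd$leaflet))) stop("assign leaflets first (assignLeaflets)")
  g <- .gridShape(frame@box, cellSize)
  sel <- bd$species == species & bd$leaflet == leaflet & bd$role == "head"
  sel <- sel & !duplicated(bd$molecule)   # one head bead per molecule
  v <- matrix(0, g$n[1], g$n[2])
  if (any(sel)) {
    cells <- .cellOf(coords(frame)[sel, 1:2, drop = FALSE], frame@box, g$n)
    for (r in seq_len(nrow(cells))) {
      v[cells[r, 1], cells[r, 2]] <- v[cells[r, 1], cells[r, 2]] + 1
    }
  }
  new("GridField", values = v, cellSize = g$cell, box = frame@box,
      label = paste0("density:", species, ":", leaflet))
}

#' Interleaflet domain correlation
#'
#' Pearson correlation across corresponding grid cells of two per-leaflet
#' density fields.  Registered domains give values near 1, anti-registered
#' near -1.  If either field is constant the correlation is undefined and
#' `NA` is returned with attribute `constantField = TRUE`.
#'
#' @param fieldTop,fieldBottom [GridField-class] objects on identical grids.
#' @return correlation coefficient in `[-1, 1]`, or flagged `NA`.
#' @export
interleafletCorrelation <- function(fieldTop, fieldBottom) {
  stopifnot(is(fieldTop, "GridField"), is(fieldBottom, "GridField"))
  a <- gridValues(fieldTop); b <- gridValues(fieldBottom)
  if (!identical(dim(a), dim(b))) {
    stop("grid mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(NA_real_, constantField = TRUE))
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Local bilayer-center map
#'
#' Divides the bilayer plane into square cells (nominal 3.0 nm) and takes,
#' per cell, the mean z of the tail beads of both leaflets.  Species listed
#' in `exclude` are omitted (by default the shortened `DPPC_3b`, whose short
#' tails would bias the center toward its own domain).  Cells without tail
#' beads are filled by iterative averaging of their periodic neighbors and
#' flagged via the attribute `interpolated`.
#'
#' @param frame a [CGFrame-class].
#' @param cellSize nominal cell edge, nm.
#' @param exclude character vector of species to omit.
#' @return a [GridField-class] of local midplane z values (nm).
#' @export
bilayerCenterMap <- function(frame, cellSize = 3.0, exclude = "DPPC_3b") {
  stopifnot(is(frame, "CGFrame"))
  bd <- beadData(frame)
  g <- .gridShape(frame@box, cellSize)
  sel <- bd$role == "tail" & !(bd$species %in% exclude)
  if (!any(sel)) stop("no tail beads available for the center map")
  cells <- .cellOf(coords(frame)[sel, 1:2, drop = FALSE], frame@box, g$n)
  z <- unwrappedCoords(frame)[sel, 3]
  sums <- matrix(0, g$n[1], g$n[2])
  cnts <- matrix(0, g$n[1], g$n[2])
  for (r in seq_along(z)) {
    sums[cells[r, 1], cells[r, 2]] <- sums[cells[r, 1], cells[r, 2]] + z[r]
    cnts[cells[r, 1], cells[r, 2]] <- cnts[cells[r, 1], cells[r, 2]] + 1
  }
  v <- sums / cnts
  empty <- cnts == 0
  filled <- v
  it <- 0L
  while (any(is.na(filled)) && it < 100L) {
    it <- it + 1L
    nx <- nrow(filled); ny <- ncol(filled)
    up <- filled[c(nx, seq_len(nx - 1L)), , drop = FALSE]
    dn <- filled[c(seq_len(nx)[-1L], 1L), , drop = FALSE]
    lf <- filled[, c(ny, seq_len(ny - 1L)), drop = FALSE]
    rt <- filled[, c(seq_len(ny)[-1L], 1L), drop = FALSE]
    nb <- array(c(up, dn, lf, rt), c(nx, ny, 4))
    nbMean <- apply(nb, c(1, 2), function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
    filled[is.na(filled)] <- nbMean[is.na(filled)]
  }
  out <- new("GridField", values = filled, cellSize = g$cell,
             box = frame@box, label = "bilayerCenter")
  attr(out, "interpolated") <- empty
  out
}

#' Head and tail z-profile relative to the local midplane
#'
#' For every species, the mean over molecules of the head-bead and
#' tail-bead z coordinate minus the local cell midplane, sign-folded so
#' both leaflets contribute with positive sign (the profile is symmetric
#' across the bilayer center by construction).  A tail value below zero
#' means the tails cross the local midplane, i.e. the leaflets
#' interdigitate.
#'
#' @param frame a [CGFrame-class] with leaflets assigned.
#' @param centerMap a [bilayerCenterMap()] result (computed if missing).
#' @return data.frame with columns `species`, `headZ`, `tailZ`,
#'   `interdigitated`.
#' @export
zProfile <- function(frame, centerMap = bilayerCenterMap(frame)) {
  stopifnot(is(frame, "CGFrame"), is(centerMap, "GridField"))
  bd <- beadData(frame)
  if (all(is.na(bd$leaflet))) stop("assign leaflets first (assignLeaflets)")
  n <- dim(gridValues(centerMap))
  z <- unwrappedCoords(frame)[, 3]
  cells <- .cellOf(coords(frame)[, 1:2, drop = FALSE], frame@box, n)
  local_ <- gridValues(centerMap)[cells]
  rel <- (z - local_) * ifelse(bd$leaflet == "upper", 1, -1)
  speciesList <- unique(bd$species)
  res <- do.call(rbind, lapply(speciesList, function(sp) {
    selH <- bd$species == sp & bd$role == "head" & !duplicated(bd$molecule)
    selT <- bd$species == sp & bd$role == "tail"
    data.frame(species = sp,
               headZ = mean(rel[selH]),
               tailZ = mean(rel[selT]),
               stringsAsFactors = FALSE)
  }))
  res$interdigitated <- res$tailZ < 0
  res
}

#' Tail-tail interdigitation across leaflets
#'
#' Signed z separation between the leaflet-mean terminal tail beads:
#' the mean tail z of species A in the upper leaflet minus that of species
#' B (default A) in the lower leaflet.  Negative values mean the tails
#' overlap (interdigitate).  The result carries the vdW sigma (0.47 nm) as
#' attribute `sigma` for reference.
#'
#' @param frame a [CGFrame-class] with leaflets assigned.
#' @param speciesA species whose upper-leaflet tails are used.
#' @param speciesB species whose lower-leaflet tails are used; default
#'   `speciesA`.
#' @return signed separation in nm, or flagged `NA` (attribute
#'   `notApplicable`) when a species is absent from a leaflet, as in
#'   asymmetric bilayers.
#' @export
interdigitation <- function(frame, speciesA, speciesB = speciesA) {
  stopifnot(is(frame, "CGFrame"))
  bd <- beadData(frame)
  if (all(is.na(bd$leaflet))) stop("assign leaflets first (assignLeaflets)")
  z <- unwrappedCoords(frame)[, 3]
  selU <- bd$species == speciesA & bd$leaflet == "upper" & bd$role == "tail"
  selL <- bd$species == speciesB & bd$leaflet == "lower" & bd$role == "tail"
  if (!any(selU) || !any(selL)) {
    return(structure(NA_real_, notApplicable = TRUE))
  }
  structure(mean(z[selU]) - mean(z[selL]), sigma = 0.47)
}

#' Detect domains in a density field
#'
#' Thresholds the field into occupied cells and returns the 4-connected
#' components under periodic wrap, sorted by decreasing size.
#'
#' @param field a [GridField-class].
#' @param threshold occupancy threshold; a cell is occupied when its value
#'   is `>= threshold`.
#' @return list with `sizes` (decreasing component sizes, cells),
#'   `largestFraction` (largest component size over occupied cells; 0 when
#'   the field is empty), and `labels` (matrix of component ids, 0 =
#'   unoccupied).
#' @export
detectDomains <- function(field, threshold = 1) {
  stopifnot(is(field, "GridField"))
  v <- gridValues(field)
  occ <- which(v >= threshold, arr.ind = TRUE)
  labels <- matrix(0L, nrow(v), ncol(v))
  if (!nrow(occ)) {
    return(list(sizes = integer(), largestFraction = 0, labels = labels))
  }
  nx <- nrow(v); ny <- ncol(v)
  id <- function(i, j) (j - 1L) * nx + i
  occId <- id(occ[, 1], occ[, 2])
  occSet <- logical(nx * ny)
  occSet[occId] <- TRUE
  edges <- integer(0)
  for (r in seq_len(nrow(occ))) {
    i <- occ[r, 1]; j <- occ[r, 2]
    for (nb in list(c(i %% nx + 1L, j), c(i, j %% ny + 1L))) {
      if (occSet[id(nb[1], nb[2])]) {
        edges <- c(edges, id(i, j), id(nb[1], nb[2]))
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(occId), directed = FALSE)
  vmap <- integer(nx * ny)
  vmap[occId] <- seq_along(occId)
  if (length(edges)) {
    g <- igraph::add_edges(g, vmap[edges])
  }
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  labels[occ] <- comp$membership
  list(sizes = sizes,
       largestFraction = sizes[1] / sum(sizes),
       labels = labels)
}
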