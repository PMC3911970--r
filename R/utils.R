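## Shared helpers: periodic wrapping, minimum image, molecule comparison.

## wrap positions into [0, box) in x/y; z is unbounded
.wrapXY <- function(xyz, box) {
  xyz[, 1] <- xyz[, 1] %% box[1]
  xyz[, 2] <- xyz[, 2] %% box[2]
  xyz
}

## minimum-image separation for vectors of coordinate differences
.minImage <- function(d, L) {
  d - L * round(d / L)
}

#' Compare two molecule specifications for equality
#'
#' Slot-wise comparison of name, beads, bonds, angles and chains, ignoring
#' data.frame row-name attributes (so that parsed and constructed molecules
#' compare equal).
#'
#' @param a,b [MoleculeSpec-class] objects.
#' @return `TRUE` or a character vector of differences.
#' @export
sameMolecule <- function(a, b) {
  stopifnot(is(a, "MoleculeSpec"), is(b, "MoleculeSpec"))
  norm <- function(df) {
    rownames(df) <- NULL
    df
  }
  msg <- character()
  if (!identical(speciesName(a), speciesName(b))) msg <- c(msg, "name differs")
  for (slot in c("beads", "bonds", "angles")) {
    ok <- isTRUE(all.equal(norm(methods::slot(a, slot)),
                           norm(methods::slot(b, slot)),
                           check.attributes = FALSE))
    if (!ok) msg <- c(msg, paste(slot, "differ"))
  }
  ca <- lapply(chains(a), as.integer)
  cb <- lapply(chains(b), as.integer)
  if (!identical(ca, cb)) msg <- c(msg, "chains differ")
  if (length(msg)) msg else TRUE
}

## per-species bead index of the head bead (first head-role bead)
.headIndex <- function(mol) {
  b <- beads(mol)
  b$index[b$role == "head"][1]
}

## terminal tail beads
.tailIndices <- function(mol) {
  b <- beads(mol)
  b$index[b$role == "tail"]
}

## species registry lookup for a frame: named list of MoleculeSpec covering
## every species present
.registryFor <- function(frame, registry = NULL) {
  if (is.null(registry)) registry <- allSpecies()
  present <- unique(beadData(frame)$species)
  missing <- setdiff(present, names(registry))
  if (length(missing)) {
    stop("species not in registry: ", paste(missing, collapse = ", "))
  }
  registry[present]
}
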