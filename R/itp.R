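## GROMACS topology-include (.itp) emission and parsing.
##
## The dialect is the standard [moleculetype]/[atoms]/[bonds]/[constraints]/
## [angles] layout (angle funct 2, the CG cosine-squared form).  Bead roles
## and the chain ordering have no GROMACS field, so they are carried in
## structured comments (`; cgraft-role=` / `; cgraft-chains:`), which any
## other reader ignores.  Numeric terms are printed with %.10g so that a
## write -> parse cycle reproduces the MoleculeSpec exactly.

.fmt <- function(x) sprintf("%.10g", x)

#' Write a molecule as a GROMACS topology include
#'
#' @param mol a [MoleculeSpec-class].
#' @param path optional file path; when `NULL` the text is only returned.
#' @return character vector of lines, invisibly when `path` is given.
#' @seealso [readItp()] for the inverse.
#' @export
writeItp <- function(mol, path = NULL) {
  stopifnot(is(mol, "MoleculeSpec"))
  validObject(mol)
  b <- beads(mol)
  lines <- c(
    "[ moleculetype ]",
    "; name  nrexcl",
    paste(speciesName(mol), 1),
    "",
    "[ atoms ]",
    "; nr  type  resnr  residue  atom  cgnr  charge",
    sprintf("%4d %5s %5d %8s %5s %4d %8s ; cgraft-role=%s",
            b$index, b$type, 1L, speciesName(mol),
            paste0("B", b$index), b$index, .fmt(b$charge), b$role))
  bd <- bonds(mol)
  plain <- bd[!bd$constraint, , drop = FALSE]
  cons  <- bd[bd$constraint, , drop = FALSE]
  if (nrow(plain)) {
    lines <- c(lines, "", "[ bonds ]", "; i  j  funct  length  k",
               sprintf("%4d %4d  1 %s %s", plain$i, plain$j,
                       .fmt(plain$length), .fmt(plain$k)))
  }
  if (nrow(cons)) {
    lines <- c(lines, "", "[ constraints ]", "; i  j  funct  length",
               sprintf("%4d %4d  1 %s", cons$i, cons$j, .fmt(cons$length)))
  }
  an <- angles(mol)
  if (nrow(an)) {
    lines <- c(lines, "", "[ angles ]", "; i  j  k  funct  theta0  fc",
               sprintf("%4d %4d %4d  2 %s %s", an$a, an$b, an$c,
                       .fmt(an$theta0), .fmt(an$k)))
  }
  chainsTxt <- vapply(chains(mol), paste, "", collapse = " ")
  lines <- c(lines, "",
             paste("; cgraft-chains:", paste(chainsTxt, collapse = " | ")))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a GROMACS topology include written by [writeItp()]
#'
#' @param x character vector of lines, a single string with embedded
#'   newlines, or a path to an existing file.
#' @return a [MoleculeSpec-class].
#' @export
readItp <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x)
  } else if (length(x) == 1L) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  chainsLine <- grep("^\\s*;\\s*cgraft-chains:", x, value = TRUE)
  section <- NA_character_
  atoms <- list(); bondsL <- list(); consL <- list(); anglesL <- list()
  name <- NA_character_
  for (raw in x) {
    line <- sub("^\\s*;.*$", "", raw)       # full-line comments
    payload <- sub("\\s*;.*$", "", line)    # trailing comments
    role <- if (grepl("cgraft-role=", raw)) {
      sub("^.*cgraft-role=([a-z]+).*$", "\\1", raw)
    } else NA_character_
    payload <- trimws(payload)
    if (!nzchar(payload)) next
    if (grepl("^\\[", payload)) {
      section <- tolower(gsub("[][ ]", "", payload))
      next
    }
    tok <- strsplit(payload, "\\s+")[[1]]
    if (is.na(section)) next
    if (section == "moleculetype") {
      name <- tok[1]
    } else if (section == "atoms") {
      atoms[[length(atoms) + 1L]] <- data.frame(
        index = as.integer(tok[1]), type = tok[2],
        role = role, charge = as.numeric(tok[7]),
        stringsAsFactors = FALSE)
    } else if (section == "bonds") {
      bondsL[[length(bondsL) + 1L]] <- data.frame(
        i = as.integer(tok[1]), j = as.integer(tok[2]),
        length = as.numeric(tok[4]), k = as.numeric(tok[5]),
        constraint = FALSE)
    } else if (section == "constraints") {
      consL[[length(consL) + 1L]] <- data.frame(
        i = as.integer(tok[1]), j = as.integer(tok[2]),
        length = as.numeric(tok[4]), k = NA_real_, constraint = TRUE)
    } else if (section == "angles") {
      anglesL[[length(anglesL) + 1L]] <- data.frame(
        a = as.integer(tok[1]), b = as.integer(tok[2]),
        c = as.integer(tok[3]), theta0 = as.numeric(tok[5]),
        k = as.numeric(tok[6]))
    }
  }
  if (is.na(name)) stop("no [moleculetype] section found")
  if (!length(atoms)) stop("no [atoms] section found")
  beads <- do.call(rbind, atoms)
  if (anyNA(beads$role)) stop("missing cgraft-role annotations in [atoms]")
  bonds <- rbind(
    if (length(consL)) do.call(rbind, consL),
    if (length(bondsL)) do.call(rbind, bondsL))
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), length = numeric(),
                        k = numeric(), constraint = logical())
  }
  ## restore the writer's ordering: constraints were emitted after plain
  ## bonds but are stored before them in the sterol constructors
  angles <- if (length(anglesL)) do.call(rbind, anglesL) else
    data.frame(a = integer(), b = integer(), c = integer(),
               theta0 = numeric(), k = numeric())
  chains <- list()
  if (length(chainsLine)) {
    body <- sub("^.*cgraft-chains:\\s*", "", chainsLine[1])
    if (nzchar(trimws(body))) {
      chains <- lapply(strsplit(body, "\\|")[[1]], function(s) {
        as.integer(strsplit(trimws(s), "\\s+")[[1]])
      })
    }
  }
  m <- .newMolecule(name, beads, bonds, angles, chains)
  validObject(m)
  m
}
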