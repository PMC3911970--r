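## Standard CG species and the modified-molecule family.
##
## Bead numbering follows the 12-bead phospholipid layout (1 choline, 2
## phosphate, 3-4 glycerol, 5-8 chain A, 9-12 chain B) and the 8-bead sterol
## layout (1 hydroxyl head, 2-6 ring, 7-8 tail).  Chain-bead types, chain
## angles and chain stiffnesses are the model-defining parameters; head and
## linker types, charges, bond lengths and linker angles are MARTINI 2.0
## registry defaults not restated by this model.

.beadDf <- function(type, role, charge = 0) {
  data.frame(index = seq_along(type), type = type, role = role,
             charge = charge, stringsAsFactors = FALSE)
}

.bondDf <- function(i, j, length, k = 1250, constraint = FALSE) {
  data.frame(i = i, j = j, length = length, k = k, constraint = constraint)
}

.angleDf <- function(a, b, c, theta0, k) {
  data.frame(a = a, b = b, c = c, theta0 = theta0, k = k)
}

.newMolecule <- function(name, beads, bonds, angles, chains) {
  new("MoleculeSpec", name = name, beads = beads, bonds = bonds,
      angles = angles, chains = chains)
}

.buildDPPC <- function(name = "DPPC", chainType = "C1",
                       chainTheta = c(180, 180), chainK = c(25, 25)) {
  beads <- .beadDf(
    type = c("Q0", "Qa", "Na", "Na", rep(chainType, 8)),
    role = c("head", "linker", "linker", "linker",
             "chain", "chain", "chain", "tail",
             "chain", "chain", "chain", "tail"),
    charge = c(1, -1, rep(0, 10)))
  bonds <- .bondDf(
    i = c(1, 2, 3, 3, 5, 6, 7, 4, 9, 10, 11),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    length = c(0.47, 0.47, 0.37, rep(0.47, 8)))
  ## chainTheta/chainK: first entry = angles 5-6-7 / 9-10-11,
  ## second = 6-7-8 / 10-11-12
  angles <- .angleDf(
    a = c(2, 2, 3, 5, 6, 4, 9, 10),
    b = c(3, 3, 5, 6, 7, 9, 10, 11),
    c = c(4, 5, 6, 7, 8, 10, 11, 12),
    theta0 = c(120, 180, 180, chainTheta[1], chainTheta[2],
               180, chainTheta[1], chainTheta[2]),
    k = c(25, 25, 25, chainK[1], chainK[2], 25, chainK[1], chainK[2]))
  .newMolecule(name, beads, bonds, angles,
               chains = list(c(5L, 6L, 7L, 8L), c(9L, 10L, 11L, 12L)))
}

.buildDUPC <- function() {
  m <- .buildDPPC(name = "DUPC", chainTheta = c(100, 120), chainK = c(10, 45))
  m@beads$type[c(6, 7, 10, 11)] <- "C4"
  validObject(m)
  m
}

.buildCHOL <- function() {
  beads <- .beadDf(
    type = c("SP1", "SC1", "SC3", "SC1", "SC1", "SC1", "SC1", "C1"),
    role = c("head", "ring", "ring", "ring", "ring", "ring", "chain", "tail"))
  ## ring geometry carried as constrained bonds (registry defaults)
  bonds <- rbind(
    .bondDf(i = c(1, 2, 2, 3, 4, 4, 5), j = c(2, 3, 4, 5, 5, 6, 6),
            length = c(0.29, 0.28, 0.32, 0.29, 0.27, 0.30, 0.30),
            k = NA_real_, constraint = TRUE),
    .bondDf(i = c(6, 7), j = c(7, 8), length = c(0.35, 0.425)))
  angles <- .angleDf(a = 4, b = 7, c = 8, theta0 = 180, k = 25)
  .newMolecule("CHOL", beads, bonds, angles, chains = list(c(7L, 8L)))
}

#' Build the three standard species
#'
#' Constructs the reference DPPC (fully saturated, all chain beads C1, chain
#' angles 180 degrees at 25 kJ/mol), DUPC (doubly unsaturated: beads 6, 7,
#' 10, 11 of type C4, chain angles 100 degrees at 10 kJ/mol and 120 degrees
#' at 45 kJ/mol) and cholesterol (ring beads SC1/SC3, hydroxyl head SP1,
#' two-bead tail with a 4-7-8 angle at 25 kJ/mol).
#'
#' @return named list of [MoleculeSpec-class]: `DPPC`, `DUPC`, `CHOL`.
#' @examples
#' sp <- buildStandardSpecies()
#' angleTerm(sp$DUPC, 5, 6, 7)$theta0  # 100
#' @export
buildStandardSpecies <- function() {
  out <- list(DPPC = .buildDPPC(), DUPC = .buildDUPC(), CHOL = .buildCHOL())
  lapply(out, validObject)
  out
}

## rows of the angle table whose three beads all sit on an acyl chain
.chainAngleRows <- function(mol) {
  b <- beads(mol)
  role <- b$role[match(seq_len(nrow(b)), b$index)]
  an <- angles(mol)
  which(b$role[match(an$a, b$index)] %in% c("chain", "tail") &
        b$role[match(an$b, b$index)] %in% c("chain", "tail") &
        b$role[match(an$c, b$index)] %in% c("chain", "tail"))
}

#' Variant rule for the modified-DUPC family
#'
#' Flags selecting which differences between DUPC and DPPC are assimilated:
#' equilibrium angles (`a`), angle force constants / stiffness (`s`), and
#' the chain-position-2 and/or position-3 bead types (`b2`, `b3`).  The
#' variant name is derived deterministically from the flags by the
#' lower-letter scheme (`DUa`, `DUs`, `DUas`, `DUb2`, `DUb3`, `DUb23`, ...).
#'
#' @param angles assimilate the chain equilibrium angles to 180 degrees.
#' @param stiffness assimilate the chain angle force constants to 25 kJ/mol.
#' @param bead2 retype the second chain beads (6 and 10) to C1.
#' @param bead3 retype the third chain beads (7 and 11) to C1.
#' @return an object of class `VariantRule`.
#' @export
variantRule <- function(angles = FALSE, stiffness = FALSE,
                        bead2 = FALSE, bead3 = FALSE) {
  structure(list(angles = isTRUE(angles), stiffness = isTRUE(stiffness),
                 bead2 = isTRUE(bead2), bead3 = isTRUE(bead3)),
            class = "VariantRule")
}

#' @rdname variantRule
#' @param rule a `VariantRule`.
#' @export
variantName <- function(rule) {
  stopifnot(inherits(rule, "VariantRule"))
  letters_ <- c(if (rule$angles) "a", if (rule$stiffness) "s")
  bnum <- paste0(c(if (rule$bead2) "2", if (rule$bead3) "3"), collapse = "")
  if (nzchar(bnum)) letters_ <- c(letters_, paste0("b", bnum))
  if (!length(letters_)) return("DUPC")
  paste0("DU", paste0(letters_, collapse = ""))
}

#' Apply a variant rule to the standard DUPC
#'
#' Systematic assimilation of DUPC chain properties to DPPC's: the angle
#' flag sets both chain angle pairs to 180 degrees, the stiffness flag sets
#' both chain angle force constants to 25 kJ/mol, and the bead flags retype
#' the second (6, 10) and/or third (7, 11) chain beads to C1.  Both chains
#' are always modified together.  All untouched fields are carried over
#' unchanged, and applying a rule twice equals applying it once.
#'
#' @param base the standard DUPC [MoleculeSpec-class].
#' @param rule a [variantRule()].
#' @return a [MoleculeSpec-class] named by the lower-letter scheme.
#' @examples
#' dupc <- buildStandardSpecies()$DUPC
#' duas <- applyDupcVariant(dupc, variantRule(angles = TRUE, stiffness = TRUE))
#' angleTerm(duas, 5, 6, 7)  # theta0 180, k 25
#' @export
applyDupcVariant <- function(base, rule) {
  stopifnot(is(base, "MoleculeSpec"), inherits(rule, "VariantRule"))
  if (speciesName(base) != "DUPC") {
    stop("applyDupcVariant() operates on the standard DUPC only, got ",
         speciesName(base))
  }
  m <- base
  rows <- .chainAngleRows(m)
  if (rule$angles)    m@angles$theta0[rows] <- 180
  if (rule$stiffness) m@angles$k[rows] <- 25
  if (rule$bead2)     m@beads$type[m@beads$index %in% c(6L, 10L)] <- "C1"
  if (rule$bead3)     m@beads$type[m@beads$index %in% c(7L, 11L)] <- "C1"
  m@name <- variantName(rule)
  validObject(m)
  m
}

#' Softened DPPC
#'
#' DPPC with all four chain angle force constants lowered (default 10 kJ/mol,
#' a 60 percent reduction of the standard 25 kJ/mol); equilibrium angles and
#' everything else unchanged.
#'
#' @param kSoft chain angle force constant, kJ/mol.
#' @return a [MoleculeSpec-class] named `DPPC_soft`.
#' @export
makeDppcSoft <- function(kSoft = 10) {
  stopifnot(is.numeric(kSoft), length(kSoft) == 1L, kSoft > 0)
  m <- .buildDPPC(name = "DPPC_soft")
  m@angles$k[.chainAngleRows(m)] <- kSoft
  validObject(m)
  m
}

#' Shortened rigid DPPC-like sterol mimic
#'
#' A DPPC-derived molecule with three chain beads per tail instead of four,
#' all chain beads retyped to the ring type SC1 (suppressing
#' self-aggregation via the 0.75 ring scaling), chain angle force constants
#' raised to 300 kJ/mol to keep the chains straight, and one extra bond
#' joining the terminal beads of the two chains.  In the original 12-bead
#' numbering that extra bond links beads 7 and 11, i.e. the beads that
#' become chain-terminal after removing the fourth chain beads.
#'
#' @return a [MoleculeSpec-class] named `DPPC_3b`.
#' @export
makeDppc3b <- function() {
  beads <- .beadDf(
    type = c("Q0", "Qa", "Na", "Na", rep("SC1", 6)),
    role = c("head", "linker", "linker", "linker",
             "chain", "chain", "tail", "chain", "chain", "tail"),
    charge = c(1, -1, rep(0, 8)))
  bonds <- rbind(
    .bondDf(i = c(1, 2, 3, 3, 5, 6, 4, 8, 9),
            j = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
            length = c(0.47, 0.47, 0.37, rep(0.47, 6))),
    ## the chain-tying bond (beads 7 and 11 of the 12-bead numbering)
    .bondDf(i = 7, j = 10, length = 0.47))
  angles <- .angleDf(
    a = c(2, 2, 3, 5, 4, 8),
    b = c(3, 3, 5, 6, 8, 9),
    c = c(4, 5, 6, 7, 9, 10),
    theta0 = c(120, 180, 180, 180, 180, 180),
    k = c(25, 25, 25, 300, 25, 300))
  m <- .newMolecule("DPPC_3b", beads, bonds, angles,
                    chains = list(c(5L, 6L, 7L), c(8L, 9L, 10L)))
  validObject(m)
  m
}

#' Cholesterol-derived variants
#'
#' * `CHOL_300`: cholesterol with the tail angle (beads 4-7-8) force
#'   constant raised from 25 to 300 kJ/mol, removing the conformational
#'   freedom of the last bead.
#' * `CHOL_+1HB`: cholesterol with one extra polar SP1 bead bonded above the
#'   hydroxyl head (bead 1), enlarging the headgroup to probe the umbrella
#'   mechanism.
#' * `DPPC_3b_plus1`: the [makeDppc3b()] mimic with one additional mobile
#'   C1 bead appended to one chain at an angle force constant of 25 kJ/mol
#'   (matching cholesterol's 4-7-8 tail term).
#'
#' @param kind one of `"CHOL_300"`, `"CHOL_+1HB"`, `"DPPC_3b_plus1"`.
#' @return a [MoleculeSpec-class].
#' @export
makeCholVariant <- function(kind = c("CHOL_300", "CHOL_+1HB", "DPPC_3b_plus1")) {
  kind <- match.arg(kind)
  if (kind == "CHOL_300") {
    m <- .buildCHOL()
    hit <- m@angles$a == 4 & m@angles$b == 7 & m@angles$c == 8
    m@angles$k[hit] <- 300
    m@name <- "CHOL_300"
  } else if (kind == "CHOL_+1HB") {
    m <- .buildCHOL()
    m@beads <- rbind(m@beads,
                     data.frame(index = 9L, type = "SP1", role = "head",
                                charge = 0))
    m@bonds <- rbind(m@bonds, .bondDf(i = 1, j = 9, length = 0.29))
    m@name <- "CHOL_+1HB"
  } else {
    m <- makeDppc3b()
    m@beads$role[m@beads$index == 7L] <- "chain"
    m@beads <- rbind(m@beads,
                     data.frame(index = 11L, type = "C1", role = "tail",
                                charge = 0))
    m@bonds <- rbind(m@bonds, .bondDf(i = 7, j = 11, length = 0.47))
    m@angles <- rbind(m@angles, .angleDf(a = 6, b = 7, c = 11,
                                         theta0 = 180, k = 25))
    m@chains <- list(c(5L, 6L, 7L, 11L), c(8L, 9L, 10L))
    m@name <- "DPPC_3b_plus1"
  }
  validObject(m)
  m
}

#' Build every species of the study
#'
#' The three standard species, the six modified-DUPC lipids, softened DPPC,
#' the sterol mimic and the cholesterol variants.
#'
#' @return named list of [MoleculeSpec-class] objects.
#' @export
allSpecies <- function() {
  std <- buildStandardSpecies()
  dupc <- std$DUPC
  ruleset <- list(
    DUa   = variantRule(angles = TRUE),
    DUs   = variantRule(stiffness = TRUE),
    DUas  = variantRule(angles = TRUE, stiffness = TRUE),
    DUb2  = variantRule(bead2 = TRUE),
    DUb3  = variantRule(bead3 = TRUE),
    DUb23 = variantRule(bead2 = TRUE, bead3 = TRUE))
  variants <- lapply(ruleset, function(r) applyDupcVariant(dupc, r))
  c(std, variants,
    list(DPPC_soft = makeDppcSoft(),
         DPPC_3b = makeDppc3b(),
         CHOL_300 = makeCholVariant("CHOL_300"),
         `CHOL_+1HB` = makeCholVariant("CHOL_+1HB"),
         DPPC_3b_plus1 = makeCholVariant("DPPC_3b_plus1")))
}
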