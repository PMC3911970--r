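## Bead-type registry and nonbonded matrix construction.
##
## Only the C1/C4 well depths (3.5 / 3.1 kJ/mol) and the ring rules
## (SCx-SCy = 0.75 x Cx-Cy, SCx-Cy = Cx-Cy, sigma = 0.47 nm) are fixed by
## the model this package implements.  All remaining entries (charged and
## polar head/linker types) are registry defaults in the style of the
## published MARTINI 2.0 interaction levels; they are user-overridable and
## are flagged as external defaults, not values of this model.

.base_types <- c("Q0", "Qa", "Na", "P1", "C1", "C2", "C3", "C4", "C5")

# parent regular type of each small ("S") type
.s_parent <- c(SP1 = "P1", SC1 = "C1", SC2 = "C2", SC3 = "C3",
               SC4 = "C4", SC5 = "C5")

.default_epsilon_table <- function() {
  n <- length(.base_types)
  e <- matrix(NA_real_, n, n, dimnames = list(.base_types, .base_types))
  set <- function(a, b, v) {
    e[a, b] <<- v
    e[b, a] <<- v
  }
  ## chain-bead block: fixed by the model
  set("C1", "C1", 3.5); set("C4", "C4", 3.5); set("C1", "C4", 3.1)
  ## remaining entries: MARTINI 2.0-style level defaults (overridable)
  set("Q0", "Q0", 3.5); set("Q0", "Qa", 4.5); set("Qa", "Qa", 5.6)
  set("Q0", "Na", 3.5); set("Qa", "Na", 4.0); set("Na", "Na", 4.0)
  set("Q0", "P1", 4.0); set("Qa", "P1", 5.0); set("Na", "P1", 4.5)
  set("P1", "P1", 4.5)
  set("Q0", "C1", 2.0); set("Qa", "C1", 2.0); set("Na", "C1", 2.7)
  set("P1", "C1", 2.7)
  set("Q0", "C2", 2.0); set("Qa", "C2", 2.0); set("Na", "C2", 2.7)
  set("P1", "C2", 3.1); set("C1", "C2", 3.5); set("C2", "C2", 3.5)
  set("Q0", "C3", 2.0); set("Qa", "C3", 2.3); set("Na", "C3", 2.7)
  set("P1", "C3", 3.1); set("C1", "C3", 3.5); set("C2", "C3", 3.5)
  set("C3", "C3", 3.5)
  set("Q0", "C4", 2.3); set("Qa", "C4", 2.3); set("Na", "C4", 3.1)
  set("P1", "C4", 3.1); set("C2", "C4", 3.5); set("C3", "C4", 3.5)
  set("Q0", "C5", 2.7); set("Qa", "C5", 3.1); set("Na", "C5", 3.5)
  set("P1", "C5", 3.5); set("C1", "C5", 3.1); set("C2", "C5", 3.5)
  set("C3", "C5", 3.5); set("C4", "C5", 3.5); set("C5", "C5", 3.5)
  e
}

#' Registered bead types
#'
#' The bead-type tokens known to the package: regular MARTINI types used by
#' the three standard species plus the small ("S") ring/head types.  Small
#' types map to a parent regular type which fixes their interactions.
#'
#' @return data.frame with columns `type`, `parent` (the regular type an S
#'   type derives from; equal to `type` for regular types), `small`
#'   (logical).
#' @export
beadTypes <- function() {
  reg <- data.frame(type = .base_types, parent = .base_types,
                    small = FALSE, stringsAsFactors = FALSE)
  sm <- data.frame(type = names(.s_parent), parent = unname(.s_parent),
                   small = TRUE, stringsAsFactors = FALSE)
  rbind(reg, sm)
}

#' Build the nonbonded van der Waals matrix
#'
#' Expands the regular-type well-depth table to all registered types by the
#' ring rules: a small type against a regular type interacts with the full
#' strength of its parent pair, while two small types interact at 0.75 times
#' the parent pair strength.  A single sigma is used for the whole family.
#'
#' @param epsilonTable optional symmetric matrix over the regular types
#'   (kJ/mol) replacing the registry defaults.
#' @param sigma Lennard-Jones sigma, nm.
#' @return a [NonbondedMatrix-class].
#' @examples
#' nb <- buildNonbondedMatrix()
#' vdwEpsilon(nb, "C1", "C4")   # 3.1
#' vdwEpsilon(nb, "SC1", "SC1") # 0.75 * 3.5
#' @export
buildNonbondedMatrix <- function(epsilonTable = .default_epsilon_table(),
                                 sigma = 0.47) {
  stopifnot(identical(rownames(epsilonTable), .base_types),
            identical(colnames(epsilonTable), .base_types),
            !anyNA(epsilonTable))
  reg <- beadTypes()
  types <- reg$type
  n <- length(types)
  e <- matrix(NA_real_, n, n, dimnames = list(types, types))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pi_ <- reg$parent[i]; pj <- reg$parent[j]
      v <- epsilonTable[pi_, pj]
      if (reg$small[i] && reg$small[j]) v <- 0.75 * v
      e[i, j] <- v
    }
  }
  new("NonbondedMatrix", epsilon = e, sigma = sigma)
}

#' Query a pairwise well depth
#'
#' @param nb a [NonbondedMatrix-class].
#' @param a,b bead-type tokens.
#' @return epsilon(a, b) in kJ/mol (symmetric in its arguments).
#' @export
setGeneric("vdwEpsilon", function(nb, a, b) standardGeneric("vdwEpsilon"))

#' @rdname vdwEpsilon
#' @export
setMethod("vdwEpsilon", "NonbondedMatrix", function(nb, a, b) {
  e <- nb@epsilon
  bad <- setdiff(c(a, b), rownames(e))
  if (length(bad)) stop("unknown bead type(s): ", paste(bad, collapse = ", "))
  unname(e[cbind(a, b)])
})

#' @rdname vdwEpsilon
#' @export
setGeneric("vdwSigma", function(nb) standardGeneric("vdwSigma"))

#' @rdname vdwEpsilon
#' @export
setMethod("vdwSigma", "NonbondedMatrix", function(nb) nb@sigma)
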