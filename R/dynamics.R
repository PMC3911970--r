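## Phenomenological lateral dynamics and scenario timecourses.
##
## Molecules undergo rigid 2D Brownian translation with per-species,
## per-phase diffusion constants, accumulated in unwrapped coordinates and
## wrapped into the periodic box.  None of this is force-field MD: the
## generator only reproduces the kinematic signatures (normal diffusion,
## gel arrest) that the MSD analysis consumes.

#' Lateral dynamics parameters
#'
#' Diffusion constants may be a single number, a named vector by phase
#' (`disordered`, `ordered`), a named vector by species, or a matrix with
#' species rows and phase columns.  With `gelArrest`, molecules inside the
#' ordered domain of a gel-state layout are frozen (D = 0).
#'
#' @param D nm^2/ns; see above for accepted shapes.
#' @param nFrames number of frames to generate after the initial one.
#' @param dt frame spacing, ns.
#' @param gelArrest freeze ordered-domain molecules.
#' @param seed RNG seed.
#' @return list of class `DynamicsParams`.
#' @export
dynamicsParams <- function(D = 0.1, nFrames = 100L, dt = 1,
                           gelArrest = FALSE, seed = NULL) {
  stopifnot(all(D >= 0), nFrames >= 1, dt > 0)
  structure(list(D = D, nFrames = as.integer(nFrames), dt = dt,
                 gelArrest = isTRUE(gelArrest), seed = seed),
            class = "DynamicsParams")
}

## resolve D to one value per molecule
.resolveD <- function(D, species, ordered) {
  phase <- ifelse(ordered, "ordered", "disordered")
  if (is.matrix(D)) {
    return(D[cbind(species, phase)])
  }
  if (!is.null(names(D))) {
    if (all(names(D) %in% c("ordered", "disordered"))) {
      return(unname(D[phase]))
    }
    out <- D[species]
    if (anyNA(out)) stop("no diffusion constant for species: ",
                         paste(unique(species[is.na(out)]), collapse = ", "))
    return(unname(out))
  }
  rep(D[1], length(species))
}

#' Simulate lateral Brownian dynamics from a frame
#'
#' Each molecule receives independent Gaussian x/y displacements of
#' variance `2 D dt` per step, applied rigidly to all its beads; internal
#' geometry is preserved.  Unwrapped coordinates accumulate the true path;
#' wrapped coordinates are re-wrapped into the box each frame.  With
#' `gelArrest`, molecules flagged as belonging to the ordered (gel) domain
#' do not move.
#'
#' @param frame0 starting [CGFrame-class] (from [buildBilayer()]).
#' @param dyn a [dynamicsParams()].
#' @param layout the [phaseLayout()] the frame was built with; controls
#'   which molecules count as ordered-domain for `gelArrest`.
#' @return a [CGTrajectory-class] of `nFrames + 1` frames.
#' @export
simulateLateralDynamics <- function(frame0, dyn,
                                    layout = phaseLayout("mixed")) {
  stopifnot(is(frame0, "CGFrame"), inherits(dyn, "DynamicsParams"))
  bd <- beadData(frame0)
  molTab <- moleculeTable(frame0)
  nMol <- nrow(molTab)
  molRow <- match(bd$molecule, molTab$molecule)
  ordered <- if ("ordered" %in% names(bd)) {
    bd$ordered[!duplicated(bd$molecule)]
  } else rep(FALSE, nMol)
  if (layout$state == "gel") ordered <- rep(TRUE, nMol)
  Dmol <- .resolveD(dyn$D, molTab$species, ordered)
  if (dyn$gelArrest) Dmol[ordered] <- 0
  sd_ <- sqrt(2 * Dmol * dyn$dt)
  nf <- dyn$nFrames + 1L
  n <- nrow(bd)
  co <- array(NA_real_, c(n, 3, nf))
  un <- array(NA_real_, c(n, 3, nf))
  un[, , 1] <- unwrappedCoords(frame0)
  co[, , 1] <- coords(frame0)
  .withSeed(dyn$seed, {
    cur <- unwrappedCoords(frame0)
    for (t in 2:nf) {
      dx <- stats::rnorm(nMol, 0, sd_)
      dy <- stats::rnorm(nMol, 0, sd_)
      cur[, 1] <- cur[, 1] + dx[molRow]
      cur[, 2] <- cur[, 2] + dy[molRow]
      un[, , t] <- cur
      co[, , t] <- .wrapXY(cur, frame0@box)
    }
  })
  new("CGTrajectory", coords = co, unwrapped = un,
      times = frame0@time + (seq_len(nf) - 1L) * dyn$dt,
      box = frame0@box, beadData = bd)
}

#' Generate a scenario timecourse
#'
#' Piecewise-interpolated trajectories connecting an initial and final
#' bilayer state on a linear schedule, so that pipeline time series are
#' monotone in the constructed direction:
#'
#' * `demixing`: mixed -> separated; order of the saturated lipid and
#'   sterol rises, ordered-domain registration approaches the target.
#' * `remixing`: separated -> mixed; order and correlation revert.
#' * `gelation`: mixed -> gel; terminal order near 0.9 for every species
#'   and tails withdrawn from the midplane.
#'
#' Each molecule keeps its species; lateral positions move linearly from
#' their initial to final lattice sites and chains are resampled each frame
#' at the interpolated order target.
#'
#' @param scenario `"demixing"`, `"remixing"` or `"gelation"`.
#' @param comp a [compositionSpec()].
#' @param nFrames number of frames (>= 2).
#' @param dt frame spacing, ns.
#' @param registration terminal registration target for the ordered domain.
#' @param seed RNG seed.
#' @return a [CGTrajectory-class].
#' @export
generateTimecourse <- function(scenario = c("demixing", "remixing", "gelation"),
                               comp = compositionSpec(),
                               nFrames = 21L, dt = 1, registration = 1,
                               seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(nFrames >= 2)
  endState <- switch(scenario, demixing = "separated",
                     remixing = "mixed", gelation = "gel")
  startState <- switch(scenario, remixing = "separated", "mixed")
  species <- names(comp$counts)
  oStart <- defaultOrderTargets(startState, species)
  oEnd <- defaultOrderTargets(endState, species)
  .withSeed(seed, {
    layStart <- phaseLayout(startState, registration = registration)
    layEnd <- phaseLayout(endState, registration = registration)
    f0 <- buildBilayer(comp, layStart, oStart)
    f1 <- buildBilayer(comp, layEnd, oEnd)
    ## pair molecules of equal species across the two endpoint frames so
    ## each keeps its identity while relocating
    bd0 <- beadData(f0); bd1 <- beadData(f1)
    m0 <- moleculeTable(f0); m1 <- moleculeTable(f1)
    map <- integer(nrow(m0))
    for (leaf in c("upper", "lower")) {
      for (sp in unique(m0$species)) {
        i0 <- which(m0$species == sp & m0$leaflet == leaf)
        i1 <- which(m1$species == sp & m1$leaflet == leaf)
        stopifnot(length(i0) == length(i1))
        map[i0] <- i1
      }
    }
    ## per-molecule lateral displacement between endpoints (first bead as
    ## the molecular anchor)
    firstBead0 <- match(m0$molecule, bd0$molecule)
    firstBead1 <- match(m1$molecule[map], bd1$molecule)
    disp <- unwrappedCoords(f1)[firstBead1, 1:2, drop = FALSE] -
      unwrappedCoords(f0)[firstBead0, 1:2, drop = FALSE]
    frames <- vector("list", nFrames)
    molRow <- match(bd0$molecule, m0$molecule)
    ordEnd <- if ("ordered" %in% names(bd1)) bd1$ordered[firstBead1] else
      rep(FALSE, nrow(m0))
    for (t in seq_len(nFrames)) {
      w <- (t - 1) / (nFrames - 1)
      S <- (1 - w) * oStart$S + w * oEnd$S
      gap <- (1 - w) * oStart$gap + w * oEnd$gap
      x0 <- unwrappedCoords(f0)[firstBead0, 1] + w * disp[, 1]
      y0 <- unwrappedCoords(f0)[firstBead0, 2] + w * disp[, 2]
      tailZ <- .defaultTailZ(species, gap)
      headZ <- .defaultHeadZ(species)
      registry <- allSpecies()
      pos <- matrix(NA_real_, nrow(bd0), 3)
      for (m in seq_len(nrow(m0))) {
        sp <- m0$species[m]
        sign_ <- if (m0$leaflet[m] == "upper") 1 else -1
        rows <- which(molRow == m)
        pos[rows, ] <- .placeMolecule(registry[[sp]], x0[m], y0[m], sign_,
                                      S[[sp]], headZ[[sp]], tailZ[[sp]])
      }
      bd <- bd0
      bd$ordered <- ordEnd[molRow]
      frames[[t]] <- new("CGFrame", coords = .wrapXY(pos, f0@box),
                         unwrapped = pos, box = f0@box,
                         time = (t - 1) * dt, beadData = bd)
    }
    framesToTrajectory(frames)
  })
}
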