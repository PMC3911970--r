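## Time-series assembly and Ld/Lo/gel phase calls.

#' Interaction-energy gain relative to a reference time
#'
#' `dE(t) = E(t) - E(t_ref)` with the reference at 1 ns by convention (the
#' time by which initial non-equilibrium transients have decayed).  When
#' `tRef` is off the time grid the nearest frame is used and recorded in
#' the attribute `tRefUsed`.
#'
#' @param E numeric vector of energies (kJ/mol per molecule).
#' @param times numeric vector of frame times, ns.
#' @param tRef reference time, ns.
#' @return numeric vector of gains; exactly 0 at the reference frame.
#' @export
energyGainSeries <- function(E, times, tRef = 1) {
  if (!length(E)) stop("empty energy series")
  stopifnot(length(E) == length(times))
  i <- which.min(abs(times - tRef))
  structure(E - E[i], tRefUsed = times[i])
}

#' Per-frame observable time series of a trajectory
#'
#' Computes, for every frame: per-species order parameters, per-species
#' pair-energy totals and the interleaflet density correlation of a
#' reference species (default the saturated lipid), and attaches the
#' energy-gain series.  Multiple replicate trajectories on the same time
#' grid are aggregated as mean with standard errors.
#'
#' @param traj a [CGTrajectory-class] or list of replicate trajectories.
#' @param nb a [NonbondedMatrix-class] for the energies.
#' @param corrSpecies species for the interleaflet correlation field.
#' @param cellSize correlation grid cell, nm.
#' @param tRef reference time for energy gains, ns.
#' @param energies compute pair energies (the slowest observable).
#' @return data.frame of class `ObservableSeries` in long format: `time`,
#'   `species`, `S`, `E`, `dE`, `corr`, plus `seS`/`seE` columns when
#'   replicates were aggregated (standard errors over replicates).
#' @export
runTimecourse <- function(traj, nb = buildNonbondedMatrix(),
                          corrSpecies = "DPPC", cellSize = 1.5,
                          tRef = 1, energies = TRUE) {
  if (is.list(traj) && !is(traj, "CGTrajectory")) {
    reps <- lapply(traj, runTimecourse, nb = nb, corrSpecies = corrSpecies,
                   cellSize = cellSize, tRef = tRef, energies = energies)
    return(.aggregateReplicates(reps))
  }
  stopifnot(is(traj, "CGTrajectory"))
  times <- frameTimes(traj)
  speciesList <- sort(unique(beadData(traj)$species))
  rows <- list()
  for (i in seq_len(nFrames(traj))) {
    fr <- getFrame(traj, i)
    if (all(is.na(beadData(fr)$leaflet))) fr <- assignLeaflets(fr)
    corr <- if (corrSpecies %in% speciesList) {
      top <- gridDensity(fr, "upper", corrSpecies, cellSize)
      bot <- gridDensity(fr, "lower", corrSpecies, cellSize)
      suppressWarnings(as.numeric(interleafletCorrelation(top, bot)))
    } else NA_real_
    en <- if (energies) pairEnergy(fr, nb) else NULL
    for (sp in speciesList) {
      S <- orderParameter(fr, sp)$S
      E <- if (is.null(en)) NA_real_ else {
        hit <- en$perSpecies$species == sp
        if (any(hit)) en$perSpecies$total[hit] else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        time = times[i], species = sp, S = S, E = E, corr = corr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$dE <- NA_real_
  for (sp in speciesList) {
    hit <- out$species == sp
    if (!anyNA(out$E[hit])) {
      out$dE[hit] <- energyGainSeries(out$E[hit], out$time[hit], tRef)
    }
  }
  class(out) <- c("ObservableSeries", class(out))
  attr(out, "replicates") <- 1L
  out
}

## mean +- standard error across replicate series on a common grid
.aggregateReplicates <- function(reps) {
  stopifnot(length(reps) >= 1L)
  grid <- reps[[1]][c("time", "species")]
  for (r in reps[-1]) {
    if (!identical(r[c("time", "species")], grid)) {
      stop("replicate time grids are mismatched")
    }
  }
  nrep <- length(reps)
  pick <- function(col) sapply(reps, function(r) r[[col]])
  out <- reps[[1]]
  for (col in c("S", "E", "dE", "corr")) {
    m <- pick(col)
    out[[col]] <- rowMeans(m)
    if (nrep >= 2L) {
      out[[paste0("se", toupper(substr(col, 1, 1)),
                  substr(col, 2, nchar(col)))]] <-
        apply(m, 1, stats::sd) / sqrt(nrep)
    }
  }
  attr(out, "replicates") <- nrep
  out
}

#' Classify the phase of each species domain
#'
#' Operationalises the qualitative phase signatures: gel requires very high
#' chain order together with an arrested MSD; Lo is ordered but mobile; Ld
#' is everything below the Lo boundary.  The mixing state is called from
#' the largest-domain fraction of a thresholded density field.  The order
#' thresholds are conventions of this package (configurable), not measured
#' constants: gel order is "around 0.9" and no Lo/Ld boundary value exists,
#' so defaults of 0.8 and 0.45 are used and echoed in the output.
#'
#' @param S named numeric vector: terminal order parameter per species.
#' @param msdPlateau named logical vector: MSD arrest flag per species.
#' @param largestDomainFraction optional: largest same-species domain
#'   fraction from [detectDomains()].
#' @param thresholds list with `sGel`, `sLo`, `domainFrac`.
#' @return data.frame with one row per species: `species`, `label`
#'   (`Ld`/`Lo`/`gel`), `mixingState` (`mixed`/`separated`/`NA`), and the
#'   evidence columns `S`, `plateau`, plus the thresholds used as
#'   attributes.
#' @export
classifyPhase <- function(S, msdPlateau,
                          largestDomainFraction = NA_real_,
                          thresholds = list(sGel = 0.8, sLo = 0.45,
                                            domainFrac = 0.5)) {
  stopifnot(!is.null(names(S)))
  if (is.null(names(msdPlateau)) || !all(names(S) %in% names(msdPlateau))) {
    stop("msdPlateau must be named and cover every species in S")
  }
  lab <- vapply(names(S), function(sp) {
    if (S[[sp]] >= thresholds$sGel && isTRUE(msdPlateau[[sp]])) "gel"
    else if (S[[sp]] >= thresholds$sLo) "Lo"
    else "Ld"
  }, "")
  mixing <- if (is.na(largestDomainFraction)) NA_character_
  else if (largestDomainFraction >= thresholds$domainFrac) "separated"
  else "mixed"
  out <- data.frame(species = names(S), label = unname(lab),
                    S = unname(S[names(S)]),
                    plateau = unname(msdPlateau[names(S)]),
                    mixingState = mixing, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}
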