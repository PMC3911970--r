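## Mean-square displacement, diffusion fits and coordinate RMSD.

#' Lateral mean-square displacement
#'
#' `<|r(t) - r(0)|^2>` in the bilayer plane (x/y) over the molecules of a
#' species, averaged over multiple time origins, from unwrapped
#' coordinates.  The log-log slope over a fit window distinguishes normal
#' diffusion (slope 1) from arrest (plateau), and a linear fit of MSD
#' against lag time through the origin yields the diffusion constant
#' `D = MSD / (4 t)`.
#'
#' @param traj a [CGTrajectory-class] with unwrapped coordinates.
#' @param species species name.
#' @param leaflet optionally restrict to one leaflet.
#' @param molecules optional vector of molecule ids to restrict to.
#' @param nOrigins number of evenly spaced time origins.
#' @param fitWindow lag-time window (ns) for both fits; default up to 20 ns
#'   (the onset of the diffusive regime) or the trajectory midpoint,
#'   whichever is smaller.
#' @param plateauThreshold log-log slope below which the terminal decade is
#'   flagged as arrested.
#' @return list with `series` (data.frame `lag`, `msd`), `slope` (log-log),
#'   `D` (nm^2/ns), `plateau` (logical).
#' @export
msdSeries <- function(traj, species, leaflet = NULL, molecules = NULL,
                      nOrigins = 10L, fitWindow = NULL,
                      plateauThreshold = 0.2) {
  stopifnot(is(traj, "CGTrajectory"))
  bd <- beadData(traj)
  sel <- bd$species == species & bd$role == "head" & !duplicated(bd$molecule)
  if (!is.null(leaflet)) sel <- sel & bd$leaflet == leaflet
  if (!is.null(molecules)) sel <- sel & bd$molecule %in% molecules
  rows <- which(sel)
  if (!length(rows)) stop("no molecules selected for species ", species)
  times <- frameTimes(traj)
  nf <- length(times)
  dtGrid <- diff(times)
  if (max(abs(dtGrid - dtGrid[1])) > 1e-9) {
    stop("msdSeries requires a uniform time grid")
  }
  dt <- dtGrid[1]
  un <- traj@unwrapped[rows, 1:2, , drop = FALSE]
  ## wrapped coordinates in disguise: a bead jumping by more than half the
  ## box between consecutive frames betrays re-wrapping
  if (nf > 1L) {
    jumps <- abs(un[, , -1L, drop = FALSE] - un[, , -nf, drop = FALSE])
    if (max(jumps) > min(traj@box) / 2) {
      stop("coordinates appear to be wrapped; unwrap the trajectory ",
           "before computing MSD")
    }
  }
  maxLag <- nf - 1L
  origins <- unique(round(seq(1, nf - 1L, length.out = min(nOrigins, nf - 1L))))
  msd <- numeric(maxLag)
  cnt <- integer(maxLag)
  for (o in origins) {
    lags <- seq_len(nf - o)
    for (l in lags) {
      d <- un[, , o + l, drop = FALSE] - un[, , o, drop = FALSE]
      msd[l] <- msd[l] + mean(d[, 1, ]^2 + d[, 2, ]^2)
      cnt[l] <- cnt[l] + 1L
    }
  }
  msd <- msd / cnt
  lag <- seq_len(maxLag) * dt
  series <- data.frame(lag = lag, msd = msd)
  if (is.null(fitWindow)) fitWindow <- min(20, max(lag) / 2)
  win <- which(lag <= fitWindow & msd > 0)
  slope <- NA_real_
  D <- NA_real_
  if (length(win) >= 2L) {
    fit <- stats::lm(log(msd[win]) ~ log(lag[win]))
    slope <- unname(stats::coef(fit)[2])
    D <- unname(stats::coef(stats::lm(msd[win] ~ 0 + lag[win]))[1]) / 4
  }
  ## plateau: terminal log-log slope over the last half of the lags;
  ## an identically arrested trajectory (zero MSD) is a plateau too
  tail_ <- which(lag > max(lag) / 2 & msd > 0)
  plateau <- max(msd) < 1e-12
  if (length(tail_) >= 2L) {
    sl2 <- unname(stats::coef(stats::lm(log(msd[tail_]) ~ log(lag[tail_])))[2])
    plateau <- sl2 < plateauThreshold
  }
  list(series = series, slope = slope, D = D, plateau = plateau)
}

#' Coordinate RMSD between two frames
#'
#' Plain root-mean-square deviation over matched beads.  No rotational
#' superposition is performed (the bilayer normal fixes the frame); the
#' lateral center-of-mass drift can optionally be removed.
#'
#' @param frame a [CGFrame-class].
#' @param reference a [CGFrame-class] with the same beads.
#' @param removeXYDrift subtract the mean x/y displacement first.
#' @return RMSD in nm.
#' @export
frameRmsd <- function(frame, reference, removeXYDrift = FALSE) {
  stopifnot(is(frame, "CGFrame"), is(reference, "CGFrame"))
  a <- unwrappedCoords(frame)
  b <- unwrappedCoords(reference)
  if (!identical(dim(a), dim(b))) {
    stop("mismatched bead counts: ", nrow(a), " vs ", nrow(b))
  }
  d <- a - b
  if (removeXYDrift) {
    d[, 1] <- d[, 1] - mean(d[, 1])
    d[, 2] <- d[, 2] - mean(d[, 2])
  }
  sqrt(mean(rowSums(d^2)))
}
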