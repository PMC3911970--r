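## GRO coordinate format IO.
##
## Standard fixed-width records: "%5d%-5s%5s%5d%8.3f%8.3f%8.3f" with a
## trailing box line.  Coordinates are stored to 0.001 nm, the format's
## native precision; a write -> read -> write cycle is bit-identical.
## Multi-frame trajectories are concatenated models in one file, with the
## frame time encoded as "t= <ns>" in the title line.  z box length is
## written as the z extent of the frame plus a margin (the bilayer is
## periodic in x/y only).

.groResname <- function(species) {
  ## GRO residue field is 5 characters; long variant names are truncated
  substr(gsub("[^A-Za-z0-9]", "", species), 1, 5)
}

.writeGroFrame <- function(frame, title) {
  bd <- beadData(frame)
  xyz <- coords(frame)
  n <- nrow(xyz)
  zspan <- max(abs(xyz[, 3])) * 2 + 2
  c(title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            bd$molecule %% 100000L, .groResname(bd$species),
            substr(paste0("B", bd$beadIndex), 1, 5),
            seq_len(n) %% 100000L,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame@box[1], frame@box[2], zspan))
}

#' Write frames in GRO format
#'
#' @param x a [CGFrame-class] or [CGTrajectory-class] (frames concatenated).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeGro <- function(x, path) {
  if (is(x, "CGFrame")) {
    lines <- .writeGroFrame(x, sprintf("cgraft bilayer t= %.6f", x@time))
  } else if (is(x, "CGTrajectory")) {
    lines <- unlist(lapply(seq_len(nFrames(x)), function(i) {
      f <- getFrame(x, i)
      .writeGroFrame(f, sprintf("cgraft bilayer t= %.6f", f@time))
    }))
  } else {
    stop("x must be a CGFrame or CGTrajectory")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read GRO frames
#'
#' Parses one or more concatenated GRO models.  Species and bead metadata
#' are reconstructed from the residue/atom fields against the species
#' registry; unwrapped coordinates are initialised to the wrapped ones.
#'
#' @param path file path.
#' @param registry named list of [MoleculeSpec-class]; defaults to
#'   [allSpecies()].
#' @return a [CGFrame-class] (single model) or [CGTrajectory-class].
#' @export
readGro <- function(path, registry = allSpecies()) {
  lines <- readLines(path)
  regNames <- names(registry)
  names(regNames) <- .groResname(regNames)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    if (!nzchar(trimws(title)) && i == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO atom count at line ", i + 1L)
    atomLines <- lines[(i + 2L):(i + 1L + n)]
    boxLine <- lines[i + 2L + n]
    resid <- as.integer(substr(atomLines, 1, 5))
    resnm <- trimws(substr(atomLines, 6, 10))
    atomnm <- trimws(substr(atomLines, 11, 15))
    xyz <- suppressWarnings(
      cbind(as.numeric(substr(atomLines, 21, 28)),
            as.numeric(substr(atomLines, 29, 36)),
            as.numeric(substr(atomLines, 37, 44))))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1, any))[1]
      stop("malformed GRO coordinate record at line ", i + 1L + bad)
    }
    box <- suppressWarnings(
      as.numeric(strsplit(trimws(boxLine), "\\s+")[[1]]))
    if (length(box) < 3 || anyNA(box[1:2])) {
      stop("missing or malformed box line at line ", i + 2L + n)
    }
    species <- unname(regNames[resnm])
    if (anyNA(species)) {
      stop("unknown residue name(s): ",
           paste(unique(resnm[is.na(species)]), collapse = ", "))
    }
    beadIndex <- as.integer(sub("^B", "", atomnm))
    tm <- if (grepl("t=", title)) {
      as.numeric(sub("^.*t=\\s*", "", title))
    } else 0
    bd <- data.frame(molecule = resid, species = species,
                     beadIndex = beadIndex, stringsAsFactors = FALSE)
    meta <- do.call(rbind, lapply(names(registry), function(s) {
      b <- beads(registry[[s]])
      data.frame(species = s, beadIndex = b$index, type = b$type,
                 role = b$role, charge = b$charge, stringsAsFactors = FALSE)
    }))
    mi <- match(paste(bd$species, bd$beadIndex),
                paste(meta$species, meta$beadIndex))
    if (anyNA(mi)) stop("bead indices do not match the species registry")
    bd$type <- meta$type[mi]
    bd$role <- meta$role[mi]
    bd$charge <- meta$charge[mi]
    bd$leaflet <- NA_character_
    frames[[length(frames) + 1L]] <- new("CGFrame",
      coords = xyz, unwrapped = xyz, box = box[1:2], time = tm,
      beadData = bd)
    i <- i + 3L + n
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  if (length(frames) == 1L) return(frames[[1]])
  framesToTrajectory(frames)
}

#' Assemble a trajectory from a list of frames
#'
#' All frames must share bead metadata and box.
#'
#' @param frames list of [CGFrame-class].
#' @return a [CGTrajectory-class].
#' @export
framesToTrajectory <- function(frames) {
  stopifnot(length(frames) >= 1L)
  n <- nrow(coords(frames[[1]]))
  nf <- length(frames)
  co <- array(NA_real_, c(n, 3, nf))
  un <- array(NA_real_, c(n, 3, nf))
  for (i in seq_len(nf)) {
    co[, , i] <- coords(frames[[i]])
    un[, , i] <- unwrappedCoords(frames[[i]])
  }
  new("CGTrajectory", coords = co, unwrapped = un,
      times = vapply(frames, function(f) f@time, 0),
      box = frames[[1]]@box, beadData = beadData(frames[[1]]))
}
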