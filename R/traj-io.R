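#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, ATOM records from the topology table.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @param resNames optional named vector mapping residue_id to three-letter
#'   residue names (default "ALA").
#' @return the path, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path, resNames = NULL) {
  x <- traj@coords
  top <- traj@topology
  rn <- if (is.null(resNames)) rep("ALA", nrow(top)) else
    unname(resNames[as.character(top$residue_id)])
  rn[is.na(rn)] <- "ALA"
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(x)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      top$index, top$atom_name, rn, top$residue_id,
      x[f, , 1], x[f, , 2], x[f, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Parses ATOM records (fixed columns) from every MODEL block; topology is
#' taken from the first model.
#'
#' @param path PDB file path.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectoryPDB <- function(path) {
  lines <- readLines(path, warn = FALSE)
  isAtom <- startsWith(lines, "ATOM")
  isEnd <- startsWith(lines, "ENDMDL")
  frameOf <- cumsum(isEnd) + 1L
  atomLines <- lines[isAtom]
  atomFrame <- frameOf[isAtom]
  nF <- max(atomFrame)
  first <- atomLines[atomFrame == 1]
  A <- length(first)
  top <- data.frame(
    index = seq_len(A),
    residue_id = as.integer(substr(first, 23, 26)),
    atom_name = trimws(substr(first, 13, 16)),
    stringsAsFactors = FALSE
  )
  xyz <- array(NA_real_, c(nF, A, 3))
  for (f in seq_len(nF)) {
    fl <- atomLines[atomFrame == f]
    if (length(fl) != A) stop("inconsistent atom count in model ", f)
    xyz[f, , 1] <- as.numeric(substr(fl, 31, 38))
    xyz[f, , 2] <- as.numeric(substr(fl, 39, 46))
    xyz[f, , 3] <- as.numeric(substr(fl, 47, 54))
  }
  trajectory(xyz, top)
}

#' Write a trajectory as whitespace XYZ frames plus a topology TSV
#'
#' The XYZ file holds one block per frame (atom count, comment line, then
#' "name x y z" rows); the topology table is written alongside.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param xyzPath output XYZ path.
#' @param topologyPath output TSV path (default: xyzPath + ".topology.tsv").
#' @return the XYZ path, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, xyzPath,
                               topologyPath = paste0(xyzPath, ".topology.tsv")) {
  x <- traj@coords
  top <- traj@topology
  con <- file(xyzPath, "w")
  on.exit(close(con))
  A <- dim(x)[2]
  for (f in seq_len(dim(x)[1])) {
    writeLines(c(as.character(A), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", top$atom_name,
                       x[f, , 1], x[f, , 2], x[f, , 3]), con)
  }
  .writeTSV(top, topologyPath)
  invisible(xyzPath)
}

#' Read XYZ frames plus a topology TSV as a Trajectory
#'
#' @param xyzPath XYZ file path.
#' @param topologyPath topology TSV path.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectoryXYZ <- function(xyzPath,
                              topologyPath = paste0(xyzPath, ".topology.tsv")) {
  top <- .readTSV(topologyPath)
  lines <- readLines(xyzPath, warn = FALSE)
  A <- as.integer(lines[1])
  block <- A + 2L
  nF <- length(lines) %/% block
  xyz <- array(NA_real_, c(nF, A, 3))
  for (f in seq_len(nF)) {
    rows <- lines[((f - 1) * block + 3):((f - 1) * block + 2 + A)]
    parts <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    xyz[f, , ] <- apply(parts[, 2:4, drop = FALSE], 2, as.numeric)
  }
  trajectory(xyz, top)
}

#' Export first-mode porcupine spikes as a pseudo-atom PDB file
#'
#' Writes one model with the mean selection coordinates and a second model
#' with the coordinates displaced along the first PC mode, so molecular
#' viewers can draw per-residue displacement arrows.
#'
#' @param modes result of \code{\link{pcaModes}}.
#' @param meanCoords R x 3 mean coordinates of the selection.
#' @param path output path.
#' @param scale arrow length scale (Angstrom per unit eigenvector).
#' @return the path, invisibly.
#' @export
writePorcupinePDB <- function(modes, meanCoords, path, scale = 10) {
  sp <- modes$spikes
  tip <- meanCoords + scale * as.matrix(sp[, c("dx", "dy", "dz")])
  top <- data.frame(index = seq_len(nrow(sp)), residue_id = sp$residue,
                    atom_name = "CA", stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(2, nrow(sp), 3))
  xyz[1, , ] <- as.matrix(meanCoords)
  xyz[2, , ] <- tip
  writeTrajectoryPDB(trajectory(xyz, top), path)
}
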