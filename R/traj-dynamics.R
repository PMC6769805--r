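#' Construct a Trajectory
#'
#' @param coords F x A x 3 array (Angstrom).
#' @param topology data.frame with columns index, residue_id, atom_name.
#' @return a \linkS4class{Trajectory}.
#' @export
trajectory <- function(coords, topology) {
  new("Trajectory", coords = coords,
      topology = as.data.frame(topology, stringsAsFactors = FALSE))
}

.selectAtoms <- function(traj, selection) {
  top <- traj@topology
  if (identical(selection, "all")) return(top$index)
  idx <- top$index[top$atom_name %in% selection]
  if (!length(idx)) stop("selection matches no atoms")
  idx
}

## torsion angle (degrees, IUPAC sign) from four points
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  wrapAngle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

#' Torsion angle of four atoms over all frames
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param idx integer vector of four atom indices.
#' @return degrees in (-180, 180], one value per frame.
#' @export
torsionSeries <- function(traj, idx) {
  stopifnot(length(idx) == 4)
  x <- traj@coords
  vapply(seq_len(dim(x)[1]), function(f)
    .torsion(x[f, idx[1], ], x[f, idx[2], ], x[f, idx[3], ], x[f, idx[4], ]),
    numeric(1))
}

#' Backbone dihedral time series of a trajectory
#'
#' phi(i) uses C(i-1), N(i), CA(i), C(i); psi(i) uses N(i), CA(i), C(i),
#' N(i+1). The first residue lacks phi and the last lacks psi; residues with
#' missing backbone atoms are flagged NA and the rest computed.
#'
#' @param traj a \linkS4class{Trajectory} whose topology names backbone
#'   atoms N, CA, C.
#' @param stride analyse every stride-th frame.
#' @return a \linkS4class{DihedralSeries}.
#' @export
computeDihedrals <- function(traj, stride = 1) {
  top <- traj@topology
  resIds <- sort(unique(top$residue_id))
  at <- function(r, name) {
    i <- top$index[top$residue_id == r & top$atom_name == name]
    if (length(i) == 1) i else NA_integer_
  }
  frames <- seq(1, dim(traj@coords)[1], by = stride)
  nF <- length(frames)
  sub <- traj@coords[frames, , , drop = FALSE]
  subTraj <- trajectory(sub, top)
  R <- length(resIds)
  phi <- matrix(NA_real_, nF, R)
  psi <- matrix(NA_real_, nF, R)
  for (j in seq_len(R)) {
    r <- resIds[j]
    Ni <- at(r, "N"); CAi <- at(r, "CA"); Ci <- at(r, "C")
    Cprev <- if (j > 1) at(resIds[j - 1], "C") else NA_integer_
    Nnext <- if (j < R) at(resIds[j + 1], "N") else NA_integer_
    if (!anyNA(c(Cprev, Ni, CAi, Ci)))
      phi[, j] <- torsionSeries(subTraj, c(Cprev, Ni, CAi, Ci))
    if (!anyNA(c(Ni, CAi, Ci, Nnext)))
      psi[, j] <- torsionSeries(subTraj, c(Ni, CAi, Ci, Nnext))
  }
  new("DihedralSeries", residues = as.integer(resIds), phi = phi, psi = psi)
}

#' Two-dimensional dihedral histogram
#'
#' 10 x 10 table of normalized frequencies over 36-degree bins from -180.
#' Bins are half-open [lo, hi) with the top edge of the last bin closed, so
#' -180 falls in the first bin and +180 in the last. Frames where either
#' angle is NA are dropped.
#'
#' @param phi,psi angle vectors (degrees) of equal length.
#' @return 10 x 10 matrix of fractions (attributes: "edges", "n" = sample
#'   count). All zeros with n = 0 for empty input.
#' @export
dihedralHistogram <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  ok <- !is.na(phi) & !is.na(psi)
  phi <- phi[ok]; psi <- psi[ok]
  binOf <- function(x) {
    i <- floor((x + 180) / 36) + 1
    i[x >= 180] <- 10L
    i[i < 1L] <- 1L
    i
  }
  H <- matrix(0, 10, 10)
  n <- length(phi)
  if (n > 0) {
    tab <- table(factor(binOf(phi), levels = 1:10),
                 factor(binOf(psi), levels = 1:10))
    H <- unclass(tab) / n
    dimnames(H) <- NULL
  }
  attr(H, "edges") <- seq(-180, 180, by = 36)
  attr(H, "n") <- n
  H
}

#' Chi-squared distance between two dihedral histograms
#'
#' (1/n^2) * sum over all cells of (f1 - f2)^2, with n the number of bins
#' per axis (10).
#'
#' @param f1,f2 histograms from \code{\link{dihedralHistogram}} with
#'   identical binning.
#' @return non-negative scalar.
#' @export
dihedralChi2 <- function(f1, f2) {
  if (!identical(dim(f1), dim(f2)) ||
      !isTRUE(all.equal(attr(f1, "edges"), attr(f2, "edges"))))
    stop("histograms have mismatched binning")
  n <- nrow(f1)
  sum((f1 - f2)^2) / n^2
}

#' Per-residue chi-squared profile between two dihedral series
#'
#' For every residue common to both series, builds the (phi, psi) histogram
#' in each and reports the chi-squared difference. Residues missing from one
#' series, or with no defined angles, are flagged.
#'
#' @param dsA,dsB \linkS4class{DihedralSeries} objects.
#' @param outPath optional TSV output path.
#' @return data.frame with columns residue, chi2, missing.
#' @export
chi2Profile <- function(dsA, dsB, outPath = NULL) {
  common <- intersect(dsA@residues, dsB@residues)
  allRes <- sort(union(dsA@residues, dsB@residues))
  rows <- lapply(allRes, function(r) {
    if (!(r %in% common))
      return(data.frame(residue = r, chi2 = NA_real_, missing = TRUE))
    ia <- match(r, dsA@residues); ib <- match(r, dsB@residues)
    hA <- dihedralHistogram(dsA@phi[, ia], dsA@psi[, ia])
    hB <- dihedralHistogram(dsB@phi[, ib], dsB@psi[, ib])
    if (attr(hA, "n") == 0 || attr(hB, "n") == 0)
      return(data.frame(residue = r, chi2 = NA_real_, missing = TRUE))
    data.frame(residue = r, chi2 = dihedralChi2(hA, hB), missing = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outPath)) .writeTSV(out, outPath)
  out
}

## Kabsch rotation aligning centered X onto centered Y
.kabsch <- function(X, Y) {
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares superpose all frames onto the iteratively refined mean
#'
#' Each frame is rigid-body fitted (rotation + translation, unweighted) on
#' the selection atoms; the mean structure is recomputed and the fit
#' repeated (\code{iterations} mean-superpose rounds). The whole frame is
#' transformed, not just the selection.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection atom name(s) to fit on (default "CA") or "all".
#' @param iterations mean-refinement rounds.
#' @return the superposed \linkS4class{Trajectory}.
#' @export
superposeTrajectory <- function(traj, selection = "CA", iterations = 2) {
  sel <- .selectAtoms(traj, selection)
  x <- traj@coords
  nF <- dim(x)[1]
  ref <- x[1, sel, , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
  for (it in seq_len(iterations)) {
    refC <- scale(ref, scale = FALSE)
    for (f in seq_len(nF)) {
      P <- x[f, sel, ]
      cp <- colMeans(P)
      Rm <- .kabsch(sweep(P, 2, cp), refC)
      moved <- sweep(x[f, , ], 2, cp) %*% Rm
      x[f, , ] <- sweep(moved, 2, attr(refC, "scaled:center"), "+")
    }
    ref <- apply(x[, sel, , drop = FALSE], c(2, 3), mean)
  }
  trajectory(x, traj@topology)
}

#' Per-residue root mean square fluctuation
#'
#' Frames are superposed on the running mean structure (two rounds), then
#' RMSF_i = sqrt(mean over frames of |r_i - mean_i|^2) for each selected
#' atom, reported per residue.
#'
#' @param traj a \linkS4class{Trajectory} (>= 2 frames).
#' @param selection atom selection (default "CA").
#' @param superpose set FALSE if the trajectory is already aligned.
#' @param stride analyse every stride-th frame.
#' @return data.frame with columns residue, rmsf (Angstrom).
#' @export
rmsf <- function(traj, selection = "CA", superpose = TRUE, stride = 1) {
  frames <- seq(1, dim(traj@coords)[1], by = stride)
  if (length(frames) < 2) {
    warning("single frame: RMSF is zero by construction")
    sel <- .selectAtoms(traj, selection)
    return(data.frame(residue = traj@topology$residue_id[sel], rmsf = 0))
  }
  tr <- trajectory(traj@coords[frames, , , drop = FALSE], traj@topology)
  if (superpose) tr <- superposeTrajectory(tr, selection)
  sel <- .selectAtoms(tr, selection)
  x <- tr@coords[, sel, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- (x[, , 1] - matrix(mu[, 1], nrow(x), length(sel), byrow = TRUE))^2 +
          (x[, , 2] - matrix(mu[, 2], nrow(x), length(sel), byrow = TRUE))^2 +
          (x[, , 3] - matrix(mu[, 3], nrow(x), length(sel), byrow = TRUE))^2
  data.frame(residue = tr@topology$residue_id[sel],
             rmsf = sqrt(colMeans(dev2)))
}

#' Principal component modes of coordinate fluctuations
#'
#' Eigendecomposition of the 3R x 3R covariance of the superposed selection
#' coordinates (denominator F so that the eigenvalue sum equals the sum of
#' squared RMSFs). The first mode's per-residue displacement vectors (the
#' porcupine spikes) are exported.
#'
#' @param traj a \linkS4class{Trajectory} (>= 2 frames).
#' @param selection atom selection (default "CA").
#' @param superpose set FALSE if already aligned.
#' @param stride analyse every stride-th frame.
#' @return list with eigenvalues (descending, Angstrom^2), eigenvectors
#'   (3R x 3R, columns orthonormal), spikes (data.frame residue, dx, dy, dz
#'   for mode 1), and residues.
#' @export
pcaModes <- function(traj, selection = "CA", superpose = TRUE, stride = 1) {
  frames <- seq(1, dim(traj@coords)[1], by = stride)
  if (length(frames) < 2) stop("need at least 2 frames")
  tr <- trajectory(traj@coords[frames, , , drop = FALSE], traj@topology)
  if (superpose) tr <- superposeTrajectory(tr, selection)
  sel <- .selectAtoms(tr, selection)
  x <- tr@coords[, sel, , drop = FALSE]
  nF <- dim(x)[1]; A <- length(sel)
  M <- cbind(x[, , 1], x[, , 2], x[, , 3])      # F x 3A, axis-major blocks
  Mc <- scale(M, scale = FALSE)
  C <- crossprod(Mc) / nF
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  v1 <- e$vectors[, 1]
  spikes <- data.frame(residue = tr@topology$residue_id[sel],
                       dx = v1[seq_len(A)], dy = v1[A + seq_len(A)],
                       dz = v1[2 * A + seq_len(A)])
  list(eigenvalues = ev, eigenvectors = e$vectors, spikes = spikes,
       residues = tr@topology$residue_id[sel])
}

#' Dynamic cross-correlation matrix
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>) with dr the
#' displacement from the mean position after superposition. Values of +1/-1
#' mark fully parallel/anti-parallel motion. Atoms with zero variance give
#' NA rows/columns (flagged via attribute "undefined").
#'
#' @param traj a \linkS4class{Trajectory} (>= 2 frames).
#' @param selection atom selection (default "CA").
#' @param superpose set FALSE if already aligned.
#' @param stride analyse every stride-th frame.
#' @param outPath optional TSV output for the matrix.
#' @return R x R correlation matrix with residue ids as dimnames.
#' @export
dccm <- function(traj, selection = "CA", superpose = TRUE, stride = 1,
                 outPath = NULL) {
  frames <- seq(1, dim(traj@coords)[1], by = stride)
  if (length(frames) < 2) stop("need at least 2 frames")
  tr <- trajectory(traj@coords[frames, , , drop = FALSE], traj@topology)
  if (superpose) tr <- superposeTrajectory(tr, selection)
  sel <- .selectAtoms(tr, selection)
  x <- tr@coords[, sel, , drop = FALSE]
  nF <- dim(x)[1]
  D1 <- scale(x[, , 1], scale = FALSE)
  D2 <- scale(x[, , 2], scale = FALSE)
  D3 <- scale(x[, , 3], scale = FALSE)
  raw <- (crossprod(D1) + crossprod(D2) + crossprod(D3)) / nF
  v <- diag(raw)
  zero <- v <= 0
  denom <- sqrt(outer(pmax(v, 0), pmax(v, 0)))
  C <- raw / denom
  C[zero, ] <- NA_real_; C[, zero] <- NA_real_
  diag(C)[!zero] <- 1
  ids <- tr@topology$residue_id[sel]
  dimnames(C) <- list(ids, ids)
  if (any(zero)) attr(C, "undefined") <- ids[zero]
  if (!is.null(outPath))
    .writeTSV(cbind(residue = ids, as.data.frame(C)), outPath)
  C
}

#' Distance between two atoms over all frames
#'
#' Atoms are named "residue:atom", e.g. "76:OD2", or given as integer
#' indices into the topology.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param pair length-2 character or integer vector.
#' @return numeric distance series (Angstrom).
#' @export
atomDistanceSeries <- function(traj, pair) {
  stopifnot(length(pair) == 2)
  top <- traj@topology
  resolve <- function(a) {
    if (is.numeric(a)) return(as.integer(a))
    parts <- strsplit(a, ":", fixed = TRUE)[[1]]
    i <- top$index[top$residue_id == as.integer(parts[1]) &
                   top$atom_name == parts[2]]
    if (length(i) != 1) stop("atom not found in topology: ", a)
    i
  }
  i <- resolve(pair[[1]]); j <- resolve(pair[[2]])
  x <- traj@coords
  sqrt((x[, i, 1] - x[, j, 1])^2 + (x[, i, 2] - x[, j, 2])^2 +
       (x[, i, 3] - x[, j, 3])^2)
}

#' Segment a distance distribution into subensembles
#'
#' Kernel-density estimate (Gaussian kernel, Silverman's rule) of the
#' distance distribution; modes are local maxima exceeding
#' \code{modeThreshold} of the global maximum, and boundaries are placed at
#' the density minima between consecutive modes. Frames are labelled "a",
#' "b", ... by increasing distance.
#'
#' @param distances numeric sample (>= 100 values).
#' @param modeThreshold fraction of the global density maximum a local
#'   maximum must exceed to count as a mode.
#' @param bw kernel bandwidth (default Silverman's rule of thumb, "nrd0").
#' @return a \linkS4class{SubensembleLabels}.
#' @export
segmentSubensembles <- function(distances, modeThreshold = 0.05, bw = "nrd0") {
  if (!length(distances)) stop("empty distance sample")
  if (length(distances) < 100) stop("need at least 100 samples")
  den <- stats::density(distances, bw = bw)
  y <- den$y
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  modes <- which(isMax & y >= modeThreshold * max(y))
  if (!length(modes)) modes <- which.max(y)
  bounds <- numeric(0)
  if (length(modes) > 1) {
    for (k in seq_len(length(modes) - 1)) {
      span <- modes[k]:modes[k + 1]
      bounds <- c(bounds, den$x[span[which.min(y[span])]])
    }
  }
  K <- length(modes)
  lab <- factor(letters[findInterval(distances, bounds) + 1],
                levels = letters[seq_len(K)])
  new("SubensembleLabels", labels = lab, boundaries = bounds)
}

#' Subensemble-conditioned chi-squared per residue
#'
#' For each residue the dihedral histogram is recomputed within every
#' subensemble; the chi-squared difference is evaluated for every unordered
#' pair of subensembles and the maximum reported (with the full pair table
#' as an attribute). Pairs touching a subensemble with fewer than
#' \code{minFrames} frames are flagged low-confidence.
#'
#' @param ds a \linkS4class{DihedralSeries}.
#' @param labels a \linkS4class{SubensembleLabels} (or factor) with one
#'   label per frame and >= 2 subensembles.
#' @param minFrames minimum frames per subensemble for full confidence.
#' @param outPath optional TSV output path.
#' @return data.frame with columns residue, max_chi2, max_pair,
#'   low_confidence; attribute "pairs" holds the per-pair table.
#' @export
conditionalChi2 <- function(ds, labels, minFrames = 50, outPath = NULL) {
  lab <- if (is(labels, "SubensembleLabels")) labels@labels else as.factor(labels)
  if (length(lab) != nFrames(ds))
    stop("labels length must equal frame count")
  lev <- levels(droplevels(lab))
  if (length(lev) < 2) stop("need at least 2 subensembles")
  counts <- table(lab)[lev]
  pairs <- utils::combn(lev, 2)
  pairRows <- list()
  rows <- lapply(seq_along(ds@residues), function(j) {
    hists <- lapply(lev, function(l)
      dihedralHistogram(ds@phi[lab == l, j], ds@psi[lab == l, j]))
    names(hists) <- lev
    chi <- apply(pairs, 2, function(pr) {
      if (attr(hists[[pr[1]]], "n") == 0 || attr(hists[[pr[2]]], "n") == 0)
        return(NA_real_)
      dihedralChi2(hists[[pr[1]]], hists[[pr[2]]])
    })
    lowconf <- apply(pairs, 2, function(pr)
      any(counts[pr] < minFrames))
    pairRows[[length(pairRows) + 1]] <<- data.frame(
      residue = ds@residues[j],
      state1 = pairs[1, ], state2 = pairs[2, ],
      chi2 = chi, low_confidence = lowconf
    )
    best <- if (all(is.na(chi))) NA_integer_ else which.max(chi)
    data.frame(
      residue = ds@residues[j],
      max_chi2 = if (is.na(best)) NA_real_ else chi[best],
      max_pair = if (is.na(best)) NA_character_ else
        paste(pairs[, best], collapse = "-"),
      low_confidence = if (is.na(best)) TRUE else lowconf[best]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- do.call(rbind, pairRows)
  if (!is.null(outPath)) .writeTSV(out, outPath)
  out
}
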