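#' Apparent amide chemical-shift difference
#'
#' Combines the 1H and 15N axes of an HSQC displacement with the standard
#' 1/5 nitrogen weight: sqrt(dH^2 + (dN/5)^2).
#'
#' @param dH,dN shift differences, ppm (vectorised).
#' @return apparent shift difference, ppm (>= 0).
#' @export
deltaApp <- function(dH, dN) {
  stopifnot(all(is.finite(dH)), all(is.finite(dN)))
  sqrt(dH^2 + (dN / 5)^2)
}

#' Per-residue shift differences between two peak lists
#'
#' For every residue shared by both lists, dH and dN differences (b minus a)
#' and the apparent shift difference; residues present in only one list are
#' returned with \code{missing = TRUE} and NA differences.
#'
#' @param a,b \linkS4class{PeakList} objects.
#' @return data.frame with columns residue, dH, dN, delta_app, missing.
#' @export
comparePeakLists <- function(a, b) {
  stopifnot(is(a, "PeakList"), is(b, "PeakList"))
  shared <- intersect(a@peaks$residue_id, b@peaks$residue_id)
  if (!length(shared)) stop("no shared residues between peak lists")
  allRes <- sort(union(a@peaks$residue_id, b@peaks$residue_id))
  ia <- match(allRes, a@peaks$residue_id)
  ib <- match(allRes, b@peaks$residue_id)
  dH <- b@peaks$dH[ib] - a@peaks$dH[ia]
  dN <- b@peaks$dN[ib] - a@peaks$dN[ia]
  miss <- is.na(ia) | is.na(ib)
  data.frame(
    residue = allRes, dH = dH, dN = dN,
    delta_app = ifelse(miss, NA_real_, sqrt(dH^2 + (dN / 5)^2)),
    missing = miss
  )
}

#' Assemble the 2R x P chemical-shift matrix of a pressure series
#'
#' Rows are residue-major (the H row then the N row for each traceable
#' residue); nitrogen rows are multiplied by \code{nScale} so that Euclidean
#' distances in row space match the apparent-shift weighting. Columns are the
#' spectra at each pressure.
#'
#' @param series a \linkS4class{PressureSeries} with >= 3 pressure points.
#' @param nScale nitrogen scale factor (default 1/5).
#' @return a \linkS4class{ShiftMatrix}.
#' @export
assembleShiftMatrix <- function(series, nScale = 1 / 5) {
  stopifnot(is(series, "PressureSeries"))
  p <- pressures(series)
  if (length(p) < 3) stop("need at least 3 pressure points")
  res <- traceableResidues(series)
  if (!length(res)) stop("traceable set is empty")
  P <- length(p)
  X <- matrix(0, 2 * length(res), P)
  for (j in seq_len(P)) {
    pk <- series@peakLists[[j]]@peaks
    i <- match(res, pk$residue_id)
    X[seq(1, by = 2, length.out = length(res)), j] <- pk$dH[i]
    X[seq(2, by = 2, length.out = length(res)), j] <- pk$dN[i] * nScale
  }
  new("ShiftMatrix",
      x = X, residues = rep(res, each = 2),
      axis = rep(c("H", "N"), length(res)),
      pressures = p, nScale = nScale)
}

#' SVD of a centered shift matrix
#'
#' Columns are centered by subtracting the first-pressure column (default;
#' the lowest-pressure spectrum becomes the origin of the PC plane) or the
#' column mean, then decomposed by SVD. Scores are the singular-value
#' weighted right singular vectors: row p of the score table places pressure
#' point p in PC space. PC1 is oriented so the last pressure point has a
#' non-negative PC1 score.
#'
#' @param X a \linkS4class{ShiftMatrix}.
#' @param centering "first" or "mean".
#' @param tol singular values below \code{tol * max(d)} count as zero.
#' @return a \linkS4class{ShiftDecomposition} (directions and patterns unset).
#' @export
svdShiftMatrix <- function(X, centering = c("first", "mean"), tol = 1e-10) {
  stopifnot(is(X, "ShiftMatrix"))
  centering <- match.arg(centering)
  ref <- if (centering == "first") X@x[, 1] else rowMeans(X@x)
  Xc <- X@x - ref
  sv <- svd(Xc)
  d <- sv$d
  nAbove <- if (max(d) == 0) {
    warning("degenerate matrix: all columns identical")
    0L
  } else sum(d > tol * max(d))
  ## orient PC1 (and PC2) so the last pressure point scores non-negative on PC1
  scores <- sv$v %*% diag(d, length(d))
  flip <- rep(1, length(d))
  if (nAbove > 0 && scores[nrow(scores), 1] < 0) flip[1] <- -1
  u <- sweep(sv$u, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  ve <- if (sum(d^2) > 0) d^2 / sum(d^2) else rep(0, length(d))
  new("ShiftDecomposition",
      d = d, u = u, scores = scores,
      centering = centering, centerRef = ref, nAboveTol = as.integer(nAbove),
      vI = numeric(0), vII = numeric(0),
      patternI = data.frame(), patternII = data.frame(),
      varianceExplained = ve,
      matrixInfo = list(residues = X@residues, axis = X@axis,
                        pressures = X@pressures, nScale = X@nScale))
}

#' Identify compression and transition directions in the PC plane
#'
#' The compression direction v_i is the unit secant from the first to the
#' second pressure point in the (PC1, PC2) plane — the initial spectral
#' change, attributed to within-state mechanical compression. The transition
#' direction v_ii is v_i rotated +90 degrees, with its sign chosen so the
#' projection of the total change (last minus first score) onto v_ii is
#' non-negative.
#'
#' @param decomp a \linkS4class{ShiftDecomposition}.
#' @param nSecant number of leading points for the initial direction; the
#'   default 2 uses the plain first-step secant, larger values fit a
#'   least-squares line through the first \code{nSecant} scores.
#' @return the decomposition with \code{vI}, \code{vII} filled in.
#' @export
identifyDirections <- function(decomp, nSecant = 2) {
  stopifnot(is(decomp, "ShiftDecomposition"))
  s <- decomp@scores[, 1:2, drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 pressure points")
  if (nSecant <= 2) {
    v <- s[2, ] - s[1, ]
  } else {
    idx <- seq_len(min(nSecant, nrow(s)))
    pc1 <- s[idx, 1] - s[1, 1]
    pc2 <- s[idx, 2] - s[1, 2]
    ## direction of the least-squares line through the leading scores
    M <- cbind(pc1, pc2)
    v <- svd(M)$v[, 1]
    if (sum(v * (s[idx[length(idx)], ] - s[1, ])) < 0) v <- -v
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-14) stop("first two pressure scores coincide")
  vI <- v / nv
  vII <- c(-vI[2], vI[1])
  if (sum((s[nrow(s), ] - s[1, ]) * vII) < 0) vII <- -vII
  decomp@vI <- vI
  decomp@vII <- vII
  decomp
}

#' Back-project a PC-plane direction into a per-residue shift pattern
#'
#' The residue-space loading U[, 1:2] %*% v is scaled by the range of the
#' score projections along v (max minus min), then split into H and N rows.
#' Nitrogen values are reported both in ppm (assembly scaling undone) and
#' N-scaled as conventionally plotted; the apparent shift difference uses the
#' ppm values.
#'
#' @param decomp a \linkS4class{ShiftDecomposition} (after
#'   \code{identifyDirections} if using its stored directions).
#' @param v unit direction vector in the PC1-PC2 plane.
#' @return data.frame with columns residue, dH, dN, dN_scaled, delta_app.
#' @export
projectPattern <- function(decomp, v) {
  stopifnot(is(decomp, "ShiftDecomposition"))
  if (length(decomp@d) < 2 || ncol(decomp@u) < 2)
    stop("fewer than 2 PCs available")
  v <- v / sqrt(sum(v^2))
  w <- decomp@u[, 1:2, drop = FALSE] %*% v
  proj <- decomp@scores[, 1:2, drop = FALSE] %*% v
  w <- as.numeric(w) * (max(proj) - min(proj))
  info <- decomp@matrixInfo
  hRows <- info$axis == "H"
  res <- info$residues[hRows]
  dH <- w[hRows]
  dNs <- w[!hRows]                 # still carries the assembly N scale
  dN <- dNs / info$nScale          # back to ppm
  data.frame(residue = res, dH = dH, dN = dN, dN_scaled = dNs,
             delta_app = sqrt(dH^2 + (dN / 5)^2))
}

#' Decompose a pressure series into compression and transition patterns
#'
#' Runs matrix assembly, centered SVD, direction identification and
#' back-projection in sequence; optionally writes the per-residue patterns,
#' scores and singular values as TSV files.
#'
#' @param series a \linkS4class{PressureSeries}.
#' @param nScale nitrogen scale at assembly.
#' @param centering "first" or "mean".
#' @param nSecant see \code{\link{identifyDirections}}.
#' @param outDir optional output directory for scores.tsv,
#'   singular_values.tsv, pattern_i.tsv, pattern_ii.tsv.
#' @return a complete \linkS4class{ShiftDecomposition}.
#' @export
decomposePressureSeries <- function(series, nScale = 1 / 5,
                                    centering = "first", nSecant = 2,
                                    outDir = NULL) {
  X <- assembleShiftMatrix(series, nScale = nScale)
  dec <- svdShiftMatrix(X, centering = centering)
  dec <- identifyDirections(dec, nSecant = nSecant)
  dec@patternI <- projectPattern(dec, dec@vI)
  dec@patternII <- projectPattern(dec, dec@vII)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    scores <- as.data.frame(dec@scores)
    names(scores) <- paste0("PC", seq_len(ncol(scores)))
    .writeTSV(cbind(pressure = X@pressures, scores),
              file.path(outDir, "scores.tsv"))
    .writeTSV(data.frame(pc = seq_along(dec@d), singular_value = dec@d,
                         variance_fraction = dec@varianceExplained),
              file.path(outDir, "singular_values.tsv"))
    .writeTSV(dec@patternI, file.path(outDir, "pattern_i.tsv"))
    .writeTSV(dec@patternII, file.path(outDir, "pattern_ii.tsv"))
  }
  dec
}
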