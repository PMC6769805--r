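#' Two-state pressure-response model for amide chemical shifts
#'
#' Each residue responds to pressure through (i) a linear compression term
#' (slopes in ppm/MPa) and (ii) a two-state population shift whose
#' excited-state fraction follows f_E(p) = 1/(1 + exp((dG0 + p*dV)/(R*T))).
#' With dV < 0, pressure stabilises the excited state and f_E rises with p.
#'
#' @slot residues integer residue ids (1-based).
#' @slot residueNames one-letter codes (may be NA).
#' @slot slopeH,slopeN per-residue compression slopes, ppm/MPa.
#' @slot ampH,ampN per-residue transition amplitudes, ppm.
#' @slot deltaH0,deltaN0 reference shifts at zero pressure, ppm.
#' @slot dG0 free-energy difference (excited minus ground) at 0 MPa, J/mol.
#' @slot dV volume difference, mL/mol (1 MPa*mL/mol = 1 J/mol).
#' @slot temperature kelvin.
#' @export
setClass("TwoStateShiftModel",
  representation(
    residues = "integer", residueNames = "character",
    slopeH = "numeric", slopeN = "numeric",
    ampH = "numeric", ampN = "numeric",
    deltaH0 = "numeric", deltaN0 = "numeric",
    dG0 = "numeric", dV = "numeric", temperature = "numeric"
  )
)

setValidity("TwoStateShiftModel", function(object) {
  n <- length(object@residues)
  lens <- vapply(
    list(object@residueNames, object@slopeH, object@slopeN, object@ampH,
         object@ampN, object@deltaH0, object@deltaN0),
    length, integer(1)
  )
  if (any(lens != n)) return("per-residue slots must share one length")
  if (anyDuplicated(object@residues)) return("duplicate residue ids")
  if (any(object@residues < 1L)) return("residue ids must be >= 1")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' Discrete latent-state Markov chain
#'
#' Small hidden-state chain driving state-conditional observables
#' (dihedral distributions, side-chain distances). Emulates discrete
#' conformational subensembles.
#'
#' @slot transition K x K row-stochastic transition matrix.
#' @slot initial initial state distribution, length K.
#' @export
setClass("LatentStateChain",
  representation(transition = "matrix", initial = "numeric")
)

setValidity("LatentStateChain", function(object) {
  P <- object@transition
  if (nrow(P) != ncol(P)) return("transition matrix must be square")
  if (length(object@initial) != nrow(P)) return("initial length != K")
  if (any(P < 0) || any(P > 1)) return("transition probabilities outside [0,1]")
  if (any(abs(rowSums(P) - 1) > 1e-12)) return("rows must sum to 1 (tol 1e-12)")
  if (abs(sum(object@initial) - 1) > 1e-12) return("initial must sum to 1")
  TRUE
})

#' State-conditional von Mises dihedral model
#'
#' Per residue and latent state, a von Mises pair for (phi, psi). Residues
#' flagged coupled draw from the state-indexed parameters; uncoupled residues
#' use state-independent parameters (rows identical across states).
#'
#' @slot residues integer residue ids.
#' @slot coupled logical per residue.
#' @slot muPhi,muPsi R x K circular means, degrees.
#' @slot kappaPhi,kappaPsi R x K von Mises concentrations (> 0).
#' @export
setClass("DihedralModel",
  representation(
    residues = "integer", coupled = "logical",
    muPhi = "matrix", muPsi = "matrix",
    kappaPhi = "matrix", kappaPsi = "matrix"
  )
)

setValidity("DihedralModel", function(object) {
  R <- length(object@residues)
  mats <- list(object@muPhi, object@muPsi, object@kappaPhi, object@kappaPsi)
  if (any(vapply(mats, nrow, 1L) != R)) return("matrices need one row per residue")
  K <- ncol(object@muPhi)
  if (any(vapply(mats, ncol, 1L) != K)) return("matrices need one column per state")
  if (length(object@coupled) != R) return("coupled flag length != residues")
  if (any(object@kappaPhi <= 0) || any(object@kappaPsi <= 0))
    return("concentrations must be positive")
  for (m in mats) {
    bad <- !object@coupled & (apply(m, 1, function(r) max(r) - min(r)) > 1e-12)
    if (any(bad)) return("uncoupled residues must have state-invariant parameters")
  }
  TRUE
})

#' Latent-mode trajectory model
#'
#' Frames are mean coordinates plus Gaussian-amplitude collective modes plus
#' isotropic noise; a low-rank stand-in for collective protein motion
#' (no claim of physical realism).
#'
#' @slot meanCoords A x 3 matrix, Angstrom.
#' @slot modes A x 3 x M array of unit-norm, mutually orthogonal mode vectors.
#' @slot amplitudeSd per-mode amplitude standard deviations, Angstrom.
#' @slot noiseSd isotropic noise sd, Angstrom.
#' @export
setClass("ModeTrajectoryModel",
  representation(
    meanCoords = "matrix", modes = "array",
    amplitudeSd = "numeric", noiseSd = "numeric"
  )
)

setValidity("ModeTrajectoryModel", function(object) {
  A <- nrow(object@meanCoords)
  dm <- dim(object@modes)
  if (length(dm) != 3 || dm[1] != A || dm[2] != 3)
    return("modes must be an A x 3 x M array")
  M <- dm[3]
  if (length(object@amplitudeSd) != M) return("one amplitude sd per mode")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  V <- matrix(object@modes, nrow = A * 3, ncol = M)
  G <- crossprod(V)
  if (max(abs(G - diag(M))) > 1e-8)
    return("mode vectors must be orthonormal")
  TRUE
})

#' A residue-assigned HSQC peak list at one condition
#'
#' @slot label condition label (e.g. "WT_AP").
#' @slot pressure MPa.
#' @slot peaks data.frame with columns residue_id, residue_name, dH, dN,
#'   height (height may be NA).
#' @export
setClass("PeakList",
  representation(label = "character", pressure = "numeric", peaks = "data.frame")
)

setValidity("PeakList", function(object) {
  pk <- object@peaks
  need <- c("residue_id", "residue_name", "dH", "dN", "height")
  if (!all(need %in% names(pk))) return("peaks must have columns residue_id, residue_name, dH, dN, height")
  if (nrow(pk) && anyDuplicated(pk$residue_id)) return("duplicate residue ids in peak list")
  if (nrow(pk) && any(pk$residue_id < 1L)) return("residue ids must be >= 1")
  if (nrow(pk) && (!all(is.finite(pk$dH)) || !all(is.finite(pk$dN))))
    return("chemical shifts must be finite")
  TRUE
})

#' An ordered series of peak lists across pressure
#'
#' @slot peakLists list of \linkS4class{PeakList} ordered by strictly
#'   increasing pressure.
#' @export
setClass("PressureSeries", representation(peakLists = "list"))

setValidity("PressureSeries", function(object) {
  if (!length(object@peakLists)) return("empty series")
  if (!all(vapply(object@peakLists, is, logical(1), "PeakList")))
    return("all elements must be PeakList")
  p <- vapply(object@peakLists, function(x) x@pressure, numeric(1))
  if (any(diff(p) <= 0)) return("pressures must be strictly increasing")
  TRUE
})

#' Assembled 2R x P chemical-shift matrix
#'
#' Rows are residue-major (H row then N row per residue), nitrogen rows
#' multiplied by \code{nScale} so the Euclidean row metric matches the
#' apparent-shift weighting; columns are pressure points.
#'
#' @slot x numeric matrix, 2R x P.
#' @slot residues integer ids in row-major order.
#' @slot axis "H"/"N" per row.
#' @slot pressures MPa per column.
#' @slot nScale nitrogen scale applied at assembly (default 1/5).
#' @export
setClass("ShiftMatrix",
  representation(
    x = "matrix", residues = "integer", axis = "character",
    pressures = "numeric", nScale = "numeric"
  )
)

setValidity("ShiftMatrix", function(object) {
  if (nrow(object@x) != 2 * length(unique(object@residues)))
    return("matrix must have exactly 2 rows per residue")
  if (length(object@residues) != nrow(object@x)) return("row metadata length mismatch")
  if (length(object@axis) != nrow(object@x)) return("axis metadata length mismatch")
  if (ncol(object@x) != length(object@pressures)) return("column count != pressures")
  TRUE
})

#' SVD decomposition of a pressure series into compression/transition parts
#'
#' @slot d singular values, descending.
#' @slot u left singular vectors (residue space, 2R rows).
#' @slot scores P x K matrix: pressure points in PC coordinates
#'   (singular-value weighted right singular vectors).
#' @slot centering "first" or "mean", with the reference column kept.
#' @slot centerRef reference column subtracted before the SVD.
#' @slot nAboveTol number of singular values above tolerance.
#' @slot vI,vII unit direction vectors in the PC1-PC2 plane for
#'   (i) mechanical compression and (ii) thermodynamic transition.
#' @slot patternI,patternII per-residue shift-change patterns (data.frame
#'   with residue, dH, dN, dN_scaled, delta_app).
#' @slot varianceExplained fraction of variance per PC.
#' @slot matrixInfo the source \linkS4class{ShiftMatrix} metadata (list).
#' @export
setClass("ShiftDecomposition",
  representation(
    d = "numeric", u = "matrix", scores = "matrix",
    centering = "character", centerRef = "numeric", nAboveTol = "integer",
    vI = "numeric", vII = "numeric",
    patternI = "data.frame", patternII = "data.frame",
    varianceExplained = "numeric", matrixInfo = "list"
  )
)

#' Coordinate trajectory with topology
#'
#' @slot coords F x A x 3 array, Angstrom.
#' @slot topology data.frame with columns index, residue_id, atom_name.
#' @export
setClass("Trajectory", representation(coords = "array", topology = "data.frame"))

setValidity("Trajectory", function(object) {
  dm <- dim(object@coords)
  if (length(dm) != 3 || dm[3] != 3) return("coords must be F x A x 3")
  top <- object@topology
  need <- c("index", "residue_id", "atom_name")
  if (!all(need %in% names(top))) return("topology needs index, residue_id, atom_name")
  if (nrow(top) != dm[2]) return("topology rows != atom count")
  if (any(top$index != seq_len(dm[2]))) return("topology index must be 1..A")
  TRUE
})

#' Per-residue backbone dihedral time series
#'
#' @slot residues integer ids.
#' @slot phi,psi F x R matrices, degrees in (-180, 180]; NA where undefined
#'   (phi of the first residue, psi of the last, missing atoms).
#' @export
setClass("DihedralSeries",
  representation(residues = "integer", phi = "matrix", psi = "matrix")
)

setValidity("DihedralSeries", function(object) {
  R <- length(object@residues)
  if (ncol(object@phi) != R || ncol(object@psi) != R)
    return("phi/psi need one column per residue")
  if (nrow(object@phi) != nrow(object@psi)) return("frame counts differ")
  TRUE
})

#' Per-frame subensemble labels from distance segmentation
#'
#' @slot labels factor with levels "a", "b", ... ordered by increasing distance.
#' @slot boundaries distances (Angstrom) separating consecutive subensembles.
#' @export
setClass("SubensembleLabels",
  representation(labels = "factor", boundaries = "numeric")
)

## ---- show methods -----------------------------------------------------------

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList '%s' at %.1f MPa: %d peaks\n",
              object@label, object@pressure, nrow(object@peaks)))
})

setMethod("show", "PressureSeries", function(object) {
  p <- pressures(object)
  cat(sprintf("PressureSeries: %d pressure points (%.1f-%.1f MPa), %d traceable residues\n",
              length(p), min(p), max(p), length(traceableResidues(object))))
})

setMethod("show", "ShiftMatrix", function(object) {
  cat(sprintf("ShiftMatrix: %d x %d (N rows scaled by %.3g)\n",
              nrow(object@x), ncol(object@x), object@nScale))
})

setMethod("show", "ShiftDecomposition", function(object) {
  cat(sprintf("ShiftDecomposition: %d singular values above tolerance; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              object@nAboveTol, 100 * object@varianceExplained[1],
              100 * object@varianceExplained[2]))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %d atoms, %d residues\n",
              dim(object@coords)[1], dim(object@coords)[2],
              length(unique(object@topology$residue_id))))
})

setMethod("show", "DihedralSeries", function(object) {
  cat(sprintf("DihedralSeries: %d residues, %d frames\n",
              length(object@residues), nrow(object@phi)))
})

setMethod("show", "SubensembleLabels", function(object) {
  tab <- table(object@labels)
  cat(sprintf("SubensembleLabels: %d subensembles (%s)\n", nlevels(object@labels),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "TwoStateShiftModel", function(object) {
  cat(sprintf("TwoStateShiftModel: %d residues, dG0 = %.0f J/mol, dV = %.0f mL/mol, T = %.0f K\n",
              length(object@residues), object@dG0, object@dV, object@temperature))
})
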