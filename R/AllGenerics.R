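#' Pressures of a series or peak list
#' @param x a \linkS4class{PressureSeries} or \linkS4class{PeakList}.
#' @return numeric vector of pressures (MPa).
#' @export
setGeneric("pressures", function(x) standardGeneric("pressures"))

#' @rdname pressures
setMethod("pressures", "PressureSeries", function(x)
  vapply(x@peakLists, function(pl) pl@pressure, numeric(1)))

#' @rdname pressures
setMethod("pressures", "PeakList", function(x) x@pressure)

#' @rdname pressures
setMethod("pressures", "ShiftMatrix", function(x) x@pressures)

#' Peak table of a PeakList
#' @param x a \linkS4class{PeakList}.
#' @return data.frame of peaks.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname peaks
setMethod("peaks", "PeakList", function(x) x@peaks)

#' Residues present at every pressure point
#'
#' The traceable set: the intersection of residue ids across all lists in the
#' series. Only these residues enter the shift matrix.
#'
#' @param x a \linkS4class{PressureSeries}.
#' @return sorted integer vector of residue ids.
#' @export
setGeneric("traceableResidues", function(x) standardGeneric("traceableResidues"))

#' @rdname traceableResidues
setMethod("traceableResidues", "PressureSeries", function(x) {
  ids <- lapply(x@peakLists, function(pl) pl@peaks$residue_id)
  sort(Reduce(intersect, ids))
})

#' Peak lists of a series
#' @param x a \linkS4class{PressureSeries}.
#' @return list of \linkS4class{PeakList}.
#' @export
setGeneric("peakLists", function(x) standardGeneric("peakLists"))

#' @rdname peakLists
setMethod("peakLists", "PressureSeries", function(x) x@peakLists)

#' Singular values of a decomposition
#' @param x a \linkS4class{ShiftDecomposition}.
#' @return numeric vector, descending.
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname singularValues
setMethod("singularValues", "ShiftDecomposition", function(x) x@d)

#' PC-space score table of a decomposition
#' @param x a \linkS4class{ShiftDecomposition}.
#' @return P x K matrix; row p is pressure point p in PC coordinates.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
setMethod("scoreTable", "ShiftDecomposition", function(x) x@scores)

#' Trajectory coordinates
#' @param x a \linkS4class{Trajectory}.
#' @return F x A x 3 array (Angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
setMethod("coords", "Trajectory", function(x) x@coords)

#' Trajectory topology table
#' @param x a \linkS4class{Trajectory}.
#' @return data.frame with columns index, residue_id, atom_name.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname topology
setMethod("topology", "Trajectory", function(x) x@topology)

#' Number of frames
#' @param x a \linkS4class{Trajectory} or \linkS4class{DihedralSeries}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname nFrames
setMethod("nFrames", "DihedralSeries", function(x) nrow(x@phi))

#' Subensemble label vector
#' @param x a \linkS4class{SubensembleLabels}.
#' @return factor of per-frame labels.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname stateLabels
setMethod("stateLabels", "SubensembleLabels", function(x) x@labels)
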