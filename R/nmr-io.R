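#' Construct a PeakList
#'
#' @param residue_id integer ids (unique, >= 1).
#' @param dH,dN chemical shifts (ppm).
#' @param residue_name optional one-letter codes.
#' @param height optional intensities.
#' @param label condition label.
#' @param pressure MPa.
#' @return a \linkS4class{PeakList}.
#' @export
peakList <- function(residue_id, dH, dN, residue_name = NA_character_,
                     height = NA_real_, label = "", pressure = NA_real_) {
  n <- length(residue_id)
  new("PeakList", label = label, pressure = as.numeric(pressure),
      peaks = data.frame(
        residue_id = as.integer(residue_id),
        residue_name = rep_len(as.character(residue_name), n),
        dH = as.numeric(dH), dN = as.numeric(dN),
        height = rep_len(as.numeric(height), n)
      ))
}

#' Construct a PressureSeries from peak lists
#'
#' @param ... \linkS4class{PeakList} objects or a single list of them,
#'   ordered by strictly increasing pressure.
#' @return a \linkS4class{PressureSeries}.
#' @export
pressureSeries <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is(lists[[1]], "PeakList"))
    lists <- lists[[1]]
  new("PressureSeries", peakLists = lists)
}

## "K41N-H" -> list(name = "K", id = 41); also accepts bare "41N-H"
.parseAssignment <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z]?)([0-9]+)N-H$", s))[[1]]
  if (!length(m)) return(NULL)
  list(name = if (nzchar(m[2])) toupper(m[2]) else NA_character_,
       id = as.integer(m[3]))
}

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited columns: assignment, w1 (15N ppm), w2 (1H ppm),
#' optional height. A header line starting with "Assignment" is skipped.
#' Assignments are parsed as residue letter + number + amide atoms
#' (e.g. "K41N-H").
#'
#' @param path file path.
#' @param label condition label to attach.
#' @param pressure pressure (MPa) to attach.
#' @return a \linkS4class{PeakList}.
#' @export
readPeakList <- function(path, label = "", pressure = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*(Assignment|#)", lines))
  if (!length(keep)) {
    warning("empty peak list: ", path)
    return(peakList(integer(0), numeric(0), numeric(0),
                    label = label, pressure = pressure))
  }
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3)
      stop("line ", i, ": expected at least 3 columns in ", path)
    a <- .parseAssignment(f[1])
    if (is.null(a))
      stop("line ", i, ": unparseable assignment '", f[1], "' in ", path)
    data.frame(residue_id = a$id, residue_name = a$name,
               dN = as.numeric(f[2]), dH = as.numeric(f[3]),
               height = if (length(f) >= 4) as.numeric(f[4]) else NA_real_)
  })
  pk <- do.call(rbind, rows)
  dup <- pk$residue_id[duplicated(pk$residue_id)]
  if (length(dup))
    stop("duplicate residue(s) ", paste(unique(dup), collapse = ", "),
         " in ", path)
  peakList(pk$residue_id, pk$dH, pk$dN, pk$residue_name, pk$height,
           label = label, pressure = pressure)
}

#' Write a Sparky-style peak list
#'
#' Shifts are written with 17 significant digits so that
#' \code{readPeakList(writePeakList(x))} reproduces \code{x} exactly.
#'
#' @param x a \linkS4class{PeakList}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePeakList <- function(x, path) {
  stopifnot(is(x, "PeakList"))
  pk <- x@peaks
  hasHeight <- nrow(pk) > 0 && any(!is.na(pk$height))
  header <- if (hasHeight) "Assignment w1 w2 Height" else "Assignment w1 w2"
  nm <- ifelse(is.na(pk$residue_name), "", pk$residue_name)
  lines <- sprintf("%s%dN-H %.17g %.17g", nm, pk$residue_id, pk$dN, pk$dH)
  if (hasHeight) lines <- paste(lines, sprintf("%.17g", pk$height))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Track peaks across a pressure series
#'
#' Starting from a fully assigned reference list, each peak at pressure k+1
#' inherits the assignment of the nearest tracked peak at pressure k under
#' the apparent-shift metric (H and N/5 weighting), provided the distance is
#' at most \code{maxStep}. Residues with no candidate within \code{maxStep}
#' are dropped from the traceable set. Ambiguous matches (two candidates
#' within \code{maxStep} of the same tracked peak and within 10\% distance of
#' each other, or two tracked peaks claiming the same candidate) raise an
#' error naming the residues involved.
#'
#' @param lists peak lists ordered by strictly increasing pressure; the
#'   assignments of all but the reference are ignored (positions only). Each
#'   element is a \linkS4class{PeakList} or a data.frame with columns dH, dN
#'   (optional height).
#' @param reference fully assigned \linkS4class{PeakList} for the first
#'   pressure point.
#' @param maxStep maximum per-step displacement, ppm (apparent-shift metric).
#' @param pressures pressures for the lists; defaults to those attached.
#' @return a \linkS4class{PressureSeries} of assigned lists.
#' @export
trackPeaks <- function(lists, reference, maxStep = 0.05, pressures = NULL) {
  stopifnot(is(reference, "PeakList"))
  getTab <- function(x) if (is(x, "PeakList")) x@peaks else as.data.frame(x)
  if (is.null(pressures))
    pressures <- vapply(lists, function(x)
      if (is(x, "PeakList")) x@pressure else NA_real_, numeric(1))
  if (anyNA(pressures) || any(diff(pressures) <= 0))
    stop("lists must carry strictly increasing pressures")

  cur <- reference@peaks[order(reference@peaks$residue_id), ]
  out <- vector("list", length(lists))
  out[[1]] <- peakList(cur$residue_id, cur$dH, cur$dN, cur$residue_name,
                       getTab(lists[[1]])$height[
                         .matchRows(cur, getTab(lists[[1]]))],
                       label = reference@label, pressure = pressures[1])

  for (k in seq_along(lists)[-1]) {
    cand <- getTab(lists[[k]])
    matched <- integer(nrow(cur))      # candidate index per tracked residue, 0 = drop
    for (i in seq_len(nrow(cur))) {
      d <- deltaApp(cand$dH - cur$dH[i], cand$dN - cur$dN[i])
      o <- order(d)
      if (!length(o) || d[o[1]] > maxStep) next
      if (length(o) > 1 && d[o[2]] <= maxStep && d[o[2]] <= 1.1 * d[o[1]])
        stop("ambiguous match for residue ", cur$residue_id[i],
             " at pressure ", pressures[k],
             ": two candidates within maxStep and within 10% distance")
      matched[i] <- o[1]
    }
    taken <- matched[matched > 0]
    if (anyDuplicated(taken)) {
      dup <- taken[duplicated(taken)][1]
      who <- cur$residue_id[matched == dup]
      stop("ambiguous match at pressure ", pressures[k], ": residues ",
           paste(who, collapse = ", "), " claim the same peak")
    }
    keep <- matched > 0
    cur <- cur[keep, , drop = FALSE]
    cur$dH <- cand$dH[matched[keep]]
    cur$dN <- cand$dN[matched[keep]]
    h <- if ("height" %in% names(cand)) cand$height[matched[keep]] else NA_real_
    out[[k]] <- peakList(cur$residue_id, cur$dH, cur$dN, cur$residue_name, h,
                         label = reference@label, pressure = pressures[k])
  }
  ## restrict earlier lists to the final traceable set
  final <- cur$residue_id
  out <- lapply(out, function(pl) {
    pk <- pl@peaks[pl@peaks$residue_id %in% final, , drop = FALSE]
    peakList(pk$residue_id, pk$dH, pk$dN, pk$residue_name, pk$height,
             label = pl@label, pressure = pl@pressure)
  })
  pressureSeries(out)
}

## exact-position row match used to carry heights onto the reference list
.matchRows <- function(cur, cand) {
  vapply(seq_len(nrow(cur)), function(i) {
    j <- which(abs(cand$dH - cur$dH[i]) < 1e-12 & abs(cand$dN - cur$dN[i]) < 1e-12)
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
}

#' Write every list of a pressure series as Sparky files
#'
#' Files are named \code{p<pressure>.list} inside \code{dir}.
#'
#' @param series a \linkS4class{PressureSeries}.
#' @param dir output directory (created if needed).
#' @return character vector of paths, invisibly.
#' @export
writePressureSeries <- function(series, dir) {
  stopifnot(is(series, "PressureSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(series@peakLists, function(pl) {
    p <- file.path(dir, sprintf("p%g.list", pl@pressure))
    writePeakList(pl, p)
    p
  }, character(1))
  invisible(paths)
}
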