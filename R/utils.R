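#' @keywords internal
#' @import methods
#' @importFrom stats rnorm runif density coef lm sd setNames
#' @importFrom utils read.table write.table combn packageVersion
#' @importFrom tools md5sum
"_PACKAGE"

## gas constant, J/(mol K); 1 MPa mL/mol == 1 J/mol so p*dV needs no conversion
.R_GAS <- 8.314

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrapAngle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180 & !is.na(y)] <- y[y <= -180 & !is.na(y)] + 360
  y
}

## Deterministic per-residue substream seed: adding residues to a model never
## perturbs the noise stream of existing ones.
.subSeed <- function(seed, id) {
  as.integer((as.double(seed) + 1000003 * as.double(id)) %% 2147483647)
}

.writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

## simple key=value config reader (comments with '#', values split on commas)
.readKV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}
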