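#' Build a run configuration
#'
#' @param preset preset name ("WT_AP", "D76N_AP" or "WT_HP").
#' @param outDir output directory.
#' @param seed master seed; every stage derives its own recorded seed.
#' @param nFrames trajectory frame count.
#' @param noiseSd peak-list noise (ppm); NULL uses the preset value.
#' @param aggregationMode "ratio" or "difference".
#' @param centering shift-matrix centering, "first" or "mean".
#' @return list of class "runConfig".
#' @export
runConfig <- function(preset, outDir, seed = 1, nFrames = 10000,
                      noiseSd = NULL, aggregationMode = "ratio",
                      centering = "first") {
  if (missing(preset) || !preset %in% presetNames())
    stop("preset must be one of: ", paste(presetNames(), collapse = ", "))
  structure(list(preset = preset, outDir = outDir, seed = as.integer(seed),
                 nFrames = as.integer(nFrames), noiseSd = noiseSd,
                 aggregationMode = aggregationMode, centering = centering),
            class = "runConfig")
}

#' Read a run configuration from a key=value file
#'
#' Recognised keys: preset, out_dir, seed, n_frames, noise_sd,
#' aggregation_mode, centering.
#'
#' @param path config file path.
#' @return list of class "runConfig".
#' @export
readRunConfig <- function(path) {
  kv <- .readKV(path)
  runConfig(
    preset = kv$preset,
    outDir = if (!is.null(kv$out_dir)) kv$out_dir else ".",
    seed = if (!is.null(kv$seed)) kv$seed else 1,
    nFrames = if (!is.null(kv$n_frames)) kv$n_frames else 10000,
    noiseSd = kv$noise_sd,
    aggregationMode = if (!is.null(kv$aggregation_mode)) kv$aggregation_mode else "ratio",
    centering = if (!is.null(kv$centering)) kv$centering else "first"
  )
}

#' Run the full simulate-and-analyse pipeline for one condition
#'
#' Stages: generate the pressure series and write Sparky lists; decompose it
#' into compression/transition patterns; simulate and fit the R2 profile;
#' simulate H/D exchange and compute protection factors; generate the latent
#' chain, dihedral, distance and mode trajectories; compute RMSF, PCA modes,
#' DCCM; segment the distance distribution and compute the conditioned
#' chi-squared profile; fit the unfolding titration. All stage seeds derive
#' deterministically from the master seed and are recorded in the manifest,
#' which lists every output file with its MD5 checksum. Any stage failure
#' aborts with the stage name; completed outputs are left in place.
#'
#' @param config a "runConfig" (see \code{\link{runConfig}}).
#' @return invisibly, the manifest data.frame.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  pre <- loadPreset(config$preset)
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(peaks = config$seed, chain = config$seed + 101L,
                dihedral = config$seed + 202L, distance = config$seed + 303L,
                modes = config$seed + 404L, decay = config$seed + 505L,
                titration = config$seed + 606L)
  files <- character(0)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  noiseSd <- if (is.null(config$noiseSd)) pre$noiseSd else config$noiseSd
  series <- stage("simulate_peaks", function()
    genPressureSeries(pre$shiftModel, pre$pressures, noiseSd,
                      seed = seeds$peaks, label = pre$condition))
  files <- c(files, stage("write_peaks", function()
    writePressureSeries(series, file.path(out, "peaklists"))))

  dec <- stage("decompose", function()
    decomposePressureSeries(series, centering = config$centering,
                            outDir = file.path(out, "decomp")))
  files <- c(files, file.path(out, "decomp",
                              c("scores.tsv", "singular_values.tsv",
                                "pattern_i.tsv", "pattern_ii.tsv")))

  r2truth <- pre$residues[pre$residues$traceable == 1L, ]
  r2curves <- stage("simulate_r2", function() {
    do.call(rbind, lapply(seq_len(nrow(r2truth)), function(i)
      cbind(residue = r2truth$residue[i],
            genDecayCurve(r2truth$r2[i], r2DelayGrid(), noiseSd = 0.01,
                          seed = .subSeed(seeds$decay, r2truth$residue[i])))))
  })
  r2file <- file.path(out, "r2_profile.tsv")
  stage("fit_r2", function() fitR2Profile(r2curves, outPath = r2file))
  files <- c(files, r2file)

  hdxTruth <- pre$residues[!is.na(pre$residues$kex_per_min), ]
  hdxCurves <- stage("simulate_hdx", function() {
    times <- seq(0, 1200, by = 60)   # minutes, one-day HSQC series
    kAgg <- pre$hdx$kAggPerMin
    do.call(rbind, lapply(seq_len(nrow(hdxTruth)), function(i)
      cbind(residue = hdxTruth$residue[i],
            genDecayCurve(hdxTruth$kex_per_min[i] + kAgg, times,
                          noiseSd = 0.005,
                          seed = .subSeed(seeds$decay + 1L, hdxTruth$residue[i])))))
  })
  hdxFile <- file.path(out, "exchange.tsv")
  stage("exchange", function()
    exchangeAnalysis(hdxCurves, beta2mSequence(),
                     kAgg = pre$hdx$kAggPerMin, mode = config$aggregationMode,
                     pDRead = pre$hdx$pDReading,
                     temperature = pre$hdx$temperature, outPath = hdxFile))
  files <- c(files, hdxFile)

  labels <- stage("latent_chain", function()
    genLatentChain(pre$chain, config$nFrames, seed = seeds$chain))
  ds <- stage("dihedrals", function()
    genDihedralSeries(pre$dihedralModel, labels, seed = seeds$dihedral))
  dist <- stage("distances", function()
    genDistanceSeries(pre$distanceMeans, pre$distanceSds, labels,
                      seed = seeds$distance))
  traj <- stage("mode_trajectory", function()
    genModeTrajectory(pre$modeModel, config$nFrames, seed = seeds$modes))

  rmsfFile <- file.path(out, "rmsf.tsv")
  stage("rmsf", function() .writeTSV(rmsf(traj), rmsfFile))
  files <- c(files, rmsfFile)
  dccmFile <- file.path(out, "dccm.tsv")
  stage("dccm", function() dccm(traj, outPath = dccmFile))
  files <- c(files, dccmFile)
  pm <- stage("pca", function() pcaModes(traj))
  porcFile <- file.path(out, "porcupine.pdb")
  stage("porcupine", function() {
    sel <- .selectAtoms(traj, "CA")
    mu <- apply(traj@coords[, sel, , drop = FALSE], c(2, 3), mean)
    writePorcupinePDB(pm, mu, porcFile)
  })
  files <- c(files, porcFile)

  segFile <- file.path(out, "subensembles.tsv")
  seg <- stage("segmentation", function() segmentSubensembles(dist))
  stage("write_segmentation", function()
    .writeTSV(data.frame(frame = seq_along(dist), distance = dist,
                         label = as.character(seg@labels)), segFile))
  files <- c(files, segFile)

  condFile <- file.path(out, "conditional_chi2.tsv")
  if (nlevels(droplevels(seg@labels)) >= 2) {
    stage("conditional_chi2", function()
      conditionalChi2(ds, seg, outPath = condFile))
    files <- c(files, condFile)
  }

  titFile <- file.path(out, "unfolding_fit.tsv")
  stage("unfolding", function() {
    cv <- genTitration(pre$unfold$midpoint, pre$unfold$slope,
                       pre$unfold$baselines, noiseSd = 0.007,
                       seed = seeds$titration)
    f <- fitSigmoid(cv)
    .writeTSV(data.frame(midpoint = f$midpoint, slope = f$slope,
                         folded = f$foldedBaseline,
                         unfolded = f$unfoldedBaseline,
                         midpoint_se = f$se["midpoint"]), titFile)
  })
  files <- c(files, titFile)

  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  header <- c(
    sprintf("# baroshift %s", as.character(utils::packageVersion("baroshift"))),
    sprintf("# preset = %s", config$preset),
    sprintf("# seed.%s = %d", names(seeds), unlist(seeds)),
    sprintf("# n_frames = %d", config$nFrames),
    sprintf("# noise_sd = %g", noiseSd),
    sprintf("# aggregation_mode = %s", config$aggregationMode),
    sprintf("# centering = %s", config$centering)
  )
  manifestPath <- file.path(out, "manifest.tsv")
  writeLines(header, manifestPath)
  suppressWarnings(
    utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE)
  )
  invisible(manifest)
}
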