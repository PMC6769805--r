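test_that("apparent shift difference applies the 1/5 nitrogen weight", {
  expect_equal(deltaApp(0, 0), 0)
  expect_equal(deltaApp(0.3, 0), 0.3)
  expect_equal(deltaApp(0.1, 0.5), sqrt(0.1^2 + 0.1^2), tolerance = 1e-6)
  expect_equal(deltaApp(0.1, 0.5), 0.14142, tolerance = 1e-4)
  ## invariant under sign flips of both inputs
  set.seed(1)
  h <- stats::rnorm(20); n <- stats::rnorm(20)
  expect_equal(deltaApp(h, n), deltaApp(-h, -n))
  expect_error(deltaApp(NA, 1))
})

test_that("peak-list comparison reports per-residue differences", {
  a <- peakList(1:3, dH = c(8, 8.2, 8.4), dN = c(110, 115, 120))
  expect_equal(comparePeakLists(a, a)$delta_app, rep(0, 3))

  b <- peakList(1:3, dH = c(8, 8.3, 8.4), dN = c(110, 115.5, 120))
  cp <- comparePeakLists(a, b)
  expect_equal(cp$delta_app, c(0, 0.14142, 0), tolerance = 1e-4)

  ## disjoint residues flagged missing; none shared is an error
  b2 <- peakList(c(2L, 9L), dH = c(8.2, 7), dN = c(115, 125))
  cp2 <- comparePeakLists(a, b2)
  expect_true(cp2$missing[cp2$residue %in% c(1, 3, 9)] |> all())
  expect_error(comparePeakLists(a, peakList(7L, 7, 125)), "shared")
})

test_that("mutation offsets dominate the WT vs D76N shift comparison", {
  wt <- loadPreset("WT_AP"); mut <- loadPreset("D76N_AP")
  pWT <- peakLists(genPressureSeries(wt$shiftModel, wt$pressures, 0, seed = 1))[[1]]
  pMU <- peakLists(genPressureSeries(mut$shiftModel, mut$pressures, 0, seed = 1))[[1]]
  cp <- comparePeakLists(pWT, pMU)
  offset <- mut$residues[match(cp$residue, mut$residues$residue), ]
  planted <- abs(offset$mut_offset_H) > 0 | abs(offset$mut_offset_N) > 0
  top <- order(cp$delta_app, decreasing = TRUE)[1:5]
  expect_true(all(planted[top]))
})

test_that("shift matrix assembly is residue-major with scaled nitrogen rows", {
  pre <- loadPreset("WT_AP")
  ser <- genPressureSeries(pre$shiftModel, pre$pressures, pre$noiseSd, seed = 1)
  X <- assembleShiftMatrix(ser)
  expect_equal(dim(X@x), c(164, 10))
  expect_equal(X@axis[1:4], c("H", "N", "H", "N"))

  m <- makeModel(1, slopeH = 1e-4)
  s3 <- genPressureSeries(m, c(5, 50, 100), noiseSd = 0, seed = 1)
  expect_equal(dim(assembleShiftMatrix(s3)@x), c(2, 3))

  X1 <- assembleShiftMatrix(ser, nScale = 1)
  X5 <- assembleShiftMatrix(ser, nScale = 1 / 5)
  nRows <- X1@axis == "N"
  expect_equal(X1@x[nRows, ], 5 * X5@x[nRows, ], tolerance = 1e-12)
})

test_that("centered SVD reports rank and reconstructs the matrix", {
  pre <- loadPreset("WT_AP")
  ser <- genPressureSeries(pre$shiftModel, pre$pressures, pre$noiseSd, seed = 1)
  X <- assembleShiftMatrix(ser)
  dec <- svdShiftMatrix(X)
  ## first-column centering forces rank P-1 = 9 on generic data
  expect_equal(dec@nAboveTol, 9L)
  ## full reconstruction of the centered matrix
  Xc <- X@x - X@x[, 1]
  K <- length(dec@d)
  rec <- dec@u %*% t(dec@scores)      # scores already carry singular values
  expect_lt(max(abs(rec - Xc)) / max(abs(Xc)), 1e-10)
  ## variance fractions: sum to one, non-increasing
  expect_equal(sum(dec@varianceExplained), 1, tolerance = 1e-12)
  expect_true(all(diff(dec@varianceExplained) <= 1e-15))

  ## degenerate matrix: identical columns collapse to zero
  m <- makeModel(2)
  sFlat <- genPressureSeries(m, c(5, 50, 100), noiseSd = 0, seed = 1)
  XF <- assembleShiftMatrix(sFlat)
  XF@x <- matrix(XF@x[, 1], nrow(XF@x), 3)
  expect_warning(dFlat <- svdShiftMatrix(XF), "degenerate")
  expect_equal(dFlat@nAboveTol, 0L)

  ## constructed rank-2 input
  m2 <- makeModel(6, slopeH = seq(1, 6) * 1e-4, ampN = c(0, 0, 1, 1, 0.5, 0))
  s2 <- genPressureSeries(m2, pre$pressures, noiseSd = 0, seed = 1)
  expect_equal(svdShiftMatrix(assembleShiftMatrix(s2))@nAboveTol, 2L)
})

test_that("direction identification splits initial and orthogonal change", {
  mk <- function(s) {
    d <- new("ShiftDecomposition", d = c(1, 1), u = diag(2),
             scores = s, centering = "first", centerRef = 0,
             nAboveTol = 2L, vI = numeric(0), vII = numeric(0),
             patternI = data.frame(), patternII = data.frame(),
             varianceExplained = c(0.5, 0.5), matrixInfo = list())
    identifyDirections(d)
  }
  ## collinear scores: the total change projects to zero on v_ii
  lin <- mk(cbind(c(0, 1, 2, 3), c(0, 0.5, 1, 1.5)))
  total <- c(3, 1.5)
  expect_equal(sum(total * lin@vII), 0, tolerance = 1e-12)

  ## L-shaped path: v_i along PC1, v_ii picks the later PC2 sense
  ell <- mk(cbind(c(0, 1, 2, 2, 2), c(0, 0, 0, 1, 2)))
  expect_equal(abs(ell@vI), c(1, 0), tolerance = 1e-12)
  expect_equal(ell@vII, c(0, 1), tolerance = 1e-12)

  ## coincident first two scores are an error
  expect_error(mk(cbind(c(0, 0, 1), c(0, 0, 1))), "coincide")
})

test_that("low-pressure secant aligns with the compression loading", {
  pre <- loadPreset("WT_AP")
  ser <- genPressureSeries(pre$shiftModel, pre$pressures, noiseSd = 0, seed = 1)
  dec <- identifyDirections(svdShiftMatrix(assembleShiftMatrix(ser)))
  ## ground-truth compression loading in row space, projected on PC1-2
  tr <- pre$residues[pre$residues$traceable == 1, ]
  g <- c(rbind(tr$slope_H, tr$slope_N / 5))
  gPC <- crossprod(dec@u[, 1:2], g)
  expect_gt(cosSim(gPC, dec@vI), 0.99)
})

test_that("back-projected patterns recover the generator ground truth", {
  pre <- loadPreset("WT_AP")
  tr <- pre$residues[pre$residues$traceable == 1, ]

  ## rank-1 compression-only series: pattern_i = slopes x pressure range
  mC <- twoStateShiftModel(tr$residue, slopeH = tr$slope_H, slopeN = tr$slope_N,
                           deltaH0 = tr$dH0, deltaN0 = tr$dN0)
  serC <- genPressureSeries(mC, pre$pressures, noiseSd = 0, seed = 1)
  decC <- decomposePressureSeries(serC)
  expected <- tr$slope_H * diff(range(pre$pressures))
  relErr <- max(abs(abs(decC@patternI$dH) - abs(expected)) / max(abs(expected)))
  expect_lt(relErr, 1e-6)
  ## and the transition pattern is numerically absent
  expect_lt(max(abs(decC@patternII$delta_app)), 1e-8)

  ## two-component preset: transition pattern matches the amplitudes
  ser2 <- genPressureSeries(pre$shiftModel, pre$pressures, noiseSd = 0, seed = 1)
  dec2 <- decomposePressureSeries(ser2)
  gII <- c(rbind(tr$amp_H, tr$amp_N / 5))
  pII <- c(rbind(dec2@patternII$dH, dec2@patternII$dN_scaled))
  expect_gt(cosSim(pII, gII), 0.99)
  expect_gt(abs(stats::cor(dec2@patternII$delta_app,
                           deltaApp(tr$amp_H, tr$amp_N))), 0.99)
  gI <- c(rbind(tr$slope_H, tr$slope_N / 5))
  pI <- c(rbind(dec2@patternI$dH, dec2@patternI$dN_scaled))
  expect_gt(cosSim(pI, gI), 0.99)

  ## graceful degradation at the default noise level
  serN <- genPressureSeries(pre$shiftModel, pre$pressures, noiseSd = 0.002, seed = 3)
  decN <- decomposePressureSeries(serN)
  pIIn <- c(rbind(decN@patternII$dH, decN@patternII$dN_scaled))
  expect_gt(cosSim(pIIn, gII), 0.9)

  ## projection needs two PCs
  dec1 <- decC; dec1@u <- decC@u[, 1, drop = FALSE]; dec1@d <- decC@d[1]
  expect_error(projectPattern(dec1, c(1, 0)), "2 PCs")
})

test_that("transition-only series yields a sigmoidal score progression", {
  pre <- loadPreset("WT_AP")
  tr <- pre$residues[pre$residues$traceable == 1, ]
  mT <- twoStateShiftModel(tr$residue, ampH = tr$amp_H, ampN = tr$amp_N,
                           deltaH0 = tr$dH0, deltaN0 = tr$dN0,
                           dG0 = 15000, dV = -100)
  serT <- genPressureSeries(mT, pre$pressures, noiseSd = 0, seed = 1)
  dec <- svdShiftMatrix(assembleShiftMatrix(serT))
  s1 <- dec@scores[, 1]
  fE <- excitedPopulation(mT, pre$pressures)
  ## one-dimensional path tracing f_E
  expect_gt(abs(stats::cor(s1, fE)), 0.9999)
  expect_equal(dec@nAboveTol, 1L)
})

test_that("decomposition writes its TSV outputs", {
  pre <- loadPreset("WT_AP")
  ser <- genPressureSeries(pre$shiftModel, pre$pressures, pre$noiseSd, seed = 1)
  out <- tempfile()
  decomposePressureSeries(ser, outDir = out)
  expect_true(all(file.exists(file.path(out,
    c("scores.tsv", "singular_values.tsv", "pattern_i.tsv", "pattern_ii.tsv")))))
  sv <- read.delim(file.path(out, "singular_values.tsv"))
  expect_equal(nrow(sv), 10)
})
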