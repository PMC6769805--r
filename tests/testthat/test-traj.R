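test_that("torsion angles follow the IUPAC convention", {
  expect_equal(torsionSeries(torsionFixture(180), 1:4), 180, tolerance = 1e-9)
  expect_equal(torsionSeries(torsionFixture(60), 1:4), 60, tolerance = 1e-9)
  expect_equal(torsionSeries(torsionFixture(-135), 1:4), -135, tolerance = 1e-9)
  ## mirroring flips the sign (chirality)
  tr <- torsionFixture(60)
  mir <- tr
  mir@coords[, , 3] <- -mir@coords[, , 3]
  expect_equal(torsionSeries(mir, 1:4), -60, tolerance = 1e-9)
})

test_that("backbone dihedrals are extracted with terminal flags", {
  ## two-residue chain with ideal geometry: residue 1 has psi, residue 2 has phi
  xyz <- array(0, c(2, 6, 3))
  coords <- rbind(
    c(0.0, 1.4, 0), c(0, 0, 0), c(1.4, -0.5, 0),        # N1 CA1 C1
    c(1.6, -1.9, 0), c(3.0, -2.4, 0.3), c(3.3, -3.8, 0.3)  # N2 CA2 C2
  )
  xyz[1, , ] <- coords
  xyz[2, , ] <- coords %*% rotZ(0.7)   # rigid rotation, angles unchanged
  top <- data.frame(index = 1:6, residue_id = rep(1:2, each = 3),
                    atom_name = rep(c("N", "CA", "C"), 2))
  ds <- computeDihedrals(trajectory(xyz, top))
  expect_true(all(is.na(ds@phi[, 1])))   # first residue lacks phi
  expect_true(all(is.na(ds@psi[, 2])))   # last residue lacks psi
  expect_false(anyNA(ds@psi[, 1]))
  expect_false(anyNA(ds@phi[, 2]))
  expect_equal(ds@psi[1, 1], ds@psi[2, 1], tolerance = 1e-9)
  expect_equal(ds@phi[1, 2], ds@phi[2, 2], tolerance = 1e-9)
})

test_that("dihedral histograms use ten 36-degree bins with closed extremes", {
  h1 <- dihedralHistogram(10, 100)
  expect_equal(dim(h1), c(10, 10))
  expect_equal(sum(h1), 1)
  expect_equal(sum(h1 == 1), 1)
  expect_equal(diff(attr(h1, "edges")), rep(36, 10))

  ## uniform grid covering every cell equally
  centers <- seq(-162, 162, by = 36)
  grid <- expand.grid(phi = centers, psi = centers)
  hU <- dihedralHistogram(rep(grid$phi, 4), rep(grid$psi, 4))
  expect_true(all(abs(hU - 0.01) < 1e-12))

  ## -180 wraps into the first bin, +180 into the last
  hB <- dihedralHistogram(c(-180, 180), c(-180, 180))
  expect_equal(hB[1, 1], 0.5)
  expect_equal(hB[10, 10], 0.5)

  ## empty input: zero table, n = 0
  h0 <- dihedralHistogram(numeric(0), numeric(0))
  expect_equal(sum(h0), 0)
  expect_equal(attr(h0, "n"), 0L)
})

test_that("chi-squared distance matches its definition and is symmetric", {
  h <- randomHistogram()
  expect_equal(dihedralChi2(h, h), 0)

  ## all mass in one cell vs a different cell: (1 + 1)/100
  a <- matrix(0, 10, 10); a[1, 1] <- 1
  b <- matrix(0, 10, 10); b[5, 7] <- 1
  attr(a, "edges") <- attr(b, "edges") <- seq(-180, 180, by = 36)
  expect_equal(dihedralChi2(a, b), 0.02)

  set.seed(2)
  for (i in 1:20) {
    f1 <- randomHistogram(); f2 <- randomHistogram()
    expect_identical(dihedralChi2(f1, f2), dihedralChi2(f2, f1))
    expect_identical(dihedralChi2(f1, f2), chi2Brute(f1, f2))
  }
  bad <- h; attr(bad, "edges") <- seq(-180, 180, length.out = 12)
  expect_error(dihedralChi2(h, bad), "binning")
})

test_that("chi-squared profiles flag planted dihedral changes", {
  pre <- loadPreset("WT_AP"); mut <- loadPreset("D76N_AP")
  labW <- genLatentChain(pre$chain, 50000, seed = 21)
  labM <- rep(1L, 50000)
  dsW <- genDihedralSeries(pre$dihedralModel, labW, seed = 22)
  dsM <- genDihedralSeries(mut$dihedralModel, labM, seed = 23)
  prof <- chi2Profile(dsW, dsM)
  coupled <- pre$dihedralModel@residues[pre$dihedralModel@coupled]
  inner <- prof[!prof$residue %in% c(1, 99), ]   # terminal residues lack angles
  expect_true(all(inner$chi2[inner$residue %in% coupled] > 1e-3))
  expect_true(all(inner$chi2[!inner$residue %in% coupled] < 1e-3))
  ## identical series give a zero profile
  expect_true(all(chi2Profile(dsW, dsW)$chi2[!is.na(prof$chi2)] == 0))
})

test_that("same-distribution chi-squared shrinks with sample size", {
  dm <- dihedralModel(5L, FALSE, muPhi = cbind(-100), muPsi = cbind(120),
                      kappaPhi = cbind(8), kappaPsi = cbind(8))
  chiAt <- function(n, s1, s2) {
    a <- genDihedralSeries(dm, rep(1L, n), seed = s1)
    b <- genDihedralSeries(dm, rep(1L, n), seed = s2)
    dihedralChi2(dihedralHistogram(a@phi[, 1], a@psi[, 1]),
                 dihedralHistogram(b@phi[, 1], b@psi[, 1]))
  }
  small <- mean(c(chiAt(1e3, 1, 2), chiAt(1e3, 3, 4), chiAt(1e3, 5, 6)))
  large <- mean(c(chiAt(1e5, 7, 8), chiAt(1e5, 9, 10)))
  expect_gt(small, large)
})

test_that("RMSF vanishes for static or rigidly moving structures", {
  pre <- loadPreset("WT_AP")
  mu <- pre$modeModel@meanCoords
  A <- nrow(mu)
  static <- array(rep(mu, each = 4), c(4, A, 3))
  top <- data.frame(index = 1:A, residue_id = 1:A, atom_name = "CA")
  expect_true(all(rmsf(trajectory(static, top))$rmsf == 0))

  ## rigid-body rotated/translated copies superpose to zero fluctuation
  rigid <- array(NA_real_, c(4, A, 3))
  for (f in 1:4)
    rigid[f, , ] <- sweep(mu %*% rotZ(0.3 * f), 2, c(f, -f, 2 * f), "+")
  expect_lt(max(rmsf(trajectory(rigid, top))$rmsf), 1e-8)

  expect_warning(r1 <- rmsf(trajectory(static[1, , , drop = FALSE], top)),
                 "single frame")
  expect_true(all(r1$rmsf == 0))
})

test_that("RMSF tracks the per-atom amplitude of a single latent mode", {
  pre <- loadPreset("WT_AP")
  m0 <- modeTrajectoryModel(pre$modeModel@meanCoords, pre$modeModel@modes,
                            3, 0)
  tr <- genModeTrajectory(m0, 10000, seed = 31)
  r <- rmsf(tr)
  perAtom <- sqrt(rowSums(matrix(c(pre$modeModel@modes[, , 1]), ncol = 3)^2))
  ## sd of the latent amplitude gives RMSF_i = sd_k * |mode_i| in closed form
  expected <- 3 * perAtom
  expect_lt(max(abs(r$rmsf - expected) / max(expected)), 0.02)
})

test_that("PCA modes recover the generating mode and the trace identity", {
  pre <- loadPreset("WT_AP")
  m0 <- modeTrajectoryModel(pre$modeModel@meanCoords, pre$modeModel@modes,
                            3, 0)
  tr <- genModeTrajectory(m0, 2000, seed = 32)
  pm <- pcaModes(tr)
  expect_gt(cosSim(pm$eigenvectors[, 1], c(pre$modeModel@modes[, , 1])), 0.99)

  ## eigenvalue sum equals the sum of squared RMSFs
  trN <- genModeTrajectory(pre$modeModel, 2000, seed = 33)
  pmN <- pcaModes(trN)
  rN <- rmsf(trN)
  expect_equal(sum(pmN$eigenvalues), sum(rN$rmsf^2), tolerance = 1e-6)

  ## eigenvectors orthonormal, eigenvalues non-negative descending
  G <- crossprod(pm$eigenvectors[, 1:10])
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(pm$eigenvalues) <= 1e-12))
  expect_true(all(pm$eigenvalues >= 0))
})

test_that("isotropic noise gives an approximately flat eigenvalue spectrum", {
  mu <- matrix(stats::rnorm(60, sd = 20), 20, 3)
  v <- matrix(0, 20, 3); v[1, 1] <- 1
  m <- modeTrajectoryModel(mu, array(v, c(20, 3, 1)), 0, 0.5)
  tr <- genModeTrajectory(m, 5000, seed = 34)
  pm <- pcaModes(tr, superpose = FALSE)
  ev <- pm$eigenvalues
  expect_lt(ev[1] / stats::median(ev), 1.3)
})

test_that("DCCM captures parallel and anti-parallel motion", {
  ## two atoms driven by one mode, same sign -> +1; opposite sign -> -1
  mu <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  v <- matrix(c(1, 0, 0,  1, 0, 0,  -1, 0, 0), 3, 3, byrow = TRUE)
  v <- v / sqrt(sum(v^2))
  m <- modeTrajectoryModel(mu, array(v, c(3, 3, 1)), 1, 0)
  tr <- genModeTrajectory(m, 200, seed = 35)
  C <- dccm(tr, superpose = FALSE)
  expect_equal(C[1, 2], 1, tolerance = 1e-10)
  expect_equal(C[1, 3], -1, tolerance = 1e-10)

  ## symmetric, unit diagonal, bounded
  pre <- loadPreset("WT_AP")
  trW <- genModeTrajectory(pre$modeModel, 1000, seed = 36)
  CW <- dccm(trW)
  expect_true(isSymmetric(unname(CW)))
  expect_equal(unname(diag(CW)), rep(1, nrow(CW)))
  expect_true(all(CW >= -1 - 1e-12 & CW <= 1 + 1e-12))

  ## invariant under a global rigid motion applied to every frame
  x <- coords(trW)
  for (f in seq_len(dim(x)[1]))
    x[f, , ] <- sweep(x[f, , ] %*% rotZ(0.8), 2, c(3, -1, 7), "+")
  C2 <- dccm(trajectory(x, topology(trW)))
  expect_lt(max(abs(C2 - CW)), 1e-8)

  ## zero-variance atom flagged undefined
  st <- coords(trW); st[, 5, ] <- 0
  C3 <- dccm(trajectory(st, topology(trW)), superpose = FALSE)
  expect_true(all(is.na(C3[5, -5])))
  expect_equal(attr(C3, "undefined"), 5)
})

test_that("DCCM agrees with an independent implementation", {
  pre <- loadPreset("WT_AP")
  tr <- genModeTrajectory(pre$modeModel, 300, seed = 37)
  sup <- superposeTrajectory(tr)
  C <- dccm(sup, superpose = FALSE)
  xyzMat <- t(apply(coords(sup), 1, function(fr) c(t(fr))))  # bio3d xyz layout
  Cref <- suppressWarnings(bio3d::dccm.xyz(xyzMat, fit = FALSE))
  expect_equal(unname(C), unname(Cref[, ]), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("collective motion exceeds the noise-dominated condition", {
  wt <- loadPreset("WT_AP"); hp <- loadPreset("WT_HP")
  CW <- dccm(genModeTrajectory(wt$modeModel, 1500, seed = 38))
  CH <- dccm(genModeTrajectory(hp$modeModel, 1500, seed = 38))
  off <- function(M) mean(abs(M[upper.tri(M)]))
  expect_gt(off(CW), off(CH))
})

test_that("atom distances resolve names and recover state means", {
  xyz <- array(0, c(2, 2, 3))
  xyz[1, 2, ] <- c(0, 0, 0)       # coincident
  xyz[2, 2, ] <- c(1, 0, 0)       # unit displacement
  top <- data.frame(index = 1:2, residue_id = c(76L, 41L),
                    atom_name = c("OD2", "NZ"))
  d <- atomDistanceSeries(trajectory(xyz, top), c("76:OD2", "41:NZ"))
  expect_equal(d, c(0, 1))
  expect_error(atomDistanceSeries(trajectory(xyz, top), c("76:OD2", "41:XX")),
               "not found")

  pre <- loadPreset("WT_AP")
  lab <- genLatentChain(pre$chain, 50000, seed = 39)
  dist <- genDistanceSeries(pre$distanceMeans, pre$distanceSds, lab, seed = 40)
  for (k in 1:3)
    expect_lt(abs(mean(dist[lab == k]) - pre$distanceMeans[k]), 0.05)
})

test_that("subensemble segmentation finds the planted states", {
  ## unimodal sample: one subensemble, no boundaries
  set.seed(41)
  u <- stats::rnorm(5000, 6, 0.4)
  segU <- segmentSubensembles(u)
  expect_equal(nlevels(stateLabels(segU)), 1)
  expect_length(segU@boundaries, 0)

  ## WT preset: three subensembles, labels match the generator
  pre <- loadPreset("WT_AP")
  lab <- genLatentChain(pre$chain, 50000, seed = 42)
  d <- genDistanceSeries(pre$distanceMeans, pre$distanceSds, lab, seed = 43)
  seg <- segmentSubensembles(d)
  expect_equal(nlevels(stateLabels(seg)), 3)
  expect_gt(mean(as.integer(stateLabels(seg)) == lab), 0.99)

  ## merged modes (1 sd apart) collapse to one subensemble
  set.seed(44)
  merged <- c(stats::rnorm(3000, 5, 0.5), stats::rnorm(3000, 5.5, 0.5))
  expect_equal(nlevels(stateLabels(segmentSubensembles(merged))), 1)

  expect_error(segmentSubensembles(numeric(0)), "empty")
  expect_error(segmentSubensembles(stats::rnorm(50)), "100")
})

test_that("conditioned chi-squared separates coupled from uncoupled residues", {
  pre <- loadPreset("WT_AP")
  lab <- genLatentChain(pre$chain, 50000, seed = 45)
  ds <- genDihedralSeries(pre$dihedralModel, lab, seed = 46)
  seg <- segmentSubensembles(
    genDistanceSeries(pre$distanceMeans, pre$distanceSds, lab, seed = 47))
  cc <- conditionalChi2(ds, seg)
  coupled <- pre$dihedralModel@residues[pre$dihedralModel@coupled]
  isC <- cc$residue %in% coupled
  expect_true(all(cc$max_chi2[!isC] < 1e-3))
  expect_gt(min(cc$max_chi2[isC]), 10 * max(cc$max_chi2[!isC]))
  ## pair table covers the three unordered state pairs
  pairs <- attr(cc, "pairs")
  expect_setequal(unique(paste(pairs$state1, pairs$state2)),
                  c("a b", "a c", "b c"))

  ## two-state labels: exactly one pair, max equals it
  lab2 <- factor(rep(c("a", "b"), length.out = 50000))
  cc2 <- conditionalChi2(ds, lab2)
  p2 <- attr(cc2, "pairs")
  expect_equal(unique(p2$state1), "a")
  expect_equal(cc2$max_chi2, p2$chi2)

  ## a sparse subensemble is flagged low-confidence
  lab3 <- factor(c(rep("a", 49980), rep("b", 20)))
  cc3 <- conditionalChi2(ds, lab3)
  expect_true(all(cc3$low_confidence))
  expect_error(conditionalChi2(ds, factor(rep("a", 50000))), "2 subensembles")
})
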