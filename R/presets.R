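#' Mature human beta-2-microglobulin sequence
#'
#' The 99-residue mature chain (D76, K41, H13, S55, C25-C80 disulfide).
#' @return a single character string.
#' @export
beta2mSequence <- function() {
  paste0("IQRTPKIQVYSRHPAENGKSNFLNCYVSGFHPSDIEVDLLKNGERIEKVEHSDLSFSKDW",
         "SFYLLYYTEFTPTEKDEYACRVNHVTLSQPKIVKWDRDM")
}

#' Available condition presets
#' @return character vector of preset names.
#' @export
presetNames <- function() c("WT_AP", "D76N_AP", "WT_HP")

.presetDir <- function() system.file("extdata", "presets", package = "baroshift")

#' Load a condition preset
#'
#' Presets bundle every ground-truth parameter the synthetic generators need
#' for one experimental condition: per-residue two-state shift parameters,
#' state-conditional dihedral parameters, the latent conformational chain,
#' side-chain distance subensembles, collective-mode settings, the
#' pH-unfolding sigmoid, and the H/D-exchange context. The shipped parameter
#' files are the single source of ground truth for recovery tests.
#'
#' @param name one of \code{presetNames()}.
#' @return a list with elements \code{condition}, \code{config},
#'   \code{residues} (per-residue table), \code{shiftModel}
#'   (\linkS4class{TwoStateShiftModel} over the traceable set),
#'   \code{pressures}, \code{noiseSd}, \code{chain}
#'   (\linkS4class{LatentStateChain}), \code{dihedralModel}
#'   (\linkS4class{DihedralModel}), \code{distanceMeans},
#'   \code{distanceSds}, \code{modeModel} (\linkS4class{ModeTrajectoryModel}),
#'   \code{unfold} (midpoint, slope, baselines), and \code{hdx}
#'   (kAggPerMin, pDReading, temperature).
#' @export
loadPreset <- function(name = presetNames()) {
  name <- match.arg(name)
  dir <- .presetDir()
  cfg <- .readKV(file.path(dir, paste0(name, ".cfg")))
  res <- .readTSV(file.path(dir, cfg$residue_table))
  dih <- .readTSV(file.path(dir, cfg$dihedral_table))

  tr <- res[res$traceable == 1L, ]
  shiftModel <- twoStateShiftModel(
    residues = tr$residue, residueNames = tr$name,
    slopeH = tr$slope_H, slopeN = tr$slope_N,
    ampH = tr$amp_H, ampN = tr$amp_N,
    deltaH0 = tr$dH0, deltaN0 = tr$dN0,
    dG0 = cfg$dG0, dV = cfg$dV, temperature = cfg$temperature
  )

  K <- as.integer(cfg$n_states)
  stay <- cfg$stay_prob
  P <- if (K == 1) matrix(1, 1, 1) else {
    off <- (1 - stay) / (K - 1)
    M <- matrix(off, K, K); diag(M) <- stay; M
  }
  chain <- latentStateChain(P)

  muPhi <- as.matrix(dih[paste0("mu_phi_", seq_len(K))])
  muPsi <- as.matrix(dih[paste0("mu_psi_", seq_len(K))])
  dihedralMod <- dihedralModel(
    residues = dih$residue, coupled = dih$coupled == 1L,
    muPhi = muPhi, muPsi = muPsi,
    kappaPhi = matrix(dih$kappa_phi, nrow(dih), K),
    kappaPsi = matrix(dih$kappa_psi, nrow(dih), K)
  )

  modeModel <- .presetModeModel(nrow(res), cfg$mode_amplitude_sd, cfg$traj_noise_sd)

  list(
    condition = cfg$condition, config = cfg, residues = res,
    shiftModel = shiftModel, pressures = cfg$pressures, noiseSd = cfg$noise_sd,
    chain = chain, dihedralModel = dihedralMod,
    distanceMeans = cfg$distance_means, distanceSds = cfg$distance_sds,
    modeModel = modeModel,
    unfold = list(midpoint = cfg$unfold_midpoint, slope = cfg$unfold_slope,
                  baselines = cfg$unfold_baselines),
    hdx = list(kAggPerMin = cfg$k_agg_per_min, pDReading = cfg$pD_reading,
               temperature = cfg$hdx_temperature)
  )
}

## Deterministic CA pseudo-structure on a gentle helix-like space curve, with
## one bending mode whose loadings peak at the chain periphery (termini and
## loop-like positions). Rigid-body translations and infinitesimal rotations
## about the centroid are projected out so the mode is purely internal and
## survives least-squares superposition unchanged.
.presetModeModel <- function(nRes, ampSd, noiseSd) {
  i <- seq_len(nRes)
  t <- i / nRes * 4 * pi
  mean <- cbind(10 * cos(t), 10 * sin(t), 1.5 * i)
  w <- (abs(i - (nRes + 1) / 2) / (nRes / 2))^2 + 0.05
  dirv <- cbind(cos(t / 2), sin(t / 2), rep(0.3, nRes))
  mode <- dirv * w
  ## rigid-body basis at the mean structure (flattened axis-major)
  cen <- sweep(mean, 2, colMeans(mean))
  basis <- cbind(
    c(rep(1, nRes), rep(0, 2 * nRes)),
    c(rep(0, nRes), rep(1, nRes), rep(0, nRes)),
    c(rep(0, 2 * nRes), rep(1, nRes)),
    c(rep(0, nRes), -cen[, 3], cen[, 2]),
    c(cen[, 3], rep(0, nRes), -cen[, 1]),
    c(-cen[, 2], cen[, 1], rep(0, nRes))
  )
  Q <- qr.Q(qr(basis))
  v <- c(mode)                      # axis-major flatten matches matrix(A x 3)
  v <- v - Q %*% crossprod(Q, v)
  v <- v / sqrt(sum(v^2))
  modeTrajectoryModel(mean, array(matrix(v, nRes, 3), c(nRes, 3, 1)),
                      ampSd, noiseSd)
}
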