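#' Generate a pressure series of peak lists from a two-state model
#'
#' For each residue and axis, observed shift at pressure p is
#' delta0 + slope*p + f_E(p)*amp + Gaussian noise. Each residue uses an
#' independent random substream, so adding residues never perturbs the noise
#' of existing ones.
#'
#' @param model a \linkS4class{TwoStateShiftModel}.
#' @param pressures strictly increasing pressures (MPa), length >= 3.
#' @param noiseSd Gaussian noise sd (ppm), applied independently on the H and
#'   N axes.
#' @param seed integer seed.
#' @param label condition label stored on each list.
#' @return a \linkS4class{PressureSeries}.
#' @export
genPressureSeries <- function(model, pressures, noiseSd = 0.002, seed = 1,
                              label = "synthetic") {
  stopifnot(is(model, "TwoStateShiftModel"))
  if (length(pressures) < 3 || any(diff(pressures) <= 0))
    stop("pressures must be strictly increasing with length >= 3")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  fE <- excitedPopulation(model, pressures)
  n <- length(model@residues)
  P <- length(pressures)
  dH <- outer(model@deltaH0, rep(1, P)) + outer(model@slopeH, pressures) +
    outer(model@ampH, fE)
  dN <- outer(model@deltaN0, rep(1, P)) + outer(model@slopeN, pressures) +
    outer(model@ampN, fE)
  if (noiseSd > 0) {
    for (i in seq_len(n)) {
      set.seed(.subSeed(seed, model@residues[i]))
      dH[i, ] <- dH[i, ] + stats::rnorm(P, 0, noiseSd)
      dN[i, ] <- dN[i, ] + stats::rnorm(P, 0, noiseSd)
    }
  }
  lists <- lapply(seq_len(P), function(j) {
    new("PeakList", label = label, pressure = pressures[j],
        peaks = data.frame(
          residue_id = model@residues,
          residue_name = model@residueNames,
          dH = dH[, j], dN = dN[, j],
          height = rep(NA_real_, n)
        ))
  })
  new("PressureSeries", peakLists = lists)
}

#' Sample per-frame labels from a latent-state chain
#'
#' @param chain a \linkS4class{LatentStateChain}.
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed.
#' @return integer vector of state labels in 1..K.
#' @export
genLatentChain <- function(chain, nFrames, seed = 1) {
  stopifnot(is(chain, "LatentStateChain"))
  nFrames <- as.integer(nFrames)
  if (nFrames < 1) stop("nFrames must be >= 1")
  K <- nrow(chain@transition)
  set.seed(seed)
  labels <- integer(nFrames)
  labels[1] <- sample.int(K, 1, prob = chain@initial)
  if (nFrames > 1) {
    u <- stats::runif(nFrames - 1)
    cum <- t(apply(chain@transition, 1, cumsum))
    for (t in 2:nFrames) {
      labels[t] <- findInterval(u[t - 1], cum[labels[t - 1], ],
                                left.open = TRUE) + 1L
    }
  }
  labels
}

#' Generate state-conditional dihedral time series
#'
#' Coupled residues sample (phi, psi) from the von Mises pair indexed by each
#' frame's latent state; uncoupled residues ignore the labels. Each residue
#' draws from its own seeded substream.
#'
#' @param model a \linkS4class{DihedralModel}.
#' @param labels per-frame latent-state labels (1..K).
#' @param seed integer seed.
#' @return a \linkS4class{DihedralSeries}.
#' @export
genDihedralSeries <- function(model, labels, seed = 1) {
  stopifnot(is(model, "DihedralModel"))
  labels <- as.integer(labels)
  K <- ncol(model@muPhi)
  if (any(labels < 1L | labels > K))
    stop("labels reference states without parameters")
  nF <- length(labels)
  R <- length(model@residues)
  phi <- matrix(NA_real_, nF, R)
  psi <- matrix(NA_real_, nF, R)
  for (i in seq_len(R)) {
    set.seed(.subSeed(seed, model@residues[i]))
    if (model@coupled[i]) {
      for (k in sort(unique(labels))) {
        idx <- which(labels == k)
        phi[idx, i] <- rVonMises(length(idx), model@muPhi[i, k], model@kappaPhi[i, k])
        psi[idx, i] <- rVonMises(length(idx), model@muPsi[i, k], model@kappaPsi[i, k])
      }
    } else {
      phi[, i] <- rVonMises(nF, model@muPhi[i, 1], model@kappaPhi[i, 1])
      psi[, i] <- rVonMises(nF, model@muPsi[i, 1], model@kappaPsi[i, 1])
    }
  }
  new("DihedralSeries", residues = model@residues, phi = phi, psi = psi)
}

#' Generate a state-conditional distance series
#'
#' Gaussian draws conditioned on each frame's latent state, truncated at zero
#' by resampling.
#'
#' @param stateMeans per-state mean distances (Angstrom, positive).
#' @param stateSds per-state standard deviations (Angstrom, positive).
#' @param labels per-frame state labels (1..K).
#' @param seed integer seed.
#' @return numeric distance sequence (Angstrom).
#' @export
genDistanceSeries <- function(stateMeans, stateSds, labels, seed = 1) {
  if (length(stateSds) == 1) stateSds <- rep(stateSds, length(stateMeans))
  if (length(stateMeans) != length(stateSds))
    stop("one (mean, sd) pair per state required")
  if (any(stateMeans <= 0)) stop("state means must be positive")
  if (any(stateSds <= 0)) stop("state sds must be positive")
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > length(stateMeans)))
    stop("labels reference states without parameters")
  set.seed(seed)
  d <- stats::rnorm(length(labels), stateMeans[labels], stateSds[labels])
  bad <- which(d <= 0)
  while (length(bad)) {
    d[bad] <- stats::rnorm(length(bad), stateMeans[labels[bad]], stateSds[labels[bad]])
    bad <- bad[d[bad] <= 0]
  }
  d
}

#' Generate a latent-mode coordinate trajectory
#'
#' frame_t = mean + sum_k a_k(t) * mode_k + noise with a_k(t) ~ N(0, sd_k^2);
#' no global rotation or translation is applied. Atoms are exported as one
#' pseudo-CA per residue.
#'
#' @param model a \linkS4class{ModeTrajectoryModel}.
#' @param nFrames number of frames (>= 2).
#' @param seed integer seed.
#' @return a \linkS4class{Trajectory} (atom names "CA", residue ids 1..A).
#' @export
genModeTrajectory <- function(model, nFrames, seed = 1) {
  stopifnot(is(model, "ModeTrajectoryModel"))
  nFrames <- as.integer(nFrames)
  if (nFrames < 2) stop("nFrames must be >= 2")
  A <- nrow(model@meanCoords)
  M <- dim(model@modes)[3]
  set.seed(seed)
  amp <- matrix(stats::rnorm(nFrames * M), nFrames, M) %*% diag(model@amplitudeSd, M)
  V <- matrix(model@modes, nrow = A * 3, ncol = M)  # columns are flattened modes
  flat <- amp %*% t(V)                              # F x (A*3)
  if (model@noiseSd > 0)
    flat <- flat + stats::rnorm(length(flat), 0, model@noiseSd)
  xyz <- array(0, c(nFrames, A, 3))
  for (j in 1:3)
    xyz[, , j] <- flat[, (j - 1) * A + seq_len(A)] +
      matrix(model@meanCoords[, j], nFrames, A, byrow = TRUE)
  top <- data.frame(index = seq_len(A), residue_id = seq_len(A),
                    atom_name = "CA", stringsAsFactors = FALSE)
  new("Trajectory", coords = xyz, topology = top)
}

#' Generate a mono-exponential decay curve
#'
#' I(t) = I0 * exp(-rate * t) + Gaussian noise.
#'
#' @param rate decay rate (per unit time, >= 0).
#' @param times non-negative, increasing time points.
#' @param noiseSd noise sd (intensity units).
#' @param seed integer seed.
#' @param I0 initial intensity.
#' @return data.frame with columns time, intensity.
#' @export
genDecayCurve <- function(rate, times, noiseSd = 0, seed = 1, I0 = 1) {
  if (rate < 0) stop("rate must be >= 0")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and increasing")
  set.seed(seed)
  I <- I0 * exp(-rate * times)
  if (noiseSd > 0) I <- I + stats::rnorm(length(times), 0, noiseSd)
  data.frame(time = times, intensity = I)
}

#' The seven-delay transverse-relaxation time grid
#'
#' Delays 17.6 to 228.8 ms in arithmetic steps of 35.2 ms, in seconds.
#' @return numeric vector of length 7 (seconds).
#' @export
r2DelayGrid <- function() seq(17.6, 228.8, by = 35.2) / 1000

#' Generate a sigmoidal pH-unfolding titration curve
#'
#' S(pH) = S_folded + (S_unfolded - S_folded)/(1 + 10^(slope*(pH - midpoint)))
#' plus Gaussian noise. With positive slope the signal approaches the folded
#' baseline at high pH (acid-unfolded convention).
#'
#' @param midpointPH transition midpoint (pH units).
#' @param slope base-10 logistic slope (nonzero).
#' @param baselines c(folded, unfolded) signal levels.
#' @param pHPoints increasing pH values.
#' @param noiseSd noise sd (signal units).
#' @param seed integer seed.
#' @return data.frame with columns pH, signal.
#' @export
genTitration <- function(midpointPH, slope = 1.5, baselines = c(1, 0.3),
                         pHPoints = seq(3, 6, length.out = 20),
                         noiseSd = 0, seed = 1) {
  if (slope == 0) stop("slope must be nonzero")
  if (any(diff(pHPoints) <= 0)) stop("pH points must be increasing")
  set.seed(seed)
  sF <- baselines[1]
  sU <- baselines[2]
  S <- sF + (sU - sF) / (1 + 10^(slope * (pHPoints - midpointPH)))
  if (noiseSd > 0) S <- S + stats::rnorm(length(S), 0, noiseSd)
  data.frame(pH = pHPoints, signal = S)
}
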