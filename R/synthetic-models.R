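#' Construct a two-state pressure-response shift model
#'
#' @param residues integer residue ids.
#' @param slopeH,slopeN compression slopes, ppm/MPa (recycled).
#' @param ampH,ampN transition amplitudes, ppm (recycled).
#' @param deltaH0,deltaN0 reference shifts at 0 MPa, ppm (recycled).
#' @param dG0 free-energy difference (excited minus ground) at 0 MPa, J/mol.
#' @param dV volume difference, mL/mol.
#' @param temperature kelvin.
#' @param residueNames optional one-letter codes.
#' @return a \linkS4class{TwoStateShiftModel}.
#' @export
twoStateShiftModel <- function(residues, slopeH = 0, slopeN = 0,
                               ampH = 0, ampN = 0,
                               deltaH0 = 8.3, deltaN0 = 120,
                               dG0 = 15000, dV = -100, temperature = 298,
                               residueNames = NA_character_) {
  residues <- as.integer(residues)
  n <- length(residues)
  new("TwoStateShiftModel",
    residues = residues,
    residueNames = rep_len(as.character(residueNames), n),
    slopeH = rep_len(as.numeric(slopeH), n),
    slopeN = rep_len(as.numeric(slopeN), n),
    ampH = rep_len(as.numeric(ampH), n),
    ampN = rep_len(as.numeric(ampN), n),
    deltaH0 = rep_len(as.numeric(deltaH0), n),
    deltaN0 = rep_len(as.numeric(deltaN0), n),
    dG0 = as.numeric(dG0), dV = as.numeric(dV),
    temperature = as.numeric(temperature)
  )
}

#' Excited-state population under pressure
#'
#' f_E(p) = 1/(1 + exp((dG0 + p*dV)/(R*T))), the Boltzmann population of the
#' excited state for a two-state equilibrium whose free-energy gap varies
#' linearly with pressure. With dV < 0 the population grows with pressure.
#'
#' @param model a \linkS4class{TwoStateShiftModel}.
#' @param p pressure(s), MPa.
#' @return population(s) in [0, 1].
#' @export
excitedPopulation <- function(model, p) {
  stopifnot(is(model, "TwoStateShiftModel"))
  1 / (1 + exp((model@dG0 + p * model@dV) / (.R_GAS * model@temperature)))
}

#' Construct a latent-state Markov chain
#'
#' @param transition K x K row-stochastic matrix.
#' @param initial initial distribution (default stationary distribution of
#'   \code{transition}).
#' @return a \linkS4class{LatentStateChain}.
#' @export
latentStateChain <- function(transition, initial = NULL) {
  transition <- as.matrix(transition)
  if (is.null(initial)) initial <- stationaryDistribution(transition)
  new("LatentStateChain", transition = transition, initial = as.numeric(initial))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solved as the left eigenvector of eigenvalue 1, normalised to sum to one.
#'
#' @param P row-stochastic K x K matrix.
#' @return numeric vector of stationary probabilities.
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Construct a state-conditional von Mises dihedral model
#'
#' @param residues integer residue ids.
#' @param coupled logical per residue; uncoupled residues must carry
#'   state-invariant parameters.
#' @param muPhi,muPsi R x K circular means (degrees).
#' @param kappaPhi,kappaPsi R x K concentrations.
#' @return a \linkS4class{DihedralModel}.
#' @export
dihedralModel <- function(residues, coupled, muPhi, muPsi, kappaPhi, kappaPsi) {
  as2 <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  new("DihedralModel",
    residues = as.integer(residues), coupled = as.logical(coupled),
    muPhi = as2(muPhi), muPsi = as2(muPsi),
    kappaPhi = as2(kappaPhi), kappaPsi = as2(kappaPsi)
  )
}

#' Construct a latent-mode trajectory model
#'
#' @param meanCoords A x 3 mean structure (Angstrom).
#' @param modes A x 3 x M array of orthonormal mode vectors.
#' @param amplitudeSd per-mode amplitude sd (Angstrom).
#' @param noiseSd isotropic coordinate noise sd (Angstrom).
#' @return a \linkS4class{ModeTrajectoryModel}.
#' @export
modeTrajectoryModel <- function(meanCoords, modes, amplitudeSd, noiseSd = 0) {
  if (length(dim(modes)) == 2) dim(modes) <- c(dim(modes), 1)
  new("ModeTrajectoryModel",
    meanCoords = as.matrix(meanCoords), modes = modes,
    amplitudeSd = as.numeric(amplitudeSd), noiseSd = as.numeric(noiseSd)
  )
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) acceptance-rejection sampler; falls back to uniform for
#' very small concentrations.
#'
#' @param n number of draws.
#' @param mu circular mean, degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees, wrapped to (-180, 180].
#' @export
rVonMises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrapAngle(stats::runif(n, -180, 180) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    u3 <- stats::runif(sum(ok))
    out <- c(out, sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
  }
  wrapAngle(mu + out[seq_len(n)] * 180 / pi)
}
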