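## independent brute-force chi-squared oracle: explicit double loop over all
## (phi_i, psi_j) cells, summed in column-major order
chi2Brute <- function(f1, f2) {
  n <- nrow(f1)
  terms <- numeric(n * n)
  for (j in seq_len(n))
    for (i in seq_len(n))
      terms[(j - 1) * n + i] <- (f1[i, j] - f2[i, j])^2
  sum(terms) / n^2
}

cosSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

## small two-state model used across tests
makeModel <- function(n = 5, slopeH = 0, slopeN = 0, ampH = 0, ampN = 0,
                      dG0 = 15000, dV = -100) {
  twoStateShiftModel(seq_len(n), slopeH = slopeH, slopeN = slopeN,
                     ampH = ampH, ampN = ampN,
                     deltaH0 = 8 + seq_len(n) / 10,
                     deltaN0 = 110 + seq_len(n),
                     dG0 = dG0, dV = dV)
}

## random normalized 10x10 histogram carrying the standard bin attributes
randomHistogram <- function() {
  H <- matrix(stats::runif(100), 10, 10)
  H <- H / sum(H)
  attr(H, "edges") <- seq(-180, 180, by = 36)
  attr(H, "n") <- 100L
  H
}

## four-atom trajectory with a prescribed torsion angle (degrees)
torsionFixture <- function(angleDeg) {
  a <- angleDeg * pi / 180
  xyz <- array(0, c(1, 4, 3))
  xyz[1, , ] <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                      c(0, cos(a), sin(a)))
  trajectory(xyz, data.frame(index = 1:4, residue_id = c(1L, 2L, 2L, 2L),
                             atom_name = c("C", "N", "CA", "C")))
}

## rotation matrix about z by theta radians
rotZ <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
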