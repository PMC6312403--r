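# Shared fixtures and independent numeric oracles for the test suite.

# The canonical 50 x 10 nm grid at tau = 0.008 per nm used throughout
# the worked examples.
canonicalGrid <- function() illuminationProfile(0.008)
canonicalResting <- function() solveRestingDensity(canonicalGrid())

# Independent oracle for the resting density: numeric root-find on
# F_initial(m) - 1 = 0 instead of the closed form.
oracleRestingDensity <- function(grid) {
  S <- sum(illumination(grid))
  uniroot(function(m) m * S - 1, c(1e-8, 10), tol = 1e-14)$root
}

# Independent oracle for delta-m: root-find on the scenario equation
# written out layer by layer.
oracleDeltaM <- function(F, resting, scenario) {
  I <- illumination(layerGrid(resting))
  N <- nLayers(layerGrid(resting))
  m <- restingDensity(resting)
  f <- function(dm) {
    if (scenario == "fixed_total")
      dm * I[1] + sum((m - dm / N) * I) - F
    else
      (m + dm) * I[1] + sum(m * I[-1]) - F
  }
  uniroot(f, c(-100, N * m + 100), tol = 1e-13)$root
}

# Exact two-sided rank-sum p by full enumeration of rank assignments
# (tie-free data only; two-sided by symmetry of the null about its mean).
oracleRankSumP <- function(a, b) {
  pooled <- rank(c(a, b))
  na <- length(a)
  obsW <- sum(pooled[seq_len(na)]) - na * (na + 1) / 2
  allW <- apply(combn(length(pooled), na), 2,
                function(ix) sum(pooled[ix]) - na * (na + 1) / 2)
  mu <- mean(allW)
  min(1, mean(abs(allW - mu) >= abs(obsW - mu) - 1e-9))
}

# A tiny deterministic stack: constant background, footprint following a
# supplied fold-change trajectory.
noiselessRender <- function(foldChangeTarget, resting = canonicalResting(),
                            times = seq(-120, 480, 10)) {
  kp <- kineticParams(solveDeltaM(foldChangeTarget, resting),
                      delay = 0, riseTau = 1e-6, plateauFraction = 1)
  renderStack(kp, resting, times, noise = NULL)
}
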