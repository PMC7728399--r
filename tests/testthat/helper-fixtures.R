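# shared fixtures, all generated in code

nominalMix <- function(epsilon = 0.04) GeneMix(epsilon = epsilon)

degenerateMultiplicity <- function(m = 10) {
  MultiplicityModel("lognormal", muM = log(m), sigmaM = 0)
}

# brute-force kernel-density mode oracle: locations of local maxima of a
# KDE, strongest first, pruned at a relative height threshold
kdeModes <- function(x, bw = 0.08, minRelHeight = 0.1) {
  d <- density(x, bw = bw, n = 1024)
  y <- d$y
  n <- length(y)
  isMax <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  pk <- which(isMax & y > minRelHeight * max(y))
  d$x[pk[order(y[pk], decreasing = TRUE)]]
}

# tiny transient circuit run shared by several tests
smallCircuitFrames <- function(topology = "FO", sigma = 0.08,
                               nCellsPerDox = 3000, nDox = 6, seed = 42) {
  spec <- buildCircuit(topology)
  simulateTransientCircuit(spec, sigma = sigma,
                           dox = doxGrid(nDox),
                           nCellsPerDox = nCellsPerDox, seed = seed)
}
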