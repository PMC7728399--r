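test_that("topologies are knockout variants of one shared map", {
  fo <- buildCircuit("FO")
  ri <- buildCircuit("RIFFM")
  expect_false(fo@kniActive || fo@laciActive)
  expect_true(ri@kniActive && ri@laciActive)
  rt <- merge(reactionTable(fo), reactionTable(ri), by = "reaction",
              suffixes = c(".fo", ".ri"))
  diffed <- rt$reaction[rt$rate.fo != rt$rate.ri]
  expect_setequal(diffed, c("mRNA2 -> mRNA2 + Kni", "mRNA3 -> mRNA3 + LacI"))
  i1 <- buildCircuit("I1FFL1"); i2 <- buildCircuit("I1FFL2")
  expect_true(i1@kniActive && !i1@laciActive)
  expect_true(!i2@kniActive && i2@laciActive)
  expect_error(buildCircuit("ring"), "unknown topology")
  expect_error(buildCircuit("FO", params = list(dm = 1)), "missing rate")
})

test_that("zero gene copies give zero readouts", {
  spec <- buildCircuit("FO")
  o <- simulateCell(spec, rep(0, 5), dox = 1000)
  expect_equal(unname(as.numeric(o)), rep(0, 5))
})

test_that("FO outputs are non-decreasing in Dox", {
  spec <- buildCircuit("FO")
  K <- matrix(c(10, 13, 8, 5, 4), 1, 5, byrow = TRUE)
  colnames(K) <- paste0("k", 1:5)
  P <- matrix(unlist(spec@params[translationNames()]), 1, 8, byrow = TRUE)
  colnames(P) <- translationNames()
  out <- t(vapply(doxGrid(), function(d)
    as.numeric(circuitSteadyState(spec, K, P, d)), numeric(5)))
  expect_true(all(diff(out[, 2]) >= 0))   # Cerulean
  expect_true(all(diff(out[, 3]) >= 0))   # Citrine
  expect_gt(out[12, 2] / out[1, 2], 5)    # genuine activation
})

test_that("vectorized steady-state solver matches full ODE integration", {
  mix <- nominalMix()
  m <- sampleMultiplicity(MultiplicityModel(), 6, seed = 5)
  K <- sampleCopyNumbers(m, mix, seed = 5)
  for (topo in c("FO", "RIFFM", "I1FFL1")) {
    spec <- buildCircuit(topo)
    nm <- unlist(spec@params[translationNames()])
    P <- sampleExpressionScalars(
      NoiseModel(0.08, nominalMeans = nm), 6, seed = 5)
    for (dox in c(100, 1e4)) {
      Ored <- circuitSteadyState(spec, K, P, dox)
      for (j in 1:6) {
        o <- simulateCell(spec, K[j, ], P[j, ], dox)
        expect_true(attr(o, "converged"))
        expect_equal(as.numeric(Ored[j, ]), as.numeric(o),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("disabling RIFFM repressor translation recovers FO", {
  fo <- buildCircuit("FO")
  ri <- buildCircuit("RIFFM")
  K <- matrix(c(10, 13, 8, 5, 4), 2, 5, byrow = TRUE)
  colnames(K) <- paste0("k", 1:5)
  P <- matrix(unlist(fo@params[translationNames()]), 2, 8, byrow = TRUE)
  colnames(P) <- translationNames()
  P[, c("pi_kni", "pi_laci")] <- 0      # knockout via zeroed translation
  expect_equal(circuitSteadyState(ri, K, P, 1e4),
               circuitSteadyState(fo, K, P, 1e4), tolerance = 1e-10)
})

test_that("single-plasmid noise-free cells are identical within a dox level", {
  spec <- buildCircuit("RIFFM")
  frames <- simulateTransientCircuit(
    spec, mix = GeneMix(epsilon = 0),
    multiplicity = degenerateMultiplicity(10),
    sigma = 0, dox = c(100, 1e4), nCellsPerDox = 20, seed = 6)
  for (fr in frames) {
    d <- cells(fr)
    for (ch in channelNames(fr))
      expect_equal(length(unique(d[[ch]])), 1L)
  }
})

test_that("the reference channel is invariant across Dox levels", {
  frames <- smallCircuitFrames("FO", nCellsPerDox = 4000, nDox = 4)
  mus <- vapply(frames, function(f)
    mean(safeLog(channelValues(f, "SBFP2"))), numeric(1))
  expect_lt(diff(range(mus)), 0.1)
})

test_that("stable designs mirror bin copy modes and nominal ratios", {
  ## degenerate run: every cell has m = 10, so k = 10 * a exactly
  spec <- buildCircuit("FO")
  frames <- simulateTransientCircuit(
    spec, mix = GeneMix(epsilon = 0),
    multiplicity = degenerateMultiplicity(10),
    sigma = 0.04, dox = 1e4, nCellsPerDox = 1000, seed = 7)
  fr <- frames[[1]]
  v <- channelValues(fr, "SBFP2")
  bins <- binByReference(fr, edges = c(min(v) * 0.9, max(v) * 1.1))
  designs <- stableCopyNumbersFromBins(fr, bins, GeneMix(epsilon = 0))
  expect_length(designs, 1L)
  expect_equal(designs[[1]]@k, 10 * c(1.0, 1.3, 0.8, 0.5, 0.4),
               tolerance = 1e-6)
  ## ratio forced by construction
  expect_equal(designs[[1]]@k[2] / designs[[1]]@k[1], 1.3)
})

test_that("copy-mode estimator agrees with a histogram-mode oracle", {
  set.seed(8)
  x <- rlnorm(2e4, log(10), 0.2)
  est <- distributionMode(x)
  oracle <- kdeModes(x, bw = 0.5)[1]
  expect_equal(est, oracle, tolerance = 0.1)
})

test_that("stable simulations collapse to a curve at sigma zero and widen with sigma", {
  spec <- buildCircuit("FO")
  dsg <- new("StableDesign", k = 10 * c(1, 1.3, 0.8, 0.5, 0.4),
             bin = 1L, y1 = log(1e4))
  f0 <- simulateStableCircuit(spec, dsg, sigma = 0, dox = c(1e4),
                              nCellsPerDox = 50, seed = 9)[[1]]
  expect_equal(length(unique(channelValues(f0, "Cerulean"))), 1L)
  ## the sigma = 0 mode equals the deterministic cell readout exactly
  o <- simulateCell(spec, dsg@k, dox = 1e4)
  expect_equal(channelValues(f0, "Cerulean")[1], unname(o["Cerulean"]),
               tolerance = 1e-6)
  spread <- vapply(c(0.04, 0.16, 0.32), function(s) {
    f <- simulateStableCircuit(spec, dsg, sigma = s, dox = c(1e4),
                               nCellsPerDox = 400, seed = 9)[[1]]
    sd(safeLog(channelValues(f, "Cerulean")))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
  ## determinism
  f1 <- simulateStableCircuit(spec, dsg, sigma = 0.08, dox = c(1e4),
                              nCellsPerDox = 100, seed = 10)[[1]]
  f2 <- simulateStableCircuit(spec, dsg, sigma = 0.08, dox = c(1e4),
                              nCellsPerDox = 100, seed = 10)[[1]]
  expect_identical(cells(f1), cells(f2))
})
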