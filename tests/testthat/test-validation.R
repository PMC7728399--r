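test_that("identical and anti-ordered mode vectors give rho of 1 and -1", {
  mk <- function(vals) data.frame(
    bin = seq_along(vals), dox = 1, channel = "Cerulean",
    inputBranch = "HIGH", inputMode = seq_along(vals),
    outputBranch = "HIGH", outputMode = vals, weight = 1)
  st <- function(vals) data.frame(
    design = seq_along(vals), dox = 1, channel = "Cerulean",
    branch = "HIGH", mode = vals, weight = 1)
  up <- c(1, 2, 3, 4)
  cc <- correlateModes(mk(up), st(up), channels = "Cerulean")
  expect_equal(cc$rho, 1)
  cc2 <- correlateModes(mk(up), st(rev(up)), channels = "Cerulean")
  expect_equal(cc2$rho, -1)
  expect_error(correlateModes(mk(up[1:2]), st(up[1:2]),
                              channels = "Cerulean"), "matched pairs")
})

test_that("stable mode extraction recovers the deterministic steady state", {
  spec <- buildCircuit("FO")
  dsg <- new("StableDesign", k = 10 * c(1, 1.3, 0.8, 0.5, 0.4),
             bin = 1L, y1 = log(1e4))
  frames <- simulateStableCircuit(spec, dsg, sigma = 0.02,
                                  dox = c(1e4), nCellsPerDox = 2000,
                                  seed = 1)
  sm <- extractStableModes(frames)
  o <- simulateCell(spec, dsg@k, dox = 1e4)
  for (ch in c("Cerulean", "Citrine")) {
    got <- sm$mode[sm$channel == ch]
    expect_length(got, 1L)
    expect_equal(got, biexpTransform(unname(o[ch])), tolerance = 0.05)
  }
})

test_that("a bimodal stable run yields two output modes in the bimodal range", {
  spec <- buildCircuit("RIFFM")
  dsg <- new("StableDesign", k = 8 * c(1, 1.3, 0.8, 0.5, 0.4),
             bin = 1L, y1 = log(8e3))
  frames <- simulateStableCircuit(spec, dsg, sigma = 0.16,
                                  dox = doxGrid()[8], nCellsPerDox = 3000,
                                  seed = 2)
  sm <- extractStableModes(frames)
  expect_gte(max(table(sm$channel)), 2L)
})

test_that("transient curves track the stable cloud end to end", {
  ## scaled-down pipeline at one noise level; the pooled correlation must
  ## already be high and the peak-finder points must sit inside the stable
  ## percentile band
  res <- runValidation(topologies = "FO", sigmas = 0.08,
                       nCellsPerDox = 4000, nStablePerDox = 300,
                       nBins = 5, seed = 3)
  expect_true(all(res$rho$rho > 0.9))
  ## band coverage for one bin: stable 2.5-97.5 display band per dox
  spec <- buildCircuit("FO")
  io <- res$io[res$io$channel == "Cerulean", ]
  b <- 3L
  covered <- 0L; total <- 0L
  frames <- simulateTransientCircuit(spec, sigma = 0.08, dox = doxGrid(),
                                     nCellsPerDox = 4000, seed = 3)
  pooled <- poolFrames(frames)
  bins <- binByReference(pooled, nBins = 5)
  designs <- suppressWarnings(stableCopyNumbersFromBins(pooled, bins,
                                                        GeneMix()))
  dsg <- designs[[b]]
  sframes <- simulateStableCircuit(spec, dsg, sigma = 0.08,
                                   dox = doxGrid(), nCellsPerDox = 300,
                                   seed = 3)
  for (l in seq_along(sframes)) {
    dox <- sframes[[l]]@metadata$dox
    band <- quantile(biexpTransform(channelValues(sframes[[l]],
                                                  "Cerulean")),
                     c(0.025, 0.975))
    pts <- io$outputMode[io$bin == b & io$dox == dox]
    total <- total + length(pts)
    covered <- covered + sum(pts >= band[1] - 0.05 &
                               pts <= band[2] + 0.05)
  }
  expect_gte(covered / total, 0.9)
})
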