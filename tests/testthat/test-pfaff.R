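test_that("equal-count binning trims tails and balances events", {
  set.seed(1)
  d <- data.frame(SBFP2 = runif(1000, 10, 1e4))
  fr <- PopulationFrame(d, channels = "SBFP2",
                        metadata = list(referenceChannel = "SBFP2"))
  bins <- binByReference(fr, nBins = 10, tailFraction = 0.025)
  counts <- tabulate(bins@assignment, 10)
  expect_true(all(abs(counts - 95) <= 1))
  expect_true(all(diff(bins@medianY) > 0))
  expect_error(binByReference(fr[1:5], nBins = 10), "fewer events")
})

test_that("mode finder matches the kernel-density oracle on mixtures", {
  set.seed(2)
  ## single component
  x1 <- rnorm(1e4, 2, 0.15)
  m1 <- fitModes(x1, inputFitRules())
  expect_equal(nrow(m1), 1L)
  expect_lt(abs(m1$mode - kdeModes(x1)[1]), 0.05)
  expect_lt(abs(m1$mode - 2), 0.02)
  ## well-separated pair, both rule sets
  for (rules in list(inputFitRules(), outputFitRules())) {
    x2 <- c(rnorm(5e3, 1.5, 0.2), rnorm(5e3, 3.0, 0.2))
    m2 <- fitModes(x2, rules)
    expect_equal(nrow(m2), 2L)
    expect_equal(sort(m2$mode), sort(kdeModes(x2)[1:2]), tolerance = 0.05)
    expect_identical(m2$branch, c("LOW", "HIGH"))
    expect_true(m2$mode[m2$branch == "HIGH"] >
                  m2$mode[m2$branch == "LOW"])
  }
  ## three components, separations >= 1: at most two are reported
  x3 <- c(rnorm(4e3, 1, 0.15), rnorm(4e3, 2.2, 0.15), rnorm(4e3, 3.4, 0.15))
  m3 <- fitModes(x3, inputFitRules())
  expect_lte(nrow(m3), 2L)
})

test_that("modes closer than 0.75 collapse to a single call", {
  set.seed(3)
  x <- c(rnorm(5e3, 2.0, 0.2), rnorm(5e3, 2.5, 0.2))
  expect_equal(nrow(fitModes(x, inputFitRules())), 1L)
  ## sweep through the threshold: wide separation keeps two calls
  x2 <- c(rnorm(5e3, 2.0, 0.15), rnorm(5e3, 3.3, 0.15))
  expect_equal(nrow(fitModes(x2, inputFitRules())), 2L)
})

test_that("sparse slices are skipped, not fitted", {
  expect_warning(m <- fitModes(rnorm(50), inputFitRules()), "events")
  expect_equal(nrow(m), 0L)
})

test_that("slice windows match a naive scan", {
  set.seed(4)
  d <- data.frame(SBFP2 = rlnorm(2000, 8, 1), Cerulean = rlnorm(2000, 6, 1))
  fr <- PopulationFrame(d, channels = c("SBFP2", "Cerulean"),
                        metadata = list(referenceChannel = "SBFP2"))
  ctr <- 2.5
  sl <- sliceWindow(fr, "Cerulean", ctr, 0.1)
  naive <- sum(abs(biexpTransform(d$Cerulean) - ctr) <= 0.1)
  expect_equal(nCells(sl), naive)
  ## degenerate windows
  d2 <- data.frame(SBFP2 = rep(100, 5), Cerulean = rep(100, 5))
  fr2 <- PopulationFrame(d2, channels = c("SBFP2", "Cerulean"))
  ctr2 <- biexpTransform(100)
  expect_equal(nCells(sliceWindow(fr2, "Cerulean", ctr2, 0.1)), 5L)
  expect_equal(nCells(sliceWindow(fr2, "Cerulean", ctr2 + 5, 0.1)), 0L)
})

test_that("a monomodal circuit yields one point per bin and dox", {
  frames <- smallCircuitFrames("FO", nCellsPerDox = 4000, nDox = 5)
  io <- extractIOPoints(frames, nBins = 5)
  cnt <- table(paste(io$bin, io$dox, io$channel))
  expect_true(all(cnt == 1))
  ## pooled curve is monotone in the input for each bin
  for (b in unique(io$bin)) {
    sub <- io[io$bin == b & io$channel == "Cerulean", ]
    sub <- sub[order(sub$inputMode), ]
    if (nrow(sub) >= 3)
      expect_true(all(diff(sub$outputMode) > -0.15))
  }
})

test_that("no bin and dox cell ever yields more than four mode pairs", {
  frames <- smallCircuitFrames("RIFFM", sigma = 0.08, nCellsPerDox = 4000,
                               nDox = 5)
  io <- extractIOPoints(frames, nBins = 5)
  cnt <- table(paste(io$bin, io$dox, io$channel))
  expect_true(all(cnt <= 4))
  ## the bimodal circuit produces two output branches somewhere
  expect_true(any(cnt >= 2))
})

test_that("pooled curves are insensitive to the bin count", {
  frames <- smallCircuitFrames("FO", nCellsPerDox = 6000, nDox = 4,
                               seed = 11)
  fits <- lapply(c(5L, 10L), function(nb) {
    io <- extractIOPoints(frames, nBins = nb)
    io <- io[io$channel == "Cerulean", ]
    ## pooled high-branch curve evaluated by local regression
    stats::lowess(io$inputMode, io$outputMode, f = 0.5)
  })
  ## compare on the interior of the shared input range, where both curve
  ## estimates are supported by points
  lo <- max(quantile(fits[[1]]$x, 0.1), quantile(fits[[2]]$x, 0.1))
  hi <- min(quantile(fits[[1]]$x, 0.9), quantile(fits[[2]]$x, 0.9))
  g <- seq(lo, hi, length.out = 20)
  y1 <- approx(fits[[1]]$x, fits[[1]]$y, g, ties = mean)$y
  y2 <- approx(fits[[2]]$x, fits[[2]]$y, g, ties = mean)$y
  expect_lt(median(abs(y1 - y2), na.rm = TRUE), 0.15)
})
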