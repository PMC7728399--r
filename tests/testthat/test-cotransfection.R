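test_that("constitutive steady state is beta * k", {
  expect_equal(steadyStateConstitutive(10, bBar = 5, delta = 0.5), 100)
  expect_equal(steadyStateConstitutive(0, bBar = 5, delta = 0.5), 0)
  expect_equal(steadyStateConstitutive(13, bBar = 1000, delta = 1), 13000)
  expect_error(steadyStateConstitutive(1, 1, 0), "delta")
})

test_that("a noise-free co-transfection is fully deterministic", {
  fr <- simulateCotransfection(
    mix = GeneMix(epsilon = 0),
    multiplicity = degenerateMultiplicity(10),
    noise = NoiseModel(0, nominalMeans = rep(1000, 5)),
    nCells = 50, seed = 1)
  a <- c(1.0, 1.3, 0.8, 0.5, 0.4)
  for (i in 1:5) {
    v <- channelValues(fr, cotransfectionChannels()[i])
    expect_length(unique(v), 1L)
    expect_equal(v[1], 1000 * a[i] * 10)
  }
})

test_that("channel means match the product of closed-form means", {
  fr <- simulateCotransfection(nCells = 1e5, seed = 2)
  a <- fr@metadata$abundances
  Em <- exp(1.4979 + 1.2686^2 / 2)
  for (i in 1:5) {
    ch <- cotransfectionChannels()[i]
    expect_equal(mean(channelValues(fr, ch)), 1000 * a[i] * Em,
                 tolerance = 0.05)
  }
})

test_that("identical seeds reproduce identical frames", {
  f1 <- simulateCotransfection(nCells = 500, seed = 3)
  f2 <- simulateCotransfection(nCells = 500, seed = 3)
  expect_identical(cells(f1), cells(f2))
})

test_that("log-space conditional spread equals sigma when copies are fixed", {
  fr <- simulateCotransfection(
    mix = GeneMix(epsilon = 0),
    multiplicity = degenerateMultiplicity(10),
    noise = NoiseModel(0.08, nominalMeans = rep(1000, 5)),
    nCells = 5e4, seed = 4)
  for (ch in cotransfectionChannels())
    expect_equal(sd(safeLog(channelValues(fr, ch))), 0.08,
                 tolerance = 0.02)
})

test_that("binned conditional noise sigma* dominates sigma", {
  fr <- simulateCotransfection(nCells = 1e5, seed = 5)
  bins <- binByReference(fr, nBins = 10, tailFraction = 0.025)
  for (ch in cotransfectionChannels()[-1]) {
    sStar <- conditionalSigma(fr, bins, ch)
    expect_true(all(sStar >= 0.08, na.rm = TRUE))
  }
})
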