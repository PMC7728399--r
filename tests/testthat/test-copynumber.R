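test_that("anticipated copy numbers follow exp(Y1)/beta1 * a", {
  expect_equal(anticipatedCopyNumber(log(10 * 1000), 1000), 10)
  expect_equal(anticipatedCopyNumber(log(10 * 1000), 1000, a = 1.3), 13)
  expect_equal(anticipatedCopyNumber(log(10 * 1000), 1000, a = 0.4), 4)
  expect_error(anticipatedCopyNumber(1, 0), "beta1")
})

test_that("noise-free copy modes are exact", {
  fr <- simulateCotransfection(
    mix = GeneMix(epsilon = 0),
    multiplicity = degenerateMultiplicity(10),
    noise = NoiseModel(0, nominalMeans = rep(1000, 5)),
    nCells = 500, seed = 1)
  v <- channelValues(fr, "SBFP2")
  bins <- binByReference(fr, edges = c(v[1] * 0.9, v[1] * 1.1))
  em <- empiricalCopyModes(fr, bins)
  expect_equal(unname(unlist(em[1, paste0("kMode.k", 1:5)])),
               10 * c(1.0, 1.3, 0.8, 0.5, 0.4))
})

test_that("copy-mode ratio trace changes sign at the global mean", {
  fr <- simulateCotransfection(nCells = 2e5, seed = 2)
  bins <- binByReference(fr, nBins = 30, tailFraction = 0.001,
                         method = "width")
  rep <- suppressWarnings(copyModeRatios(fr, bins))
  mb <- attr(rep, "meanBin")
  rcols <- grep("^ratio\\.", names(rep), value = TRUE)
  below <- rep[rep$bin < mb - 2, rcols]
  above <- rep[rep$bin > mb + 2, rcols]
  expect_true(all(colMeans(below) > 1))
  expect_true(all(colMeans(above) < 1))
  ## anchored at ~1 in the mean bin
  expect_equal(unname(unlist(rep[rep$bin == mb, rcols])), rep(1, 5),
               tolerance = 0.05)
  ## monotone decreasing trace up to Monte-Carlo jitter
  for (rc in rcols)
    expect_lt(cor(rep$bin, rep[[rc]], method = "spearman"), -0.8)
})

test_that("the mode ratio stays near the nominal abundances across bins", {
  fr <- simulateCotransfection(nCells = 2e5, seed = 3)
  bins <- binByReference(fr, nBins = 20, tailFraction = 0.001,
                         method = "width")
  em <- suppressWarnings(empiricalCopyModes(fr, bins))
  a <- fr@metadata$abundances
  for (i in 2:5) {
    ratio <- em[[paste0("kMode.k", i)]] / em[["kMode.k1"]]
    expect_equal(median(ratio), a[i], tolerance = 0.05)
  }
})

test_that("the anchor property survives Poisson and Gamma multiplicity", {
  for (mult in list(MultiplicityModel("poisson", lambda = 10),
                    MultiplicityModel("gamma", shapeK = 0.7436,
                                      scaleTheta = 13.46))) {
    fr <- simulateCotransfection(multiplicity = mult, nCells = 2e5,
                                 seed = 4)
    bins <- binByReference(fr, nBins = 30, tailFraction = 0.001,
                           method = "width")
    rep <- suppressWarnings(copyModeRatios(fr, bins))
    mb <- attr(rep, "meanBin")
    row <- rep[rep$bin == mb, grep("^ratio\\.", names(rep))]
    expect_equal(unname(unlist(row)), rep(1, 5), tolerance = 0.1)
  }
})

test_that("conditional noise sigma* dominates the intrinsic sigma", {
  fr <- simulateCotransfection(nCells = 1e5, seed = 5)
  bins <- binByReference(fr, nBins = 10, tailFraction = 0.025)
  sStar <- conditionalSigma(fr, bins, "Cerulean")
  expect_true(all(sStar >= 0.08, na.rm = TRUE))
  ## and vanishes when every noise source is removed
  fr0 <- simulateCotransfection(
    mix = GeneMix(epsilon = 0),
    multiplicity = degenerateMultiplicity(10),
    noise = NoiseModel(0, nominalMeans = rep(1000, 5)),
    nCells = 1000, seed = 5)
  v <- channelValues(fr0, "SBFP2")
  bins0 <- binByReference(fr0, edges = c(v[1] * 0.9, v[1] * 1.1))
  expect_equal(conditionalSigma(fr0, bins0, "Cerulean"), 0)
})

test_that("divergence metrics vanish for a monomodal circuit", {
  frames <- simulateTransientCircuit(buildCircuit("FO"), sigma = 0.08,
                                     dox = doxGrid()[8],
                                     nCellsPerDox = 2e4, seed = 6)
  fr <- frames[[1]]
  bins <- binByReference(fr, nBins = 10, tailFraction = 0.001,
                         method = "width")
  bm <- suppressWarnings(branchCopyModes(fr, bins))
  expect_true(all(bm$branch == "HIGH"))
  const <- simulateCotransfection(nCells = 5e4, seed = 6)
  dm <- divergenceMetrics(bm, const, bins)
  expect_true(all(dm$deltaKtilde == 0))
  expect_true(all(dm$deltaPhi == 0))
})
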