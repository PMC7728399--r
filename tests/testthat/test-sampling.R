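test_that("lognormal multiplicity reproduces the closed-form mean", {
  model <- MultiplicityModel()          # muM = 1.4979, sigmaM = 1.2686
  m <- sampleMultiplicity(model, 2e5, seed = 1)
  muTrue <- exp(model@muM + model@sigmaM^2 / 2)    # = 10.0
  sdTrue <- muTrue * sqrt(exp(model@sigmaM^2) - 1)
  expect_equal(muTrue, 10, tolerance = 0.01)
  expect_lt(abs(mean(m) - muTrue), 3 * sdTrue / sqrt(length(m)))
  expect_true(all(m > 0))
})

test_that("poisson and gamma multiplicity families hit their means", {
  mp <- sampleMultiplicity(MultiplicityModel("poisson", lambda = 10),
                           2e5, seed = 2)
  expect_lt(abs(mean(mp) - 10), 0.05)
  mg <- sampleMultiplicity(
    MultiplicityModel("gamma", shapeK = 0.7436, scaleTheta = 13.46),
    2e5, seed = 3)
  expect_lt(abs(mean(mg) - 0.7436 * 13.46) / (0.7436 * 13.46), 0.02)
})

test_that("degenerate lognormal multiplicity is exactly constant", {
  m <- sampleMultiplicity(degenerateMultiplicity(10), 100, seed = 4)
  expect_length(unique(m), 1L)
  expect_equal(m[1], 10)
})

test_that("invalid multiplicity configurations are rejected", {
  expect_error(MultiplicityModel("poisson", lambda = NA_real_), "lambda")
  expect_error(MultiplicityModel("gamma", shapeK = -1, scaleTheta = 2),
               "gamma")
  expect_error(sampleMultiplicity(MultiplicityModel(), 0, seed = 1),
               "nCells")
})

test_that("copy numbers collapse to a*m at epsilon zero", {
  mix <- GeneMix(epsilon = 0)
  k <- sampleCopyNumbers(10, mix, seed = 1)
  expect_equal(as.numeric(k), c(10, 13, 8, 5, 4))
})

test_that("copy-number dispersion scales as epsilon * a * m", {
  mix <- nominalMix()
  k <- sampleCopyNumbers(rep(20, 4e4), mix, seed = 5)
  expect_equal(unname(colMeans(k)), 20 * mix@abundances, tolerance = 0.01)
  expect_equal(unname(apply(k, 2, sd)),
               mix@epsilon * mix@abundances * 20, tolerance = 0.03)
  ## epsilon-scaling invariant: sd of k/(a m) converges to epsilon
  rel <- sweep(k, 2, 20 * mix@abundances, "/")
  expect_equal(unname(apply(rel, 2, sd)), rep(mix@epsilon, 5),
               tolerance = 0.03)
})

test_that("non-positive multiplicity is a domain error", {
  expect_error(sampleCopyNumbers(0, nominalMix(), seed = 1), "> 0")
  expect_error(sampleCopyNumbers(-3, nominalMix(), seed = 1), "> 0")
})

test_that("expression draws are mean-preserving for both families", {
  for (fam in c("lognormal", "gamma")) {
    nz <- NoiseModel(0.08, nominalMeans = c(b = 1000), family = fam)
    b <- sampleExpressionScalars(nz, 2e5, seed = 6)
    sdTrue <- 1000 * sqrt(exp(0.08^2) - 1)
    expect_lt(abs(mean(b) - 1000), 3 * sdTrue / sqrt(nrow(b)))
    ## variance matched between families at the same sigma
    expect_equal(sd(b), sdTrue, tolerance = 0.02)
  }
})

test_that("sigma zero gives the nominal values exactly", {
  nz <- NoiseModel(0, nominalMeans = c(a = 5, b = 1000), family = "gamma")
  b <- sampleExpressionScalars(nz, 50, seed = 7)
  expect_true(all(b[, 1] == 5) && all(b[, 2] == 1000))
})

test_that("gamma moment matching solves the stated equations", {
  sig <- 0.08; beta <- 1000
  cv2 <- exp(sig^2) - 1
  shape <- 1 / cv2; scale <- beta * cv2
  expect_equal(shape * scale, beta)
  expect_equal(shape * scale^2, beta^2 * cv2)
})

test_that("samplers are seed-deterministic and prefix-stable", {
  model <- MultiplicityModel()
  expect_identical(sampleMultiplicity(model, 1000, seed = 9),
                   sampleMultiplicity(model, 1000, seed = 9))
  ## growing n keeps the first cells' draws
  m1 <- sampleMultiplicity(model, 100, seed = 9)
  m2 <- sampleMultiplicity(model, 1000, seed = 9)
  expect_identical(m1, m2[1:100])
  k1 <- sampleCopyNumbers(m1, nominalMix(), seed = 9)
  k2 <- sampleCopyNumbers(m2, nominalMix(), seed = 9)
  expect_identical(k1, k2[1:100, ])
  nz <- NoiseModel(0.08, nominalMeans = c(b1 = 10, b2 = 20))
  p1 <- sampleExpressionScalars(nz, 100, seed = 9)
  p2 <- sampleExpressionScalars(nz, 1000, seed = 9)
  expect_identical(p1, p2[1:100, ])
})
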