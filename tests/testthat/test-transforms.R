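test_that("display scale is zero at W and reaches T at the scale top", {
  pr <- biexpParams()
  expect_equal(biexpInverse(pr$W, pr), 0)
  expect_equal(biexpInverse(pr$M, pr), pr$T, tolerance = 3e-4)
})

test_that("display-to-signal transform is strictly increasing", {
  pr <- biexpParams()
  x <- seq(-1, pr$M + 0.5, length.out = 500)
  s <- biexpInverse(x, pr)
  expect_true(all(diff(s) > 0))
})

test_that("display scale is odd-symmetric about W", {
  pr <- biexpParams()
  d <- c(0.1, 0.5, 1, 2, 4)
  expect_equal(biexpInverse(pr$W + d, pr), -biexpInverse(pr$W - d, pr))
})

test_that("forward transform round-trips raw signal values", {
  pr <- biexpParams()
  v <- c(-1e3, 0, 1e2, 1e5, pr$T)
  x <- biexpTransform(v, pr)
  expect_lt(max(abs(biexpInverse(x, pr) - v) / pmax(1, abs(v))), 1e-6)
  expect_equal(biexpTransform(0, pr), pr$W, tolerance = 1e-8)
})

test_that("safeLog clamps at the floor and preserves order", {
  expect_equal(safeLog(exp(1)), 1)
  expect_equal(safeLog(0, floor = 1e-3), log(1e-3))
  expect_equal(safeLog(100, base = "10"), 2)
  v <- c(5, 0, 3, 1e-9, 7)
  expect_identical(order(safeLog(v)), order(pmax(v, 1e-3)))
  expect_message(safeLog(c(0, 1), verbose = TRUE), "clamped 1")
  expect_error(safeLog(1, floor = 0), "floor")
})
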