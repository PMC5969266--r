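test_that("identical curves sit at y = 1 and scaled curves at the scale", {
  ref <- simulateReferenceTac()
  p1 <- patlakTransform(ref, ref)
  expect_true(all(abs(p1$y - 1) < 1e-12))
  two <- new("TimeActivityCurve", frameStart = frameStart(ref),
             frameEnd = frameEnd(ref), activity = 2 * activity(ref))
  p2 <- patlakTransform(two, ref)
  expect_true(all(abs(p2$y - 2) < 1e-12))
  f2 <- fitPatlak(p2)
  expect_equal(ki(f2), 0, tolerance = 1e-12)
  expect_equal(patlakIntercept(f2), 2, tolerance = 1e-12)
})

test_that("the transform and fit are invariant to global activity scaling", {
  ref <- simulateReferenceTac()
  tis <- simulateTissueTac(0.012, ref, vRef = 1.2)
  scale <- function(tac, c)
    new("TimeActivityCurve", frameStart = frameStart(tac),
        frameEnd = frameEnd(tac), activity = c * activity(tac))
  p <- patlakTransform(tis, ref)
  ps <- patlakTransform(scale(tis, 7), scale(ref, 7))
  expect_equal(ps$x, p$x)
  expect_equal(ps$y, p$y)
  expect_equal(ki(fitPatlak(ps)), ki(fitPatlak(p)))
})

test_that("mismatched grids and zero reference activity are rejected", {
  ref <- simulateReferenceTac()
  short <- new("TimeActivityCurve", frameStart = frameStart(ref)[1:5],
               frameEnd = frameEnd(ref)[1:5], activity = activity(ref)[1:5])
  expect_error(patlakTransform(short, ref), "frame grid")
  zero <- new("TimeActivityCurve", frameStart = frameStart(ref),
              frameEnd = frameEnd(ref),
              activity = rep(0, length(activity(ref))))
  expect_error(patlakTransform(ref, zero), "zero on all frames")
})

test_that("collinear points give a perfect fit and short windows fail", {
  pts <- data.frame(mid = seq(25, 85, by = 5))
  pts$x <- pts$mid * 0.9
  pts$y <- 0.01 * pts$x + 0.7
  f <- fitPatlak(pts)
  expect_equal(ki(f), 0.01, tolerance = 1e-12)
  expect_equal(patlakIntercept(f), 0.7, tolerance = 1e-10)
  expect_equal(patlakRsq(f), 1)
  expect_error(fitPatlak(pts, tStart = 84, tEnd = 89), "at least 2 points")
})

test_that("Ki is window-stable on noiseless data", {
  ref <- simulateReferenceTac()
  pts <- patlakTransform(simulateTissueTac(0.012, ref), ref)
  windows <- list(c(24, 89), c(30, 80), c(40, 89), c(24, 50))
  kis <- vapply(windows, function(w) ki(fitPatlak(pts, w[1], w[2])),
                numeric(1))
  expect_true(all(abs(kis - 0.012) < 1e-12))
})

test_that("noisy Monte-Carlo recovery of Ki is nearly unbiased", {
  ref <- simulateReferenceTac()
  kiTrue <- 0.012
  fits <- vapply(1:300, function(s)
    ki(fitPatlak(patlakTransform(
      simulateTissueTac(kiTrue, ref, noiseSd = 0.05, seed = s), ref))),
    numeric(1))
  expect_lt(abs(mean(fits) - kiTrue) / kiTrue, 0.02)
  # RMSE shrinks with noise
  fitsLo <- vapply(1:300, function(s)
    ki(fitPatlak(patlakTransform(
      simulateTissueTac(kiTrue, ref, noiseSd = 0.01, seed = s), ref))),
    numeric(1))
  expect_lt(sqrt(mean((fitsLo - kiTrue)^2)), sqrt(mean((fits - kiTrue)^2)))
})
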