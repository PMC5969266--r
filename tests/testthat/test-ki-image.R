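# Voxel-wise Ki mapping, template masking, ROI extraction.

makePhantom <- function(d = c(6, 6, 4), hi = 0.015, lo = 0.005,
                        noiseSd = 0, seed = NULL) {
  km <- array(lo, d)
  km[1:3, , ] <- hi
  km[, , 1] <- 0        # reference-like slab
  ref <- simulateReferenceTac()
  sim <- simulateDynamicVolume(km, ref, vRef = 1, noiseSd = noiseSd,
                               seed = seed)
  refMask <- new("RoiMask", mask = array(slice.index(km, 3) == 1, d),
                 affine = sim$affine)
  list(sim = sim, km = km, refMask = refMask)
}

test_that("a noiseless two-valued phantom is recovered voxel-wise", {
  ph <- makePhantom()
  kiv <- kiImage(ph$sim$volume, ph$sim$frames, ph$refMask)
  expect_lt(max(abs(ki(kiv) - ph$km)), 1e-12)
  expect_equal(attr(kiv, "nNonFittable"), 0)
  # intercept over the zero-Ki reference slab recovers vRef
  icpt <- attr(kiv, "intercepts")[, , 1]
  expect_true(all(abs(icpt - 1) < 1e-10))
})

test_that("the vectorized map equals looped per-voxel fits", {
  ph <- makePhantom(noiseSd = 0.05, seed = 8)
  kiv <- kiImage(ph$sim$volume, ph$sim$frames, ph$refMask)
  d <- dim(ph$km)
  nf <- nrow(ph$sim$frames)
  Y <- matrix(ph$sim$volume, ncol = nf)
  refA <- colMeans(Y[as.vector(roiMask(ph$refMask)), ])
  refTac <- new("TimeActivityCurve",
                frameStart = ph$sim$frames$frame_start_min,
                frameEnd = ph$sim$frames$frame_end_min, activity = refA)
  idx <- c(1, 17, 60, 100, 144)
  for (v in idx) {
    tac <- new("TimeActivityCurve",
               frameStart = ph$sim$frames$frame_start_min,
               frameEnd = ph$sim$frames$frame_end_min, activity = Y[v, ])
    expect_equal(ki(kiv)[v], ki(fitPatlak(patlakTransform(tac, refTac))),
                 tolerance = 1e-10)
  }
})

test_that("empty reference masks and all-zero volumes are rejected", {
  ph <- makePhantom()
  d <- dim(ph$km)
  empty <- new("RoiMask", mask = array(FALSE, d), affine = diag(4))
  expect_error(kiImage(ph$sim$volume, ph$sim$frames, empty), "empty")
  zeroVol <- array(0, dim(ph$sim$volume))
  expect_error(kiImage(zeroVol, ph$sim$frames, ph$refMask),
               "zero on all frames")
})

test_that("the k-SD template rule keeps only extreme voxels", {
  v <- array(0, c(10, 10, 10))
  v[5, 5, 5] <- 10
  tpl <- new("KiVolume", values = v, voxelSize = c(1, 1, 1),
             affine = diag(4))
  mk <- makeTemplateMask(tpl, k = 3)
  expect_equal(sum(roiMask(mk)), 1)
  expect_true(roiMask(mk)[5, 5, 5])
  expect_equal(sum(roiMask(makeTemplateMask(tpl, k = Inf))), 0)
  flat <- new("KiVolume", values = array(1, c(3, 3, 3)),
              voxelSize = c(1, 1, 1), affine = diag(4))
  expect_error(makeTemplateMask(flat), "zero variance")
})

test_that("the 3-SD mask fraction on a Gaussian template matches the tail", {
  set.seed(1)
  tpl <- new("KiVolume", values = array(rnorm(1e6), c(100, 100, 100)),
             voxelSize = c(1, 1, 1), affine = diag(4))
  frac <- mean(roiMask(makeTemplateMask(tpl, k = 3)))
  expect_equal(frac, pnorm(-3), tolerance = 0.25)
})

test_that("ROI extraction summarizes finite masked voxels", {
  v <- array(0.01, c(4, 4, 4))
  kiv <- new("KiVolume", values = v, voxelSize = c(1, 1, 1), affine = diag(4))
  mask <- fullMask(c(4, 4, 4))
  s <- extractRoi(kiv, mask)
  expect_equal(s$mean, 0.01)
  expect_equal(s$sd, 0)
  expect_equal(s$nVoxels, 64)
  # mask covering only the high region of a two-valued image
  v2 <- array(0.005, c(4, 4, 4))
  v2[1:2, , ] <- 0.015
  kiv2 <- new("KiVolume", values = v2, voxelSize = c(1, 1, 1),
              affine = diag(4))
  hiMask <- new("RoiMask", mask = array(slice.index(v2, 1) <= 2, c(4, 4, 4)),
                affine = diag(4))
  expect_equal(extractRoi(kiv2, hiMask)$mean, 0.015)
  # one-voxel mask and sentinel counting
  v2[1, 1, 1] <- NaN
  kiv3 <- new("KiVolume", values = v2, voxelSize = c(1, 1, 1),
              affine = diag(4))
  one <- array(FALSE, c(4, 4, 4))
  one[3, 3, 3] <- TRUE
  expect_equal(extractRoi(kiv3, new("RoiMask", mask = one,
                                    affine = diag(4)))$mean, 0.005)
  expect_equal(extractRoi(kiv3, hiMask)$nExcluded, 1)
  expect_error(extractRoi(kiv3, new("RoiMask",
                                    mask = array(FALSE, c(4, 4, 4)),
                                    affine = diag(4))), "empty")
})
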