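test_that("preprocessing is zero on zero input and kills DC offsets", {
  expect_equal(preprocessVeog(rep(0, 2000), rate = 100), rep(0, 2000))
  out <- preprocessVeog(rep(100, 2000), rate = 100)
  expect_lt(max(abs(out)), 1e-8)  # rectification removes the median first
  expect_error(preprocessVeog(rnorm(100), rate = 40), "Nyquist")
})

test_that("the band-pass attenuates 50 Hz by 20 dB or more relative to 5 Hz", {
  rate <- 200
  tt <- seq(0, 10, by = 1 / rate)
  core <- seq_along(tt) > rate & seq_along(tt) <= length(tt) - rate
  steadyPower <- function(f)
    mean(preprocessVeog(100 * sin(2 * pi * f * tt), rate = rate)[core]^2)
  expect_gt(10 * log10(steadyPower(5) / steadyPower(50)), 20)
})

test_that("threshold rises are detected and sub-threshold rises are not", {
  rate <- 100
  flat <- rep(0, 1000)
  expect_equal(nrow(detectBlinks(flat, rate = rate)), 0)
  ramp <- function(amp, riseS) {
    up <- seq(0, amp, length.out = riseS * rate)
    c(rep(0, 300), up, rev(up), rep(0, 300))
  }
  expect_equal(nrow(detectBlinks(ramp(150, 0.2), rate = rate)), 1)
  expect_equal(nrow(detectBlinks(ramp(90, 0.4), rate = rate)), 0)
  expect_error(detectBlinks(flat, rate = rate, windowMs = 5), "2 samples")
})

test_that("synthetic recordings are recovered with matched onsets", {
  rec <- simulateEog(randomEogTruth(30, amplitude = 400, noiseSd = 10,
                                    seed = 11))
  ev <- detectBlinks(rec)
  m <- matchOnsets(ev$onset, eogTruth(rec)$blinkOnsets, tol = 0.05)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
})

test_that("detections at conservative thresholds are nested subsets", {
  for (s in 1:5) {
    rec <- simulateEog(randomEogTruth(25, amplitude = 350, amplitudeSd = 120,
                                      noiseSd = 15, seed = 100 + s))
    filt <- preprocessVeog(rec)
    e100 <- detectBlinks(filt, rate = 100, thresholdUv = 100)
    e200 <- detectBlinks(filt, rate = 100, thresholdUv = 200)
    e300 <- detectBlinks(filt, rate = 100, thresholdUv = 300)
    expect_lte(nrow(e300), nrow(e200))
    expect_lte(nrow(e200), nrow(e100))
    nested <- function(hi, lo)
      all(vapply(hi$peak, function(p) any(abs(lo$peak - p) <= 0.05),
                 logical(1)))
    expect_true(nested(e300, e200))
    expect_true(nested(e200, e100))
  }
})

test_that("shifting the signal shifts every event time by the same amount", {
  rate <- 100
  sig <- veog(simulateEog(makeEogTruth(blinkOnsets = c(3, 6, 9),
                                       blinkAmplitudes = 400, noiseSd = 0),
                          duration = 12, rate = rate))
  k <- 37
  shifted <- c(rep(0, k), sig)[seq_along(sig)]
  e0 <- detectBlinks(sig, rate = rate)
  e1 <- detectBlinks(shifted, rate = rate)
  expect_equal(nrow(e1), nrow(e0))
  expect_equal(e1$onset, e0$onset + k / rate, tolerance = 1e-9)
})

test_that("sEBR is invariant to blink-amplitude rescaling above threshold", {
  base <- randomEogTruth(20, amplitude = 300, amplitudeSd = 0, noiseSd = 5,
                         seed = 21)
  big <- base
  big$blinkAmplitudes <- 2.5 * base$blinkAmplitudes
  e1 <- detectBlinks(simulateEog(base))
  e2 <- detectBlinks(simulateEog(big))
  expect_equal(nrow(e1), nrow(e2))
  expect_equal(computeSebr(e1, 6)$rate, computeSebr(e2, 6)$rate)
  expect_equal(e1$peak, e2$peak, tolerance = 0.03)
})

test_that("saccade-coincident events are flagged and Inf threshold is a no-op", {
  tr <- makeEogTruth(blinkOnsets = c(2, 6), blinkAmplitudes = 400,
                     saccadeIntervals = rbind(c(5.9, 6.5)), noiseSd = 0)
  rec <- simulateEog(tr, duration = 10, rate = 100)
  ev <- detectBlinks(rec)
  expect_equal(nrow(ev), 2)
  flagged <- rejectSaccadeArtifacts(ev, rec)
  expect_equal(flagged$rejected, c(FALSE, TRUE))
  expect_equal(flagged$reason, c(NA, "saccade"))
  noop <- rejectSaccadeArtifacts(ev, rec, heogThresholdUv = Inf)
  expect_identical(noop, ev)
  # no deflections at all -> zero rejections
  tr2 <- makeEogTruth(blinkOnsets = c(2, 6), blinkAmplitudes = 400,
                      noiseSd = 0)
  rec2 <- simulateEog(tr2, duration = 10, rate = 100)
  expect_false(any(rejectSaccadeArtifacts(detectBlinks(rec2), rec2)$rejected))
})

test_that("data loss counts saturated runs and drives the 50% exclusion rule", {
  clean <- simulateEog(randomEogTruth(10, noiseSd = 10, seed = 3))
  lossC <- assessDataLoss(clean)
  expect_equal(lossC$lossFraction, 0)
  expect_false(lossC$excluded)
  expect_equal(lossC$exploitableMinutes, 6)

  sat4 <- simulateEog(makeEogTruth(saturatedIntervals = rbind(c(60, 300)),
                                   noiseSd = 10, seed = 4))
  loss4 <- assessDataLoss(sat4)
  expect_equal(loss4$lossFraction, 2 / 3, tolerance = 1e-3)
  expect_true(loss4$excluded)

  # partial recordings with 3.5, 4.4 and 4.5 exploitable minutes all survive
  for (expl in c(3.5, 4.4, 4.5)) {
    satLen <- (6 - expl) * 60
    rec <- simulateEog(makeEogTruth(
      saturatedIntervals = rbind(c(0, satLen)), noiseSd = 10, seed = 5))
    l <- assessDataLoss(rec)
    expect_equal(l$exploitableMinutes, expl, tolerance = 0.01)
    expect_false(l$excluded)
  }
})

test_that("sEBR arithmetic divides non-rejected blinks by exploitable minutes", {
  noEv <- data.frame(rejected = logical(0))
  expect_equal(computeSebr(noEv, 6)$rate, 0)
  expect_equal(computeSebr(data.frame(rejected = logical(30)), 6)$rate, 5)
  expect_equal(computeSebr(data.frame(rejected = logical(14)), 3.5)$rate, 4)
  ev <- data.frame(rejected = c(FALSE, TRUE, FALSE))
  expect_equal(computeSebr(ev, 2)$blinkCount, 2)
  expect_error(computeSebr(ev, 0), "excluded")
})

test_that("rater merging averages and reports Cronbach's alpha", {
  a <- c(10, 20, 30)
  m1 <- mergeRaters(a, a)
  expect_equal(m1$sebr, a)
  expect_equal(m1$alpha, 1)
  m2 <- mergeRaters(a, a + 7)
  expect_equal(m2$alpha, 1)
  b <- c(12, 19, 33)
  m3 <- mergeRaters(a, b)
  expect_equal(m3$sebr, (a + b) / 2)
  expect_equal(m3$alpha, bruteAlpha2(a, b), tolerance = 1e-12)
  expect_error(mergeRaters(a, b[1:2]), "same subjects")
})
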