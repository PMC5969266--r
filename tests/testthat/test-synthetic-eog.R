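test_that("a truth with no events and no noise renders a flat recording", {
  rec <- simulateEog(makeEogTruth(noiseSd = 0), duration = 10, rate = 100)
  expect_equal(veog(rec), rep(0, 1000))
  expect_equal(heog(rec), rep(0, 1000))
  expect_equal(samplingRate(rec), 100)
  expect_equal(eogDuration(rec), 10)
})

test_that("planted blinks are smooth deflections peaking 150-250 ms after onset", {
  tr <- makeEogTruth(blinkOnsets = c(2, 5), blinkAmplitudes = c(400, 300),
                     noiseSd = 0)
  rec <- simulateEog(tr, duration = 10, rate = 100)
  v <- veog(rec)
  tt <- eogTime(rec)
  for (i in 1:2) {
    seg <- tt >= tr$blinkOnsets[i] & tt <= tr$blinkOnsets[i] + 0.4
    pk <- tt[seg][which.max(v[seg])]
    expect_equal(max(v[seg]), tr$blinkAmplitudes[i], tolerance = 1e-6)
    expect_gte(pk - tr$blinkOnsets[i], 0.15)
    expect_lte(pk - tr$blinkOnsets[i], 0.25)
  }
})

test_that("saccade intervals put step deflections on the horizontal channel", {
  tr <- makeEogTruth(saccadeIntervals = rbind(c(1, 1.5)), noiseSd = 0)
  rec <- simulateEog(tr, duration = 5, rate = 100)
  h <- heog(rec)
  tt <- eogTime(rec)
  expect_true(all(abs(h[tt >= 1 & tt < 1.5]) == 200))
  expect_true(all(h[tt < 1 | tt >= 1.5] == 0))
})

test_that("saturated intervals are clamped at the rail", {
  tr <- makeEogTruth(saturatedIntervals = rbind(c(2, 4)), noiseSd = 5,
                     seed = 1)
  rec <- simulateEog(tr, duration = 6, rate = 100, railUv = 500)
  v <- veog(rec)
  tt <- eogTime(rec)
  expect_true(all(v[tt >= 2 & tt < 4] == 500))
  expect_false(any(v[tt < 2] == 500))
})

test_that("identical seeds give bit-identical recordings", {
  tr <- randomEogTruth(10, duration = 60, noiseSd = 15, seed = 7)
  a <- simulateEog(tr, duration = 60)
  b <- simulateEog(tr, duration = 60)
  expect_identical(veog(a), veog(b))
  expect_identical(heog(a), heog(b))
})

test_that("invalid truths are rejected", {
  expect_error(makeEogTruth(blinkOnsets = c(3, 1)), "increasing")
  expect_error(makeEogTruth(blinkOnsets = 1, blinkAmplitudes = -5),
               "positive")
  expect_error(makeEogTruth(saturatedIntervals = rbind(c(2, 1))), "end")
  # blink overlapping a saturated stretch
  tr <- makeEogTruth(blinkOnsets = 3, blinkAmplitudes = 400,
                     saturatedIntervals = rbind(c(2.8, 3.5)))
  expect_error(simulateEog(tr, duration = 10), "overlap")
  # events outside the recording
  tr2 <- makeEogTruth(blinkOnsets = 9.9, blinkAmplitudes = 400)
  expect_error(simulateEog(tr2, duration = 10), "within")
})

test_that("the detector recovers planted onsets within 50 ms", {
  rec <- simulateEog(randomEogTruth(30, noiseSd = 10, seed = 1))
  ev <- detectBlinks(rec)
  planted <- eogTruth(rec)$blinkOnsets
  expect_equal(nrow(ev), 30)
  m <- matchOnsets(ev$onset, planted, tol = 0.05)
  expect_equal(m$tp, 30)
})
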