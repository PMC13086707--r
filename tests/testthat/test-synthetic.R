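# Synthetic-data generator: calibration pairs, induced and intrinsic
# series, frame rendering.

test_that("calibration pairs follow the forward gamma model", {
  cam <- studyCamera()
  p <- generateCalibrationPairs(cam, 1, sigma = 0)
  expect_equal(p$Y_out, 16.71)
  expect_equal(generateCalibrationPairs(identityCamera(), 0.25)$Y_out, 0.25)
  # frozen from evaluating 16.71 * 0.5^0.58 at high precision
  expect_equal(generateCalibrationPairs(cam, 0.5)$Y_out, 11.178385,
               tolerance = 1e-6)
  expect_error(generateCalibrationPairs(cam, c(0.5, 0)), "> 0")
  expect_error(generateCalibrationPairs(cam, numeric(0)), "nonempty")
})

test_that("calibration pair noise is seeded and reproducible", {
  cam <- studyCamera()
  lum <- (1:10) / 10
  a <- generateCalibrationPairs(cam, lum, sigma = 0.3, seed = 42)
  b <- generateCalibrationPairs(cam, lum, sigma = 0.3, seed = 42)
  c <- generateCalibrationPairs(cam, lum, sigma = 0.3, seed = 43)
  expect_identical(a, b)
  expect_false(all(a$Y_out == c$Y_out))
})

test_that("induced closing series hits half-maximum at t50 and decays", {
  s <- simulateInducedSeries(KineticTruth(b = 2, t50 = 300),
                             durationS = 3600, dtS = 1,
                             calib = identityCamera(),
                             noise = NoiseModel(sigma = 0))
  v <- seriesValues(s)
  t <- sampleTimes(s)
  expect_equal(v[t == 300], 0.5)
  expect_true(all(diff(v) <= 0))      # monotone nonincreasing
  expect_lt(v[length(v)], 0.01)       # approaches 0
  expect_equal(v[1], 1)               # closing starts fully open
})

test_that("opening series with bump has its minimum between peak and t50", {
  s <- simulateInducedSeries(KineticTruth(b = -2, t50 = 1800),
                             durationS = 3600, dtS = 1,
                             bump = BumpParams(0.3, 120, 200),
                             calib = identityCamera(),
                             noise = NoiseModel(sigma = 0))
  g <- groundTruth(s)$signal
  t <- sampleTimes(s)
  # dense numerical evaluation of the composite curve: the global minimum
  # falls after the bump peak and before t50
  tMin <- t[which.min(g)]
  expect_gt(tMin, 120)
  expect_lt(tMin, 1800)
  expect_equal(g[t == 0], 0.3)  # recording starts at the elevated level
})

test_that("camera round trip recovers the noiseless ground truth", {
  s <- simulateInducedSeries(KineticTruth(b = 2.5, t50 = 300),
                             durationS = 900, dtS = 1,
                             noise = NoiseModel(sigma = 0))
  corr <- quietCorrect(s, studyCamera())
  expect_equal(seriesValues(corr), groundTruth(s)$signal, tolerance = 1e-9)
})

test_that("temperature slows t50 by the Q10-style factor", {
  warm <- simulateInducedSeries(KineticTruth(2, 300), 900, 1,
                                noise = NoiseModel(sigma = 0),
                                temperatureC = 22)
  cold <- simulateInducedSeries(KineticTruth(2, 300), 900, 1,
                                noise = NoiseModel(sigma = 0),
                                temperatureC = 15)
  expect_equal(groundTruth(warm)$t50_effective_s, 300)
  expect_equal(groundTruth(cold)$t50_effective_s, 600)
})

test_that("intrinsic series reports the transitions it renders", {
  s <- simulateIntrinsicSeries(IntrinsicParams(periodH = 12), durationH = 36,
                               dtMin = 5, calib = identityCamera(),
                               noise = NoiseModel(sigma = 0))
  expect_equal(groundTruth(s)$switch_times_h, c(12, 24, 36))
  # the rendered signal crosses 0.5 exactly at each stored switch
  g <- groundTruth(s)$signal
  tH <- sampleTimes(s) / 3600
  expect_equal(g[tH == 12], 0.5)
  expect_equal(g[tH == 24], 0.5)
})

test_that("linear drift lowers later plateaus by drift times time", {
  s <- simulateIntrinsicSeries(IntrinsicParams(driftPerH = -0.01),
                               durationH = 36, dtMin = 5,
                               calib = identityCamera(),
                               noise = NoiseModel(sigma = 0))
  g <- groundTruth(s)$signal
  tH <- sampleTimes(s) / 3600
  # mid-plateau samples sit on the drifted open level (1 + drift * t)
  expect_equal(g[tH == 30], 1 - 0.01 * 30, tolerance = 1e-9)
  expect_equal(g[tH == 6], 1 - 0.01 * 6, tolerance = 1e-9)
  # the open level just before the final transition is ~0.355 below start
  expect_equal(g[tH == 35.5], 1 - 0.01 * 35.5, tolerance = 1e-6)
})

test_that("intrinsic series are deterministic under a fixed seed", {
  a <- simulateIntrinsicSeries(IntrinsicParams(), noise = NoiseModel(0.05, 9))
  b <- simulateIntrinsicSeries(IntrinsicParams(), noise = NoiseModel(0.05, 9))
  expect_identical(seriesValues(a), seriesValues(b))
  expect_error(simulateIntrinsicSeries(IntrinsicParams(periodH = -1)),
               "periodH")
})

test_that("monotonicity holds for noiseless bump-free series", {
  closing <- simulateInducedSeries(KineticTruth(3, 200), 900, 1,
                                   noise = NoiseModel(sigma = 0))
  opening <- simulateInducedSeries(KineticTruth(-3, 200), 900, 1,
                                   noise = NoiseModel(sigma = 0))
  expect_true(all(diff(seriesValues(closing)) <= 0))
  expect_true(all(diff(seriesValues(opening)) >= 0))
})

test_that("rendered frames carry the series into the pupil disc", {
  s <- ReflectanceSeries(0:4, rep(120, 5))
  st <- renderFrames(s, imageSize = 48, eyeRadius = 18, pupilRadius = 7)
  expect_equal(length(st), 5L)
  expect_equal(sampleTimes(st), 0:4)
  roi <- CircularROI((48 - 1) / 2, (48 - 1) / 2, 7)
  ext <- extractSeries(st, roi, meanGrey = TRUE)
  expect_equal(seriesValues(ext), rep(120, 5))
  expect_error(renderFrames(s, imageSize = 48, eyeRadius = 30,
                            pupilRadius = 7), "eyeRadius")
  expect_error(renderFrames(s, imageSize = 48, eyeRadius = 18,
                            pupilRadius = 20), "pupilRadius")
})

test_that("specimen tables are seeded and carry the requested effects", {
  a <- simulateSpecimenTable(nPerCell = 4, seed = 7)
  b <- simulateSpecimenTable(nPerCell = 4, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 4 * 3 * 2 * 2)
  expect_setequal(unique(a$species), c("CP", "LB", "GM"))
  shifted <- simulateSpecimenTable(nPerCell = 4,
                                   sigma = c(b = 1e-9, t50_s = 1e-9),
                                   speciesEffect = list(b = c(GM = 2)),
                                   seed = 7)
  gmB <- mean(shifted$b[shifted$species == "GM"])
  cpB <- mean(shifted$b[shifted$species == "CP"])
  expect_equal(gmB - cpB, 2, tolerance = 1e-6)
})
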