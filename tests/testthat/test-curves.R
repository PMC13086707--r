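# Normalization, bump exclusion and log-logistic fitting.

corrSeries <- function(times, values) {
  ReflectanceSeries(times, values, units = "corrected")
}

test_that("normalization maps the series extremes to 0 and 1", {
  crv <- normalizeCurve(corrSeries(0:2, c(2, 6, 10)))
  expect_equal(seriesValues(crv), c(0, 0.5, 1))
  expect_equal(curveDirection(crv), "opening")

  set.seed(31)
  s <- corrSeries(1:50, runif(50, 3, 9))
  n1 <- normalizeCurve(s)
  expect_equal(min(seriesValues(n1)), 0)
  expect_equal(max(seriesValues(n1)), 1)
  # idempotence
  n2 <- normalizeCurve(n1)
  expect_equal(seriesValues(n2), seriesValues(n1))
  expect_error(normalizeCurve(corrSeries(1:3, rep(5, 3))), "degenerate")
  expect_error(normalizeCurve(ReflectanceSeries(1:3, 1:3, units = "raw")),
               "corrected")
})

test_that("the log-logistic sigmoid is monotone with f(t50) = 0.5", {
  t <- seq(1, 1000, by = 1)
  closing <- logLogistic(t, 2, 300)
  opening <- logLogistic(t, -2, 300)
  expect_equal(logLogistic(300, 2, 300), 0.5)
  expect_equal(logLogistic(300, -2, 300), 0.5)
  expect_true(all(diff(closing) < 0))
  expect_true(all(diff(opening) > 0))
  expect_equal(logLogistic(0, 2, 300), 1)   # one-sided limit
  expect_equal(logLogistic(0, -2, 300), 0)
})

test_that("the opening bump is located between its peak and t50", {
  s <- simulateInducedSeries(KineticTruth(-2, 1800), 5400, 60,
                             bump = BumpParams(0.3, 120, 200),
                             calib = identityCamera(),
                             noise = NoiseModel(sigma = 0))
  crv <- normalizeCurve(quietCorrect(s, identityCamera()), "opening")
  ann <- detectBump(crv)
  expect_true(ann@present)
  expect_gt(ann@bumpEnd, 120)
  expect_lt(ann@bumpEnd, 1800)
  # the composite curve's own post-peak minimum is the oracle for bumpEnd
  g <- groundTruth(s)$signal
  t <- sampleTimes(s)
  after <- t > 120 & t <= 1200
  expect_equal(ann@bumpEnd, t[after][which.min(g[after])],
               tolerance = 120)  # within two sample intervals
})

test_that("monotone and flat-then-rise curves carry no bump", {
  s <- simulateInducedSeries(KineticTruth(-2, 1800), 5400, 60,
                             calib = identityCamera(),
                             noise = NoiseModel(sigma = 0))
  crv <- normalizeCurve(quietCorrect(s, identityCamera()), "opening")
  ann <- detectBump(crv)
  expect_false(ann@present)
  expect_equal(ann@bumpEnd, 0)

  flat <- NormalizedCurve(seq(0, 3000, 60),
                          c(rep(0, 20), seq(0, 1, length.out = 31)),
                          direction = "opening")
  expect_false(detectBump(flat)@present)
  expect_error(detectBump(crv, windowS = 1e6), "span")
  closing <- NormalizedCurve(1:10, seq(1, 0, length.out = 10), "closing")
  expect_error(detectBump(closing), "opening")
})

test_that("trimming drops the transient and re-normalizes the rise", {
  s <- simulateInducedSeries(KineticTruth(-2, 1800), 5400, 60,
                             bump = BumpParams(0.3, 120, 200),
                             calib = identityCamera(),
                             noise = NoiseModel(sigma = 0))
  crv <- normalizeCurve(quietCorrect(s, identityCamera()), "opening")
  ann <- detectBump(crv)
  trimmed <- trimToRise(crv, ann)
  expect_equal(seriesValues(trimmed)[1], 0)       # starts at the minimum
  expect_equal(sampleTimes(trimmed)[1], 0)        # time re-zeroed
  expect_equal(length(trimmed),
               length(crv) - sum(sampleTimes(crv) < ann@bumpEnd))
  # without a bump the curve passes through unchanged
  noBump <- new("BumpAnnotation", present = FALSE, bumpEnd = 0,
                peakValue = NA_real_)
  same <- trimToRise(crv, noBump)
  expect_equal(seriesValues(same), seriesValues(crv))
  short <- NormalizedCurve(seq(0, 300, 60), c(0, 0.9, 1, 0.2, 0.4, 0.6),
                           "opening")
  expect_error(trimToRise(short, new("BumpAnnotation", present = TRUE,
                                     bumpEnd = 250, peakValue = 0.9)),
               "fewer than")
})

test_that("fitting exact model samples recovers the parameters", {
  t <- seq(1, 900, by = 1)
  crv <- NormalizedCurve(t, logLogistic(t, 2.5, 300), "closing")
  fit <- fitLogLogistic(crv)
  expect_true(fit@converged)
  expect_equal(coef(fit)[["b"]], 2.5, tolerance = 1e-6)
  expect_equal(coef(fit)[["t50"]], 300, tolerance = 1e-6)
  expect_equal(rSquared(fit), 1, tolerance = 1e-9)
  expect_equal(predict(fit, coef(fit)[["t50"]]), 0.5)

  tOp <- seq(0, 5400, by = 60)
  crvOp <- NormalizedCurve(tOp, logLogistic(tOp, -3, 1800), "opening")
  fitOp <- fitLogLogistic(crvOp)   # exercises the t = 0 half-step shift
  expect_equal(coef(fitOp)[["b"]], -3, tolerance = 1e-3)
  expect_equal(coef(fitOp)[["t50"]], 1800, tolerance = 1)
})

test_that("rescaling time rescales t50 and leaves the slope unchanged", {
  t <- seq(1, 900, by = 1)
  y <- logLogistic(t, 2.5, 300)
  f1 <- fitLogLogistic(NormalizedCurve(t, y, "closing"))
  f2 <- fitLogLogistic(NormalizedCurve(t * 60, y, "closing"))
  expect_equal(coef(f2)[["b"]], coef(f1)[["b"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["t50"]], 60 * coef(f1)[["t50"]], tolerance = 1e-4)
})

test_that("estimator bias on model samples vanishes as noise shrinks", {
  run <- function(sigma, seeds) {
    t(vapply(seeds, function(sd) {
      set.seed(sd)
      t <- 1:900
      y <- pmin(pmax(logLogistic(t, 2.5, 300) + rnorm(900, 0, sigma), 0), 1)
      coef(fitLogLogistic(NormalizedCurve(t, y, "closing")))
    }, numeric(2)))
  }
  noisy <- run(0.03, 1:50)
  expect_lt(abs(mean(noisy[, 1]) - 2.5) / 2.5, 0.05)
  expect_lt(abs(mean(noisy[, 2]) - 300) / 300, 0.05)
  quiet <- run(0.003, 1:20)
  expect_lt(abs(mean(quiet[, 1]) - 2.5), abs(mean(noisy[, 1]) - 2.5))
  expect_lt(abs(mean(quiet[, 2]) - 300), abs(mean(noisy[, 2]) - 300))
})

test_that("full-pipeline closing recovery carries the normalization bias", {
  # min-max normalization over noisy extremes compresses the curve and the
  # finite window truncates its tail, so pipeline estimates sit somewhat
  # below truth; bounds frozen from the observed distribution under the
  # study recording conditions (1 Hz, 900 s, sigma 0.03)
  cam <- studyCamera()
  est <- t(vapply(1:50, function(sd) {
    s <- simulateInducedSeries(KineticTruth(2.5, 300), 900, 1,
                               noise = NoiseModel(0.03, sd))
    coef(quietPipeline(s, cam, "closing")$fit)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 2.5), 0.35)
  expect_lt(abs(mean(est[, 2]) - 300), 55)
})

test_that("opening-curve recovery through the full pipeline is within 5%", {
  cam <- studyCamera()
  est <- t(vapply(1:50, function(sd) {
    s <- simulateInducedSeries(KineticTruth(-2, 1800), 5400, 60,
                               noise = NoiseModel(0.03, sd))
    coef(quietPipeline(s, cam, "opening")$fit)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - (-2)) / 2, 0.05)
  expect_lt(abs(mean(est[, 2]) - 1800) / 1800, 0.05)
})

test_that("a slope sign inconsistent with the declared direction warns", {
  t <- seq(1, 900, by = 1)
  crv <- NormalizedCurve(t, logLogistic(t, 2.5, 300), "opening")
  expect_warning(fitLogLogistic(crv), "inconsistent")
})

test_that("fits degrade gracefully when the half-crossing is absent", {
  # early truncation: values never reach 0.5, forcing the grid fallback
  t <- seq(1, 120, by = 1)
  y <- logLogistic(t, 2.5, 300)
  y <- pmin(y / max(y), 1)
  fit <- fitLogLogistic(NormalizedCurve(t, y, "closing"))
  expect_s4_class(fit, "LogLogisticFit")
  expect_gt(coef(fit)[["t50"]], 120)  # extrapolated beyond the window
})
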