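## Seeded synthetic-data generator emulating the NIR pupillometry recordings:
## calibration chart pairs, induced closing/opening series, 36-h intrinsic
## rhythm series, and rendered image stacks.

.DEFAULT_CAMERA <- function() CameraCalibration(A = 16.71, gamma = 0.58)

#' Forward camera transfer function
#'
#' Maps scene luminance to recorded grey value,
#' \eqn{Y_{out} = A \cdot Y_{in}^{\gamma}}.
#'
#' @param calib a \linkS4class{CameraCalibration}.
#' @param x luminance values (>= 0).
#' @return Grey values on the camera scale.
#' @seealso [correctSeries()] for the inverse.
#' @export
#' @examples
#' cameraForward(CameraCalibration(16.71, 0.58), 1)  # = A
cameraForward <- function(calib, x) {
  stopifnot(is(calib, "CameraCalibration"))
  if (any(x < 0)) stop("luminance values must be >= 0")
  calib@A * x^calib@gamma
}

#' Generate synthetic calibration chart pairs
#'
#' Emulates photographing a reflectance chart: for each patch luminance the
#' camera records \eqn{A \cdot Y_{in}^{\gamma}} plus additive Gaussian noise
#' on the grey scale.
#'
#' @param calib a \linkS4class{CameraCalibration} (the true camera).
#' @param luminances patch luminances, all > 0 (typically in (0, 1]; a
#'   24-patch chart is the usual fixture).
#' @param sigma grey-scale noise SD (0 for noiseless pairs).
#' @param seed RNG seed (ignored when \code{sigma = 0}).
#' @return A data.frame with columns \code{Y_in}, \code{Y_out}.
#' @export
#' @examples
#' pairs <- generateCalibrationPairs(CameraCalibration(16.71, 0.58),
#'                                   seq(1, 24) / 24)
#' fitGamma(pairs)
generateCalibrationPairs <- function(calib, luminances, sigma = 0,
                                     seed = NULL) {
  stopifnot(is(calib, "CameraCalibration"))
  if (!length(luminances)) stop("'luminances' must be nonempty")
  if (any(luminances <= 0))
    stop("all luminances must be > 0 (got min = ",
         format(min(luminances)), ")")
  if (sigma < 0) stop("'sigma' must be >= 0")
  out <- cameraForward(calib, luminances)
  if (sigma > 0)
    out <- out + withSeed(seed, stats::rnorm(length(out), 0, sigma))
  data.frame(Y_in = as.numeric(luminances), Y_out = out)
}

# Additive opening transient: the eye brightness is already elevated when
# the recording starts (the sudden increase happens at stimulus-off), holds
# near the peak level until peakTime, then decays exponentially.
.bumpPulse <- function(t, bump) {
  if (is.null(bump)) return(numeric(length(t)))
  p <- bump@peakHeight *
    pmin(1, exp(-(t - bump@peakTime) / bump@decayTau))
  p[t < 0] <- 0
  p
}

# Apply the camera forward model plus noise; sigma is given in normalized
# brightness, so its grey-scale SD is sigma * A. Grey values are clipped at
# 0 (a camera cannot record negative grey).
.cameraAndNoise <- function(g, calib, noise) {
  grey <- cameraForward(calib, pmax(g, 0))
  if (noise@sigma > 0) {
    grey <- grey + withSeed(noise@seed,
                            stats::rnorm(length(grey), 0,
                                         noise@sigma * calib@A))
  }
  pmax(grey, 0)
}

#' Simulate an induced pupil closing or opening recording
#'
#' Generates the normalized ground-truth kinetics
#' \eqn{g(t) = f(t; b, t_{50})} (plus the optional opening transient), pushes
#' it through the camera forward model and adds noise, so that the full
#' correction/normalization/fitting pipeline is exercised. The noiseless
#' normalized signal, the truth and the bump parameters are attached as
#' ground truth.
#'
#' Temperature enters as a Q10-style multiplicative factor on \eqn{t_{50}}:
#' \code{t50Factor^((referenceC - temperatureC)/7)} with a default factor of
#' 2 per 7 degrees C, emulating slower kinetics in the cold.
#'
#' @param truth a \linkS4class{KineticTruth}.
#' @param durationS,dtS recording length and sampling interval, seconds
#'   (UV-induced closing: ~900 s at 1 frame/s; dark opening: ~5400 s at
#'   1 frame/min).
#' @param bump optional \linkS4class{BumpParams} (opening curves only).
#' @param calib camera model (default: the fitted study camera,
#'   A = 16.71, gamma = 0.58).
#' @param noise a \linkS4class{NoiseModel}.
#' @param temperatureC,referenceC,t50Factor temperature scaling of t50.
#' @return A \linkS4class{ReflectanceSeries} with units \code{"raw"}; its
#'   \code{groundTruth} holds \code{signal} (noiseless normalized values),
#'   \code{truth}, \code{bump} and \code{t50_effective_s}.
#' @export
#' @examples
#' s <- simulateInducedSeries(KineticTruth(b = 2, t50 = 300),
#'                            durationS = 900, dtS = 1,
#'                            noise = NoiseModel(sigma = 0))
#' range(seriesValues(s))
simulateInducedSeries <- function(truth, durationS, dtS, bump = NULL,
                                  calib = .DEFAULT_CAMERA(),
                                  noise = NoiseModel(),
                                  temperatureC = 22, referenceC = 22,
                                  t50Factor = 2) {
  stopifnot(is(truth, "KineticTruth"), is(calib, "CameraCalibration"),
            is(noise, "NoiseModel"))
  if (!is.null(bump)) stopifnot(is(bump, "BumpParams"))
  if (dtS <= 0 || durationS <= dtS)
    stop("need durationS > dtS > 0")
  t <- seq(0, durationS, by = dtS)
  t50eff <- truth@t50 * t50Factor^((referenceC - temperatureC) / 7)
  g <- logLogistic(t, truth@b, t50eff) + .bumpPulse(t, bump)
  g <- pmin(pmax(g, 0), 1)
  vals <- .cameraAndNoise(g, calib, noise)
  ReflectanceSeries(
    times = t, values = vals, units = "raw",
    groundTruth = list(signal = g, truth = truth, bump = bump,
                       t50_effective_s = t50eff, calib = calib,
                       sigma = noise@sigma))
}

# Log-logistic-shaped unit step: 0 before onset, 0.5 at onset + half, -> 1.
.llStep <- function(u, b, half) {
  s <- numeric(length(u))
  pos <- u > 0
  s[pos] <- 1 / (1 + (u[pos] / half)^(-b))
  s
}

#' Simulate a constant-darkness intrinsic rhythm recording
#'
#' Alternating open/closed plateaus of length \code{periodH} hours with
#' log-logistic-shaped transitions, a linear brightness drift, and the
#' camera/noise forward model. The recording starts in the open state (the
#' subjective night of a 12:12-entrained animal); switch k occurs at
#' \code{phaseOffsetH + k * periodH} hours. Switch times within the
#' recording are attached as ground truth.
#'
#' @param params an \linkS4class{IntrinsicParams}.
#' @param durationH recording length, hours (the study recorded 36 h).
#' @param dtMin sampling interval, minutes (the study used 1 frame/5 min).
#' @param calib camera model.
#' @param noise a \linkS4class{NoiseModel}.
#' @param transitionHalfH half-duration of each transition, hours; the
#'   0.5-crossing of every transition falls exactly on the switch time.
#' @return A \linkS4class{ReflectanceSeries} (times in seconds, units
#'   \code{"raw"}); \code{groundTruth} holds \code{switch_times_h},
#'   \code{signal} and \code{params}.
#' @export
#' @examples
#' s <- simulateIntrinsicSeries(IntrinsicParams(), durationH = 36,
#'                              dtMin = 5, noise = NoiseModel(sigma = 0))
#' groundTruth(s)$switch_times_h
simulateIntrinsicSeries <- function(params, durationH = 36, dtMin = 5,
                                    calib = .DEFAULT_CAMERA(),
                                    noise = NoiseModel(),
                                    transitionHalfH = 0.25) {
  stopifnot(is(params, "IntrinsicParams"), is(calib, "CameraCalibration"),
            is(noise, "NoiseModel"))
  if (durationH <= 0 || dtMin <= 0)
    stop("need durationH > 0 and dtMin > 0")
  tH <- seq(0, durationH, by = dtMin / 60)
  kMax <- floor((durationH - params@phaseOffsetH) / params@periodH + 1e-9)
  switches <- if (kMax >= 1)
    params@phaseOffsetH + seq_len(kMax) * params@periodH else numeric(0)
  switches <- switches[switches > 0 & switches <= durationH + 1e-9]
  g <- rep(1, length(tH))  # open at start
  sign <- -1
  for (Tk in switches) {
    g <- g + sign * .llStep(tH - (Tk - transitionHalfH), params@transitionB,
                            transitionHalfH)
    sign <- -sign
  }
  g <- pmax(g + params@driftPerH * tH, 0)
  vals <- .cameraAndNoise(g, calib, noise)
  ReflectanceSeries(
    times = tH * 3600, values = vals, units = "raw",
    groundTruth = list(signal = g, params = params,
                       switch_times_h = switches, calib = calib,
                       sigma = noise@sigma))
}

#' Generate a synthetic specimen parameter table
#'
#' Builds the per-curve parameter table the statistics module consumes:
#' one row per specimen with species, sex, temperature, phase, and kinetic
#' parameters drawn from Gaussian cell distributions. Effects are additive
#' shifts on the cell mean, so a "null" table (all effects zero) and
#' single-factor designs for power checks are both expressible.
#'
#' @param nPerCell specimens per species x sex x temperature cell (the study
#'   tested 10 individuals per species and temperature, 4-6 per sex).
#' @param phase \code{"closing"} or \code{"opening"}.
#' @param baseline named vector \code{c(b = , t50_s = )} of grand means.
#' @param sigma named vector of within-cell SDs for b and t50_s.
#' @param speciesEffect,sexEffect,temperatureEffect lists with optional
#'   numeric elements \code{b} and \code{t50_s}: per-level additive shifts
#'   (named by level for species/sex; a single number for the 22 vs 15
#'   degree contrast, applied at 22).
#' @param species,sexes,temperatures factor levels of the design.
#' @param seed RNG seed.
#' @return A data.frame with columns \code{specimen_id}, \code{species},
#'   \code{sex}, \code{temperature_C}, \code{phase}, \code{b},
#'   \code{t50_s}.
#' @export
#' @examples
#' head(simulateSpecimenTable(nPerCell = 2, seed = 1))
simulateSpecimenTable <- function(nPerCell = 10, phase = "closing",
                                  baseline = c(b = 2.5, t50_s = 300),
                                  sigma = c(b = 0.4, t50_s = 40),
                                  speciesEffect = list(),
                                  sexEffect = list(),
                                  temperatureEffect = list(),
                                  species = c("CP", "LB", "GM"),
                                  sexes = c("male", "female"),
                                  temperatures = c(15, 22),
                                  seed = 1L) {
  stopifnot(nPerCell >= 1, phase %in% .DIRECTIONS)
  grid <- expand.grid(species = species, sex = sexes,
                      temperature_C = temperatures,
                      rep = seq_len(nPerCell), stringsAsFactors = FALSE)
  shift <- function(effect, var, levels) {
    e <- effect[[var]]
    if (is.null(e)) return(numeric(nrow(grid)))
    if (!is.null(names(e))) {
      out <- rep(0, nrow(grid))
      for (lv in names(e)) out[levels == lv] <- e[[lv]]
      out
    } else {
      # single number: applied at the higher temperature
      ifelse(grid$temperature_C == max(temperatures), e, 0)
    }
  }
  withSeed(seed, {
    n <- nrow(grid)
    b <- baseline[["b"]] + shift(speciesEffect, "b", grid$species) +
      shift(sexEffect, "b", grid$sex) +
      shift(temperatureEffect, "b", NULL) +
      stats::rnorm(n, 0, sigma[["b"]])
    t50 <- baseline[["t50_s"]] +
      shift(speciesEffect, "t50_s", grid$species) +
      shift(sexEffect, "t50_s", grid$sex) +
      shift(temperatureEffect, "t50_s", NULL) +
      stats::rnorm(n, 0, sigma[["t50_s"]])
    data.frame(specimen_id = sprintf("S%03d", seq_len(n)),
               species = grid$species, sex = grid$sex,
               temperature_C = grid$temperature_C, phase = phase,
               b = b, t50_s = pmax(t50, 1))
  })
}

#' Render a reflectance series as a synthetic image stack
#'
#' Draws, for each sample, a frame with a noisy dark background, a dim eye
#' disc and a central pupil disc whose grey value equals the series value at
#' that time (rounded to the 8-bit grid), emulating the appearance of a
#' dark-adapted superposition pupil under NIR illumination. This makes the
#' imaging module testable end to end: extracting the mean grey over the
#' pupil ROI recovers the series up to quantization.
#'
#' @param series a \linkS4class{ReflectanceSeries}; values must lie in
#'   [0, 255].
#' @param imageSize side of the square frames, px.
#' @param eyeRadius,pupilRadius disc radii, px; need
#'   \code{pupilRadius < eyeRadius < imageSize / 2}.
#' @param eyeGrey grey value of the eye disc outside the pupil.
#' @param backgroundGrey,backgroundSigma background mean and Gaussian SD
#'   (grey values; 0 SD for a noiseless background).
#' @param seed RNG seed for the background noise.
#' @return A \linkS4class{FrameStack} (8-bit).
#' @export
#' @examples
#' s <- ReflectanceSeries(0:2, c(100, 120, 140))
#' renderFrames(s, imageSize = 32, eyeRadius = 12, pupilRadius = 5)
renderFrames <- function(series, imageSize = 64, eyeRadius = 24,
                         pupilRadius = 10, eyeGrey = 40,
                         backgroundGrey = 10, backgroundSigma = 0,
                         seed = 1L) {
  stopifnot(is(series, "ReflectanceSeries"))
  if (!(pupilRadius < eyeRadius && eyeRadius < imageSize / 2))
    stop("need pupilRadius < eyeRadius < imageSize / 2 (got ",
         pupilRadius, ", ", eyeRadius, ", ", imageSize, ")")
  v <- seriesValues(series)
  if (any(v < 0 | v > 255))
    stop("series values must be in [0, 255] to render 8-bit frames")
  n <- length(v)
  cx <- (imageSize - 1) / 2
  xs <- matrix(rep(0:(imageSize - 1), each = imageSize), imageSize)
  ys <- matrix(rep(0:(imageSize - 1), times = imageSize), imageSize)
  d2 <- (xs - cx)^2 + (ys - cx)^2
  inEye <- d2 <= eyeRadius^2
  inPupil <- d2 <= pupilRadius^2
  frames <- withSeed(seed, {
    lapply(seq_len(n), function(i) {
      f <- matrix(backgroundGrey, imageSize, imageSize)
      if (backgroundSigma > 0)
        f <- f + matrix(stats::rnorm(imageSize^2, 0, backgroundSigma),
                        imageSize)
      f[inEye] <- eyeGrey
      f[inPupil] <- v[i]
      pmin(pmax(round(f), 0), 255)
    })
  })
  FrameStack(frames, timestamps = sampleTimes(series), bitDepth = 8L)
}
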