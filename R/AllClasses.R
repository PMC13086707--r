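#' @import methods
NULL

.UNIT_LEVELS <- c("raw", "corrected", "normalized")
.DIRECTIONS <- c("closing", "opening")

## ---------------------------------------------------------------------------
## CameraCalibration
## ---------------------------------------------------------------------------

#' Camera gamma transfer function
#'
#' Parameters of the camera's grey-intensity response
#' \eqn{Y_{out} = A \cdot Y_{in}^{\gamma}}, estimated by photographing a
#' reflectance chart of known patch luminances. The inverse,
#' \eqn{Y_{corr} = (Y_{meas}/A)^{1/\gamma}}, linearizes measured grey values.
#'
#' @slot A positive amplitude (grey-value units per unit luminance^gamma).
#' @slot gamma positive dimensionless exponent.
#' @slot rss residual sum of squares of the fit (0 for an assumed
#'   calibration).
#' @seealso [fitGamma()], [correctSeries()], [cameraForward()]
#' @export
setClass("CameraCalibration",
         slots = c(A = "numeric", gamma = "numeric", rss = "numeric"))

setValidity("CameraCalibration", function(object) {
  if (length(object@A) != 1L || !is.finite(object@A) || object@A <= 0)
    return("'A' must be a single positive finite number")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0)
    return("'gamma' must be a single positive finite number")
  TRUE
})

#' @describeIn CameraCalibration-class Constructor.
#' @param A amplitude.
#' @param gamma exponent.
#' @param rss residual sum of squares (default 0).
#' @export
CameraCalibration <- function(A, gamma, rss = 0) {
  new("CameraCalibration", A = as.numeric(A), gamma = as.numeric(gamma),
      rss = as.numeric(rss))
}

#' @rdname amplitude
#' @aliases amplitude,CameraCalibration-method
setMethod("amplitude", "CameraCalibration", function(x) x@A)

#' @rdname gammaExponent
#' @aliases gammaExponent,CameraCalibration-method
setMethod("gammaExponent", "CameraCalibration", function(x) x@gamma)

setMethod("show", "CameraCalibration", function(object) {
  cat("CameraCalibration: Y_out = A * Y_in^gamma\n")
  cat(sprintf("  A = %.6g, gamma = %.6g (rss = %.4g)\n",
              object@A, object@gamma, object@rss))
})

## ---------------------------------------------------------------------------
## ReflectanceSeries
## ---------------------------------------------------------------------------

#' Timestamped eye-reflectance series
#'
#' One specimen/phase worth of eye brightness over time: either raw
#' integrated density (grey times px^2), camera-corrected values, or
#' normalized brightness. Synthetic series carry their generating ground
#' truth in \code{groundTruth} for recovery tests.
#'
#' @slot times seconds, strictly increasing.
#' @slot values nonnegative reflectance values, same length as \code{times}.
#' @slot units one of \code{"raw"}, \code{"corrected"}, \code{"normalized"}.
#' @slot groundTruth list; empty for measured data.
#' @export
setClass("ReflectanceSeries",
         slots = c(times = "numeric", values = "numeric",
                   units = "character", groundTruth = "list"),
         prototype = prototype(units = "raw", groundTruth = list()))

setValidity("ReflectanceSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("'times' and 'values' must have the same length")
  if (length(object@times) && any(diff(object@times) <= 0))
    return("'times' must be strictly increasing")
  if (any(!is.finite(object@values)))
    return("'values' must be finite")
  if (length(object@units) != 1L || !object@units %in% .UNIT_LEVELS)
    return(sprintf("'units' must be one of: %s",
                   paste(.UNIT_LEVELS, collapse = ", ")))
  TRUE
})

#' @describeIn ReflectanceSeries-class Constructor.
#' @param times seconds.
#' @param values reflectance values.
#' @param units units flag.
#' @param groundTruth optional list of generating parameters.
#' @export
ReflectanceSeries <- function(times, values, units = "raw",
                              groundTruth = list()) {
  new("ReflectanceSeries", times = as.numeric(times),
      values = as.numeric(values), units = units, groundTruth = groundTruth)
}

#' @rdname sampleTimes
#' @aliases sampleTimes,ReflectanceSeries-method
setMethod("sampleTimes", "ReflectanceSeries", function(x) x@times)

#' @rdname seriesValues
#' @aliases seriesValues,ReflectanceSeries-method
setMethod("seriesValues", "ReflectanceSeries", function(x) x@values)

#' @rdname seriesUnits
#' @aliases seriesUnits,ReflectanceSeries-method
setMethod("seriesUnits", "ReflectanceSeries", function(x) x@units)

#' @rdname groundTruth
#' @aliases groundTruth,ReflectanceSeries-method
setMethod("groundTruth", "ReflectanceSeries", function(x) x@groundTruth)

#' @describeIn ReflectanceSeries-class Number of samples.
#' @param x a ReflectanceSeries.
#' @export
setMethod("length", "ReflectanceSeries", function(x) length(x@times))

setMethod("show", "ReflectanceSeries", function(object) {
  n <- length(object@times)
  cat(sprintf("ReflectanceSeries: %d samples, units = %s\n", n, object@units))
  if (n) {
    cat(sprintf("  time span: %.4g .. %.4g s (dt ~ %.4g s)\n",
                object@times[1], object@times[n],
                if (n > 1) stats::median(diff(object@times)) else NA_real_))
    cat(sprintf("  value range: %.4g .. %.4g\n",
                min(object@values), max(object@values)))
  }
  if (length(object@groundTruth))
    cat("  carries simulation ground truth\n")
})

## ---------------------------------------------------------------------------
## NormalizedCurve
## ---------------------------------------------------------------------------

#' Min-max normalized pupil curve
#'
#' A reflectance curve rescaled so its minimum is 0 and maximum is 1, with
#' times re-zeroed at the analysis start, and a direction label (closing:
#' brightness falls under light adaptation; opening: brightness rises in
#' darkness).
#'
#' @slot direction \code{"closing"} or \code{"opening"}.
#' @export
setClass("NormalizedCurve", contains = "ReflectanceSeries",
         slots = c(direction = "character"),
         prototype = prototype(units = "normalized", direction = "closing"))

setValidity("NormalizedCurve", function(object) {
  if (object@units != "normalized")
    return("a NormalizedCurve has units 'normalized'")
  if (length(object@direction) != 1L ||
      !object@direction %in% .DIRECTIONS)
    return("'direction' must be 'closing' or 'opening'")
  if (length(object@values)) {
    tol <- 1e-8
    if (min(object@values) < -tol || max(object@values) > 1 + tol)
      return("normalized values must lie in [0, 1]")
    if (object@times[1] < 0)
      return("times must be re-zeroed (times[1] >= 0)")
  }
  TRUE
})

#' @describeIn NormalizedCurve-class Constructor (values are assumed already
#'   normalized; use [normalizeCurve()] to build one from a corrected
#'   series).
#' @param times,values,groundTruth see \linkS4class{ReflectanceSeries}.
#' @param direction curve direction.
#' @export
NormalizedCurve <- function(times, values, direction,
                            groundTruth = list()) {
  new("NormalizedCurve", times = as.numeric(times),
      values = as.numeric(values), units = "normalized",
      direction = direction, groundTruth = groundTruth)
}

#' @rdname curveDirection
#' @aliases curveDirection,NormalizedCurve-method
setMethod("curveDirection", "NormalizedCurve", function(x) x@direction)

setMethod("show", "NormalizedCurve", function(object) {
  cat(sprintf("NormalizedCurve (%s): %d samples over %.4g s\n",
              object@direction, length(object@times),
              if (length(object@times)) diff(range(object@times)) else 0))
})

## ---------------------------------------------------------------------------
## LogLogisticFit
## ---------------------------------------------------------------------------

#' Fitted log-logistic pupil kinetics
#'
#' Two-parameter log-logistic model
#' \deqn{f(x) = 1 / (1 + \exp(b (\log x - \log t_{50})))}
#' fitted to a normalized pupil curve. \code{b} is the slope of the linear
#' part of the sigmoid and \code{t50} the time at half brightness;
#' \code{f(t50) = 0.5} by construction. Under the adopted sign convention
#' closing curves have \code{b > 0} (f decreasing) and opening curves
#' \code{b < 0} (f increasing). There are no offset or amplitude parameters:
#' the asymptotes are fixed at 0 and 1.
#'
#' @slot b slope parameter.
#' @slot t50 time at half brightness, seconds (> 0).
#' @slot rSquared \eqn{1 - SS_{res}/SS_{tot}}.
#' @slot direction curve direction the fit was made on.
#' @slot converged logical convergence status.
#' @slot message optimizer diagnostics.
#' @seealso [fitLogLogistic()], [logLogistic()]
#' @export
setClass("LogLogisticFit",
         slots = c(b = "numeric", t50 = "numeric", rSquared = "numeric",
                   direction = "character", converged = "logical",
                   message = "character"))

setValidity("LogLogisticFit", function(object) {
  if (length(object@t50) != 1L || !is.finite(object@t50) || object@t50 <= 0)
    return("'t50' must be a single positive number")
  if (length(object@b) != 1L || !is.finite(object@b) || object@b == 0)
    return("'b' must be a single nonzero number")
  if (!object@direction %in% .DIRECTIONS)
    return("'direction' must be 'closing' or 'opening'")
  if (length(object@rSquared) != 1L || object@rSquared > 1 + 1e-12)
    return("'rSquared' must be a single number <= 1")
  TRUE
})

#' @rdname curveDirection
#' @aliases curveDirection,LogLogisticFit-method
setMethod("curveDirection", "LogLogisticFit", function(x) x@direction)

#' @rdname rSquared
#' @aliases rSquared,LogLogisticFit-method
setMethod("rSquared", "LogLogisticFit", function(x) x@rSquared)

#' @describeIn LogLogisticFit-class Fitted parameters as a named vector
#'   \code{c(b, t50)}.
#' @param object a LogLogisticFit.
#' @param ... ignored.
#' @export
setMethod("coef", "LogLogisticFit",
          function(object, ...) c(b = object@b, t50 = object@t50))

#' @describeIn LogLogisticFit-class Evaluate the fitted curve at times
#'   \code{newtimes} (seconds).
#' @param newtimes times at which to evaluate the fitted sigmoid.
#' @export
setMethod("predict", "LogLogisticFit", function(object, newtimes, ...) {
  logLogistic(newtimes, object@b, object@t50)
})

setMethod("show", "LogLogisticFit", function(object) {
  cat(sprintf("LogLogisticFit (%s%s)\n", object@direction,
              if (object@converged) "" else ", NOT converged"))
  cat(sprintf("  b = %.6g, t50 = %.6g s, R^2 = %.4f\n",
              object@b, object@t50, object@rSquared))
})

## ---------------------------------------------------------------------------
## BumpAnnotation
## ---------------------------------------------------------------------------

#' Annotation of the post-UV opening transient
#'
#' Dark re-opening recordings start with a transient brightness "bump":
#' a sudden increase that quickly decays to a minimum before the sigmoid
#' rise. The transient is excluded before fitting; \code{bumpEnd} is the
#' time of the windowed minimum at which the rise begins.
#'
#' @slot present logical; whether a bump was detected.
#' @slot bumpEnd end time of the transient in seconds (0 when absent).
#' @slot peakValue normalized brightness at the bump peak (NA when absent).
#' @seealso [detectBump()], [trimToRise()]
#' @export
setClass("BumpAnnotation",
         slots = c(present = "logical", bumpEnd = "numeric",
                   peakValue = "numeric"))

setValidity("BumpAnnotation", function(object) {
  if (object@present && object@bumpEnd <= 0)
    return("a present bump must have bumpEnd > 0")
  if (!object@present && object@bumpEnd != 0)
    return("an absent bump has bumpEnd = 0")
  TRUE
})

setMethod("show", "BumpAnnotation", function(object) {
  if (object@present)
    cat(sprintf("BumpAnnotation: present, ends at %.4g s (peak %.3f)\n",
                object@bumpEnd, object@peakValue))
  else cat("BumpAnnotation: no bump detected\n")
})

## ---------------------------------------------------------------------------
## RhythmResult
## ---------------------------------------------------------------------------

#' Intrinsic pupil rhythm summary
#'
#' Quantifies the spontaneous open/closed switching of the superposition
#' pupil under constant darkness: detected switch times, mean period, and
#' the slow irreversible drift of the open-plateau level seen in small
#' specimens as the preparation deteriorates.
#'
#' @slot switchTimes hours, strictly increasing.
#' @slot meanPeriod mean of successive switch differences, hours (NA if
#'   fewer than 2 switches).
#' @slot sdPeriod SD of successive differences (NA if fewer than 3).
#' @slot nSwitches integer switch count.
#' @slot driftSlope open-plateau median slope, normalized brightness per
#'   hour (NA when not estimable).
#' @slot stateAtStart \code{"open"} or \code{"closed"}.
#' @seealso [analyzeRhythm()]
#' @export
setClass("RhythmResult",
         slots = c(switchTimes = "numeric", meanPeriod = "numeric",
                   sdPeriod = "numeric", nSwitches = "integer",
                   driftSlope = "numeric", stateAtStart = "character"))

setValidity("RhythmResult", function(object) {
  if (length(object@switchTimes) > 1 && any(diff(object@switchTimes) <= 0))
    return("'switchTimes' must be strictly increasing")
  if (object@nSwitches != length(object@switchTimes))
    return("'nSwitches' must equal length(switchTimes)")
  if (!object@stateAtStart %in% c("open", "closed"))
    return("'stateAtStart' must be 'open' or 'closed'")
  TRUE
})

#' @rdname switchTimes
#' @aliases switchTimes,RhythmResult-method
setMethod("switchTimes", "RhythmResult", function(x) x@switchTimes)

#' @rdname meanPeriod
#' @aliases meanPeriod,RhythmResult-method
setMethod("meanPeriod", "RhythmResult", function(x) x@meanPeriod)

#' @rdname driftSlope
#' @aliases driftSlope,RhythmResult-method
setMethod("driftSlope", "RhythmResult", function(x) x@driftSlope)

setMethod("show", "RhythmResult", function(object) {
  cat(sprintf("RhythmResult: %d switches, start state %s\n",
              object@nSwitches, object@stateAtStart))
  if (object@nSwitches)
    cat(sprintf("  switch times (h): %s\n",
                paste(sprintf("%.2f", object@switchTimes), collapse = ", ")))
  cat(sprintf("  mean period: %.3g h (sd %.3g), drift: %.3g /h\n",
              object@meanPeriod, object@sdPeriod, object@driftSlope))
})

## ---------------------------------------------------------------------------
## FrameStack and CircularROI
## ---------------------------------------------------------------------------

#' Grayscale image stack with per-frame timestamps
#'
#' Frames are stored as a numeric array \code{[row, col, frame]} of grey
#' values on the native integer scale (0..2^bitDepth - 1).
#'
#' @slot frames numeric 3-d array (rows x cols x n frames).
#' @slot timestamps seconds, strictly increasing, one per frame.
#' @slot bitDepth integer bit depth (8 for the rendered fixtures).
#' @export
setClass("FrameStack",
         slots = c(frames = "array", timestamps = "numeric",
                   bitDepth = "integer"))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("'frames' must be a 3-d array [row, col, frame]")
  if (d[3] != length(object@timestamps))
    return("number of frames must equal number of timestamps")
  if (length(object@timestamps) > 1 && any(diff(object@timestamps) <= 0))
    return("'timestamps' must be strictly increasing")
  if (object@bitDepth < 1L) return("'bitDepth' must be >= 1")
  TRUE
})

#' @describeIn FrameStack-class Constructor.
#' @param frames 3-d array or list of equal-sized matrices.
#' @param timestamps seconds.
#' @param bitDepth bit depth (default 8).
#' @export
FrameStack <- function(frames, timestamps, bitDepth = 8L) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (any(!vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share dimensions")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  new("FrameStack", frames = frames, timestamps = as.numeric(timestamps),
      bitDepth = as.integer(bitDepth))
}

#' @describeIn FrameStack-class Number of frames.
#' @param x a FrameStack.
#' @export
setMethod("length", "FrameStack", function(x) dim(x@frames)[3])

#' @rdname sampleTimes
#' @aliases sampleTimes,FrameStack-method
setMethod("sampleTimes", "FrameStack", function(x) x@timestamps)

#' @describeIn FrameStack-class Extract frame \code{i} as a matrix.
#' @param i frame index.
#' @param j,...,drop ignored.
#' @export
setMethod("[[", "FrameStack", function(x, i, j, ...) x@frames[, , i])

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px, %d-bit\n",
              d[3], d[1], d[2], object@bitDepth))
})

#' Circular region of interest
#'
#' Pixel coordinates use a 0-based pixel-centre convention: pixel (0, 0) is
#' the top-left pixel and its centre is at x = 0, y = 0 (x along columns,
#' y along rows). A pixel belongs to the ROI when its centre lies within
#' \code{radius} of the ROI centre.
#'
#' @slot cx,cy centre in pixels (0-based).
#' @slot radius radius in pixels (> 0).
#' @export
setClass("CircularROI", slots = c(cx = "numeric", cy = "numeric",
                                  radius = "numeric"))

setValidity("CircularROI", function(object) {
  if (object@radius <= 0) return("'radius' must be > 0")
  TRUE
})

#' @describeIn CircularROI-class Constructor.
#' @param cx,cy centre coordinates in pixels (0-based).
#' @param radius radius in pixels.
#' @export
CircularROI <- function(cx, cy, radius) {
  new("CircularROI", cx = as.numeric(cx), cy = as.numeric(cy),
      radius = as.numeric(radius))
}

setMethod("show", "CircularROI", function(object) {
  cat(sprintf("CircularROI: centre (%.4g, %.4g), radius %.4g px\n",
              object@cx, object@cy, object@radius))
})

## ---------------------------------------------------------------------------
## Generator parameter classes
## ---------------------------------------------------------------------------

#' Ground-truth kinetic parameters for simulation
#'
#' @slot b nonzero log-logistic slope; positive for closing, negative for
#'   opening.
#' @slot t50 positive half-brightness time, seconds.
#' @slot direction \code{"closing"} or \code{"opening"}.
#' @export
setClass("KineticTruth",
         slots = c(b = "numeric", t50 = "numeric", direction = "character"))

setValidity("KineticTruth", function(object) {
  if (object@t50 <= 0) return("'t50' must be > 0")
  if (object@b == 0) return("'b' must be nonzero")
  if (!object@direction %in% .DIRECTIONS)
    return("'direction' must be 'closing' or 'opening'")
  ok <- (object@direction == "closing" && object@b > 0) ||
    (object@direction == "opening" && object@b < 0)
  if (!ok)
    return("sign(b) must match direction (closing: b > 0, opening: b < 0)")
  TRUE
})

#' @describeIn KineticTruth-class Constructor; \code{direction} defaults to
#'   the sign convention implied by \code{b}.
#' @param b slope.
#' @param t50 half-time in seconds.
#' @param direction optional explicit direction.
#' @export
KineticTruth <- function(b, t50,
                         direction = if (b > 0) "closing" else "opening") {
  new("KineticTruth", b = as.numeric(b), t50 = as.numeric(t50),
      direction = direction)
}

#' @rdname curveDirection
#' @aliases curveDirection,KineticTruth-method
setMethod("curveDirection", "KineticTruth", function(x) x@direction)

#' @describeIn KineticTruth-class Ground-truth parameters as \code{c(b, t50)}.
#' @param object a KineticTruth.
#' @param ... ignored.
#' @export
setMethod("coef", "KineticTruth",
          function(object, ...) c(b = object@b, t50 = object@t50))

#' Parameters of the opening-curve transient ("bump")
#'
#' Additive pulse modelling the brightness transient at the start of dark
#' re-opening: the recording begins with the eye already brightened, the
#' pulse holds at \code{peakHeight} until \code{peakTime} and then decays
#' exponentially with time constant \code{decayTau}, producing the
#' characteristic dip ("minimum low") before the sigmoid rise.
#'
#' @slot peakHeight peak height in normalized brightness, in [0, 1].
#' @slot peakTime time of the peak, seconds (> 0).
#' @slot decayTau exponential decay time constant, seconds (> 0).
#' @export
setClass("BumpParams",
         slots = c(peakHeight = "numeric", peakTime = "numeric",
                   decayTau = "numeric"))

setValidity("BumpParams", function(object) {
  if (object@peakHeight < 0) return("'peakHeight' must be >= 0")
  if (object@peakTime <= 0) return("'peakTime' must be > 0")
  if (object@decayTau <= 0) return("'decayTau' must be > 0")
  TRUE
})

#' @describeIn BumpParams-class Constructor.
#' @param peakHeight peak height (normalized brightness).
#' @param peakTime peak time, s.
#' @param decayTau decay constant, s.
#' @export
BumpParams <- function(peakHeight, peakTime, decayTau) {
  new("BumpParams", peakHeight = as.numeric(peakHeight),
      peakTime = as.numeric(peakTime), decayTau = as.numeric(decayTau))
}

#' Parameters of the intrinsic circadian rhythm generator
#'
#' The constant-darkness series alternates between open (bright) and closed
#' (dark) plateaus every \code{periodH} hours with log-logistic-shaped
#' transitions, plus an optional linear drift of the brightness level
#' (negative for the irreversible closure seen in deteriorating small
#' preparations).
#'
#' @slot periodH plateau length, hours (> 0); default 12 to match a 12:12
#'   entrainment photoperiod.
#' @slot transitionB positive log-logistic shape of each transition.
#' @slot driftPerH linear drift of normalized brightness per hour (<= 0
#'   for deterioration).
#' @slot phaseOffsetH offset of the first switch relative to periodH, hours.
#' @export
setClass("IntrinsicParams",
         slots = c(periodH = "numeric", transitionB = "numeric",
                   driftPerH = "numeric", phaseOffsetH = "numeric"))

setValidity("IntrinsicParams", function(object) {
  if (object@periodH <= 0) return("'periodH' must be > 0")
  if (object@transitionB <= 0) return("'transitionB' must be > 0")
  TRUE
})

#' @describeIn IntrinsicParams-class Constructor with defaults emulating the
#'   12:12-entrained constant-darkness recordings.
#' @param periodH plateau length in hours.
#' @param transitionB transition shape parameter.
#' @param driftPerH linear drift per hour.
#' @param phaseOffsetH phase offset in hours.
#' @export
IntrinsicParams <- function(periodH = 12, transitionB = 8, driftPerH = 0,
                            phaseOffsetH = 0) {
  new("IntrinsicParams", periodH = as.numeric(periodH),
      transitionB = as.numeric(transitionB),
      driftPerH = as.numeric(driftPerH),
      phaseOffsetH = as.numeric(phaseOffsetH))
}

#' Additive noise model for the simulators
#'
#' Gaussian noise expressed in normalized-brightness units; the simulators
#' scale it by the camera amplitude when adding it to camera-scale grey
#' values. Identical seeds reproduce identical series.
#'
#' @slot sigma nonnegative SD, normalized-brightness units.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseModel", slots = c(sigma = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (object@sigma < 0) return("'sigma' must be >= 0")
  TRUE
})

#' @describeIn NoiseModel-class Constructor.
#' @param sigma noise SD (default 0.03).
#' @param seed RNG seed.
#' @export
NoiseModel <- function(sigma = 0.03, seed = 1L) {
  new("NoiseModel", sigma = as.numeric(sigma), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Statistics containers
## ---------------------------------------------------------------------------

#' Nested Gaussian GLM hierarchy
#'
#' Gaussian-family models of a kinetic parameter on
#' \code{~ (sex + species + temperature)^n} for n = 0 (intercept only)
#' up to \code{maxOrder}, with sequential F-test p-values between
#' consecutive orders and per-model AIC. \code{stats::AIC} counts the
#' dispersion parameter, so the intercept-only model has k = 2; comparisons
#' between orders are unaffected by this constant convention.
#'
#' @slot response name of the modelled response.
#' @slot models list of fitted \code{glm} objects, index n + 1.
#' @slot formulas character descriptions of the designs.
#' @slot aic AIC per order.
#' @slot logLik log-likelihood per order.
#' @slot dfResidual residual df per order.
#' @slot pSequential p-value of the F test of order n vs n - 1 (NA for
#'   n = 0), aligned with \code{models}.
#' @slot maxOrder highest order actually fitted (may be downgraded when the
#'   design has empty cells).
#' @seealso [fitGlmHierarchy()], [selectModel()]
#' @export
setClass("ModelHierarchy",
         slots = c(response = "character", models = "list",
                   formulas = "character", aic = "numeric",
                   logLik = "numeric", dfResidual = "numeric",
                   pSequential = "numeric", maxOrder = "integer"))

setValidity("ModelHierarchy", function(object) {
  n <- length(object@models)
  if (n != object@maxOrder + 1L)
    return("'models' must hold orders 0..maxOrder")
  if (length(object@aic) != n || length(object@pSequential) != n)
    return("'aic' and 'pSequential' must align with 'models'")
  TRUE
})

setMethod("show", "ModelHierarchy", function(object) {
  cat(sprintf("ModelHierarchy for '%s' (orders 0..%d)\n",
              object@response, object@maxOrder))
  for (i in seq_along(object@models)) {
    cat(sprintf("  n=%d: AIC = %.2f, logLik = %.2f, seq p = %s\n",
                i - 1L, object@aic[i], object@logLik[i],
                ifelse(is.na(object@pSequential[i]), "-",
                       format.pval(object@pSequential[i], digits = 3))))
  }
})

#' Marginal-mean contrast table
#'
#' Estimated marginal means for one factor of a chosen model, all pairwise
#' differences with Tukey (studentized-range) adjustment, and a compact
#' letter display in which levels sharing a letter are not significantly
#' different at \code{alpha}.
#'
#' @slot factor name of the factor compared.
#' @slot emmeans data.frame of level, emmean, SE, df, letters.
#' @slot contrasts data.frame of pairwise contrasts with adjusted p.
#' @slot alpha significance level used for the letters.
#' @seealso [emmPairwise()]
#' @export
setClass("ContrastTable",
         slots = c(factor = "character", emmeans = "data.frame",
                   contrasts = "data.frame", alpha = "numeric"))

setMethod("show", "ContrastTable", function(object) {
  cat(sprintf("ContrastTable for '%s' (Tukey-adjusted, alpha = %.2f)\n",
              object@factor, object@alpha))
  print(object@emmeans, row.names = FALSE)
})
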