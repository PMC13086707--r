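#' Sampling times of a series
#'
#' @param x a \linkS4class{ReflectanceSeries}, \linkS4class{NormalizedCurve}
#'   or \linkS4class{FrameStack}.
#' @return Numeric vector of times in seconds.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' Sample values of a series
#'
#' @param x a \linkS4class{ReflectanceSeries} or \linkS4class{NormalizedCurve}.
#' @return Numeric vector of brightness values.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' Units flag of a series
#'
#' @param x a \linkS4class{ReflectanceSeries} or \linkS4class{NormalizedCurve}.
#' @return One of \code{"raw"}, \code{"corrected"}, \code{"normalized"}.
#' @export
setGeneric("seriesUnits", function(x) standardGeneric("seriesUnits"))

#' Simulation ground truth attached to a series
#'
#' Synthetic series carry the noiseless normalized signal and the generating
#' parameters so that parameter-recovery tests can compare against them.
#'
#' @param x a \linkS4class{ReflectanceSeries} or \linkS4class{NormalizedCurve}.
#' @return A list (possibly empty) with elements such as \code{signal},
#'   \code{truth}, \code{switch_times_h}.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Amplitude of a camera calibration
#'
#' @param x a \linkS4class{CameraCalibration}.
#' @return The amplitude A (grey-value units per unit luminance^gamma).
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' Gamma exponent of a camera calibration
#'
#' @param x a \linkS4class{CameraCalibration}.
#' @return The dimensionless exponent gamma.
#' @export
setGeneric("gammaExponent", function(x) standardGeneric("gammaExponent"))

#' Direction of a curve or fit
#'
#' @param x a \linkS4class{NormalizedCurve}, \linkS4class{KineticTruth} or
#'   \linkS4class{LogLogisticFit}.
#' @return \code{"closing"} or \code{"opening"}.
#' @export
setGeneric("curveDirection", function(x) standardGeneric("curveDirection"))

#' Goodness of fit
#'
#' @param x a \linkS4class{LogLogisticFit}.
#' @return R-squared of the fit (1 - SS_res/SS_tot).
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' Detected open/closed switch times
#'
#' @param x a \linkS4class{RhythmResult}.
#' @return Numeric vector of switch times in hours.
#' @export
setGeneric("switchTimes", function(x) standardGeneric("switchTimes"))

#' Mean switching period
#'
#' @param x a \linkS4class{RhythmResult}.
#' @return Mean of successive switch-time differences, hours (NA when fewer
#'   than two switches were found).
#' @export
setGeneric("meanPeriod", function(x) standardGeneric("meanPeriod"))

#' Slow drift of the open-plateau level
#'
#' @param x a \linkS4class{RhythmResult}.
#' @return Slope of the open-plateau median level, normalized brightness per
#'   hour (NA when not estimable).
#' @export
setGeneric("driftSlope", function(x) standardGeneric("driftSlope"))

#' Apply the inverse camera transfer function to a raw series
#'
#' @param series a \linkS4class{ReflectanceSeries} with units \code{"raw"}.
#' @param calib a \linkS4class{CameraCalibration}.
#' @param ... further arguments passed to methods.
#' @return A \linkS4class{ReflectanceSeries} with units \code{"corrected"}.
#' @export
setGeneric("correctSeries",
           function(series, calib, ...) standardGeneric("correctSeries"))

#' Extract the integrated-density time series from an image stack
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param roi a \linkS4class{CircularROI}.
#' @param ... further arguments passed to methods.
#' @return A \linkS4class{ReflectanceSeries} with units \code{"raw"}.
#' @export
setGeneric("extractSeries",
           function(stack, roi, ...) standardGeneric("extractSeries"))
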