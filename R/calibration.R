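## Camera gamma calibration: fit Y_out = A * Y_in^gamma to chart pairs and
## apply the inverse to linearize measured series.

#' Fit the camera gamma transfer function
#'
#' Nonlinear least squares of \eqn{Y_{out} = A \cdot Y_{in}^{\gamma}} on
#' calibration pairs, initialized from the log-log linear regression
#' (\eqn{\log Y_{out} = \log A + \gamma \log Y_{in}}). The fit is performed
#' in the original response space with a Levenberg-Marquardt optimizer.
#'
#' @param pairs data.frame with columns \code{Y_in}, \code{Y_out} (or any
#'   two-column numeric object, taken in that order); at least 3 pairs,
#'   all values > 0.
#' @return A \linkS4class{CameraCalibration} with the residual sum of
#'   squares in its \code{rss} slot.
#' @export
#' @examples
#' p <- generateCalibrationPairs(CameraCalibration(16.71, 0.58), (1:24) / 24)
#' fitGamma(p)
fitGamma <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("Y_in", "Y_out") %in% names(pairs))) {
    if (ncol(pairs) < 2) stop("'pairs' needs columns Y_in and Y_out")
    names(pairs)[1:2] <- c("Y_in", "Y_out")
  }
  yin <- pairs$Y_in; yout <- pairs$Y_out
  if (length(yin) < 3)
    stop("at least 3 calibration pairs are required (got ", length(yin), ")")
  if (any(yin <= 0) || any(yout <= 0))
    stop("all calibration values must be > 0")
  init <- stats::lm(log(yout) ~ log(yin))
  start <- list(A = exp(stats::coef(init)[[1]]),
                g = stats::coef(init)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(yout ~ A * yin^g, start = start,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-14, ptol = 1e-14, maxiter = 200)),
    error = function(e)
      stop("gamma calibration fit failed to converge: ",
           conditionMessage(e)))
  est <- stats::coef(fit)
  CameraCalibration(A = est[["A"]], gamma = est[["g"]],
                    rss = sum(stats::residuals(fit)^2))
}

#' @rdname correctSeries
#' @aliases correctSeries,ReflectanceSeries,CameraCalibration-method
#' @details Each raw grey value is mapped through the inverse transfer
#'   function \eqn{Y_{corr} = (Y_{meas}/A)^{1/\gamma}}, which preserves the
#'   ordering of values (the transfer function is strictly increasing).
#'   Values above the calibration amplitude correct to > 1; such
#'   extrapolation is allowed and reported with a message.
setMethod("correctSeries", signature("ReflectanceSeries",
                                     "CameraCalibration"),
          function(series, calib, ...) {
  if (seriesUnits(series) != "raw")
    stop("correctSeries expects a series with units 'raw', got '",
         seriesUnits(series), "'")
  v <- seriesValues(series)
  if (any(v < 0)) stop("raw grey values must be >= 0")
  corr <- (v / calib@A)^(1 / calib@gamma)
  nOut <- sum(v > calib@A)
  if (nOut > 0)
    message(nOut, " value(s) above the calibration amplitude; ",
            "corrected by extrapolation (> 1)")
  ReflectanceSeries(times = sampleTimes(series), values = corr,
                    units = "corrected", groundTruth = groundTruth(series))
})

#' Write / read a camera calibration as JSON
#'
#' @param calib a \linkS4class{CameraCalibration}.
#' @param path JSON file path.
#' @return \code{writeCalibrationJSON}: \code{path} invisibly;
#'   \code{readCalibrationJSON}: a \linkS4class{CameraCalibration}.
#' @export
writeCalibrationJSON <- function(calib, path) {
  stopifnot(is(calib, "CameraCalibration"))
  jsonlite::write_json(list(A = calib@A, gamma = calib@gamma,
                            rss = calib@rss),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJSON
#' @export
readCalibrationJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  CameraCalibration(A = x$A, gamma = x$gamma,
                    rss = if (is.null(x$rss)) 0 else x$rss)
}
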