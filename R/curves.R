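## Log-logistic (Lipetz-type) pupil kinetics: normalization, opening-bump
## exclusion, and two-parameter nonlinear least-squares fitting.

#' The two-parameter log-logistic sigmoid
#'
#' \deqn{f(x) = \frac{1}{1 + \exp(b(\log x - \log t_{50}))}}
#'
#' Strictly monotone in x for nonzero b: decreasing for b > 0 (pupil
#' closing) and increasing for b < 0 (pupil opening), with asymptotes 0 and
#' 1 and \eqn{f(t_{50}) = 0.5} exactly. At x = 0 the one-sided limit is
#' returned (1 for b > 0, 0 for b < 0).
#'
#' @param x times, >= 0.
#' @param b slope parameter (nonzero).
#' @param t50 half-brightness time (> 0).
#' @return f(x), in [0, 1].
#' @export
#' @examples
#' logLogistic(300, b = 2, t50 = 300)  # 0.5
logLogistic <- function(x, b, t50) {
  if (t50 <= 0) stop("'t50' must be > 0")
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- 1 / (1 + exp(b * (log(x[pos]) - log(t50))))
  out[!pos] <- if (b > 0) 1 else 0
  out
}

#' Min-max normalize a corrected reflectance series
#'
#' Rescales the curve's minimum and maximum brightness (taken over the full
#' series) to 0 and 1 and re-zeroes time at the first sample. The direction
#' label is inferred from the sign of the early-vs-late brightness change
#' unless given explicitly.
#'
#' @param series a \linkS4class{ReflectanceSeries} with units
#'   \code{"corrected"} (or an already-normalized curve, returned with its
#'   values re-normalized, making the operation idempotent); at least 2
#'   samples with max > min.
#' @param direction optional \code{"closing"} or \code{"opening"}.
#' @return A \linkS4class{NormalizedCurve}.
#' @export
normalizeCurve <- function(series, direction = NULL) {
  stopifnot(is(series, "ReflectanceSeries"))
  if (seriesUnits(series) == "raw")
    stop("normalize a corrected series (apply correctSeries first)")
  v <- seriesValues(series)
  if (length(v) < 2) stop("at least 2 samples are required")
  vn <- rescale01(v, "curve")
  if (is.null(direction)) {
    k <- max(2L, ceiling(length(vn) / 10))
    direction <- if (mean(vn[seq_len(k)]) >
                     mean(vn[seq(length(vn) - k + 1L, length(vn))]))
      "closing" else "opening"
  }
  t <- sampleTimes(series)
  NormalizedCurve(times = t - t[1], values = vn, direction = direction,
                  groundTruth = groundTruth(series))
}

#' Detect the opening transient ("bump")
#'
#' Dark re-opening curves typically begin with a short transient: a sudden
#' brightness increase that decays to a minimum before the sigmoid rise.
#' On the smoothed curve (centered moving average, width
#' \code{smoothWidth}), the first local maximum within the search window
#' marks the transient's peak (the first sample qualifies when the curve
#' starts elevated and falls); the bump end is the windowed minimum after
#' that peak - the "minimum low" at which the sigmoid rise begins. A bump
#' is reported only when the peak stands at least \code{minProminence}
#' above that minimum, so monotone or flat-then-rising curves are
#' bump-free.
#'
#' @param curve an opening \linkS4class{NormalizedCurve}.
#' @param windowS search window from the start, seconds; default 20 min,
#'   covering the observed 5-15 min transients. Must not exceed the
#'   recording span.
#' @param smoothWidth moving-average width in samples (default 5).
#' @param minProminence minimum drop from the peak to the following
#'   minimum (normalized brightness) for the transient to count; guards
#'   against flat starts and noise ripples.
#' @return A \linkS4class{BumpAnnotation}.
#' @export
detectBump <- function(curve, windowS = 1200, smoothWidth = 5L,
                       minProminence = 0.02) {
  stopifnot(is(curve, "NormalizedCurve"))
  if (curveDirection(curve) != "opening")
    stop("bump detection applies to opening curves only")
  t <- sampleTimes(curve)
  if (windowS <= 0 || windowS > diff(range(t)))
    stop("'windowS' must be positive and no larger than the recording span")
  s <- movingAverage(seriesValues(curve), smoothWidth)
  win <- which(t - t[1] <= windowS)
  # first local maximum in the window (the first sample counts when the
  # curve starts at an elevated level and falls from it)
  iPeak <- NA_integer_
  for (i in win[win < length(s)]) {
    atMax <- if (i == 1L) s[1L] >= s[2L]
             else s[i] >= s[i - 1L] && s[i] >= s[i + 1L]
    if (atMax) { iPeak <- i; break }
  }
  if (is.na(iPeak) || !any(win > iPeak))
    return(new("BumpAnnotation", present = FALSE, bumpEnd = 0,
               peakValue = NA_real_))
  after <- win[win > iPeak]
  iMin <- after[which.min(s[after])]
  if (s[iPeak] - s[iMin] < minProminence)   # flat start, not a transient
    return(new("BumpAnnotation", present = FALSE, bumpEnd = 0,
               peakValue = NA_real_))
  new("BumpAnnotation", present = TRUE, bumpEnd = t[iMin] - t[1],
      peakValue = s[iPeak])
}

#' Trim an opening curve to its sigmoid rising part
#'
#' Removes all samples before the bump end (the windowed minimum where the
#' rise begins), re-zeroes time there, and re-normalizes the retained span
#' to [0, 1]. With no bump present the curve is returned with only the
#' (no-op) re-normalization applied.
#'
#' @param curve the opening \linkS4class{NormalizedCurve} the annotation
#'   was computed on.
#' @param annotation a \linkS4class{BumpAnnotation} from [detectBump()].
#' @param minSamples minimum retained samples (default 5).
#' @return A \linkS4class{NormalizedCurve}.
#' @export
trimToRise <- function(curve, annotation, minSamples = 5L) {
  stopifnot(is(curve, "NormalizedCurve"), is(annotation, "BumpAnnotation"))
  t <- sampleTimes(curve)
  v <- seriesValues(curve)
  if (annotation@present) {
    keep <- t >= annotation@bumpEnd
    if (sum(keep) < minSamples)
      stop("trimming the transient leaves fewer than ", minSamples,
           " samples")
    t <- t[keep] - annotation@bumpEnd
    v <- v[keep]
  }
  NormalizedCurve(times = t, values = rescale01(v, "trimmed curve"),
                  direction = curveDirection(curve),
                  groundTruth = groundTruth(curve))
}

# Initial values for (b, log t50) from the quantile-crossing heuristic:
# t50 from the interpolated 0.5 crossing; b from the spread between the
# 0.75 and 0.25 crossings. NULL when crossings are absent.
.llInit <- function(x, y) {
  t50 <- firstCrossing(x, y, 0.5)
  t25 <- firstCrossing(x, y, 0.25)
  t75 <- firstCrossing(x, y, 0.75)
  if (is.na(t50) || t50 <= 0) return(NULL)
  b0 <- if (!is.na(t25) && !is.na(t75) && t25 > 0 && t75 > 0 &&
            abs(log(t25) - log(t75)) > 1e-12)
    4 / (log(t25) - log(t75)) else NULL
  if (is.null(b0)) return(NULL)
  list(b = b0, lt50 = log(t50))
}

.llSS <- function(par, x, y) {
  f <- 1 / (1 + exp(par[1] * (log(x) - par[2])))
  sum((y - f)^2)
}

#' Fit the log-logistic model to a normalized pupil curve
#'
#' Least-squares estimation of (b, t50) for
#' \eqn{f(x) = 1/(1+\exp(b(\log x - \log t_{50})))}. The model has no
#' offset or amplitude terms: its asymptotes are fixed at 0 and 1, the
#' curve-through-origin constraint. Optimization runs on (b, log t50) with
#' a Levenberg-Marquardt least-squares solver (convergence tolerance 1e-10
#' on the sum of squares, at most 500 iterations), initialized from the
#' interpolated quantile crossings of the data; when crossings are absent a
#' grid of slopes b in {+-0.5, +-1, +-2, +-4, +-8} (sign matching the curve
#' direction) times candidate t50 values is searched and the best cell is
#' polished.
#'
#' A sample at exactly t = 0 would put log(0) into the loss; it is shifted
#' forward by half the sampling interval (\code{zeroShift} overrides).
#'
#' @param curve a \linkS4class{NormalizedCurve} with at least 5 samples.
#' @param zeroShift replacement time for a sample at t = 0; default
#'   \code{dt/2}.
#' @return A \linkS4class{LogLogisticFit}; its \code{converged} slot is
#'   FALSE (with diagnostics in \code{message}) when the optimizer failed.
#' @export
#' @examples
#' t <- 1:900
#' crv <- NormalizedCurve(t, logLogistic(t, 2.5, 300), "closing")
#' fitLogLogistic(crv)
fitLogLogistic <- function(curve, zeroShift = NULL) {
  stopifnot(is(curve, "NormalizedCurve"))
  x <- sampleTimes(curve)
  y <- seriesValues(curve)
  if (length(x) < 5) stop("at least 5 samples are required")
  if (all(is.na(y))) stop("all values are NA")
  if (x[1] == 0) {
    x[1] <- if (is.null(zeroShift)) (x[2] - x[1]) / 2 else zeroShift
  }
  if (any(x <= 0)) stop("all times entering the fit must be > 0")
  dirSign <- if (curveDirection(curve) == "closing") 1 else -1

  start <- .llInit(x, y)
  fit <- NULL
  if (!is.null(start)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + exp(b * (log(x) - lt50))),
                        start = start,
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    # grid fallback over slope magnitudes and candidate half-times
    bGrid <- dirSign * c(0.5, 1, 2, 4, 8)
    tGrid <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    grid <- expand.grid(b = bGrid, lt50 = log(tGrid))
    ss <- apply(grid, 1, function(p) .llSS(p, x, y))
    best <- as.numeric(grid[which.min(ss), ])
    opt <- stats::optim(best, .llSS, x = x, y = y, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + exp(b * (log(x) - lt50))),
                        start = list(b = opt$par[1], lt50 = opt$par[2]),
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(new("LogLogisticFit", b = opt$par[1], t50 = exp(opt$par[2]),
                 rSquared = 1 - opt$value / sum((y - mean(y))^2),
                 direction = curveDirection(curve), converged = FALSE,
                 message = "optimizer did not converge; grid/simplex value"))
    }
  }
  est <- stats::coef(fit)
  b <- est[["b"]]; t50 <- exp(est[["lt50"]])
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  if (sign(b) != dirSign)
    warning("fitted slope sign (b = ", format(b, digits = 3),
            ") is inconsistent with the declared '",
            curveDirection(curve), "' direction")
  new("LogLogisticFit", b = b, t50 = t50,
      rSquared = 1 - ssRes / ssTot,
      direction = curveDirection(curve), converged = TRUE,
      message = "converged")
}

#' Run the full induced-curve pipeline on a raw series
#'
#' Convenience wrapper: camera correction, normalization, bump exclusion
#' (opening curves), and log-logistic fitting.
#'
#' @param series a raw \linkS4class{ReflectanceSeries}.
#' @param calib a \linkS4class{CameraCalibration}.
#' @param direction \code{"closing"} or \code{"opening"} (inferred when
#'   NULL).
#' @param bumpWindowS bump search window for opening curves, seconds.
#' @return A list with elements \code{fit} (\linkS4class{LogLogisticFit}),
#'   \code{curve} (the fitted \linkS4class{NormalizedCurve}) and
#'   \code{bump} (\linkS4class{BumpAnnotation} or NULL).
#' @export
fitInducedCurve <- function(series, calib, direction = NULL,
                            bumpWindowS = 1200) {
  curve <- normalizeCurve(correctSeries(series, calib), direction)
  bump <- NULL
  if (curveDirection(curve) == "opening") {
    bump <- detectBump(curve, windowS = min(bumpWindowS,
                                            diff(range(sampleTimes(curve)))))
    curve <- trimToRise(curve, bump)
  }
  list(fit = fitLogLogistic(curve), curve = curve, bump = bump)
}
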