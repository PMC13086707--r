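## Intrinsic circadian pupil rhythm: hysteresis switch detection, period
## estimation and open-plateau drift estimation on constant-darkness series.

# Smooth / optionally detrend / re-normalize a curve for switch detection.
# Returns list(tH, s) with times in hours.
.rhythmSignal <- function(curve, smoothWidth, detrendSlope = 0) {
  tH <- sampleTimes(curve) / 3600
  s <- movingAverage(seriesValues(curve), smoothWidth)
  if (detrendSlope != 0) s <- s - detrendSlope * (tH - tH[1])
  rng <- range(s)
  if (rng[2] > rng[1]) s <- (s - rng[1]) / (rng[2] - rng[1])
  list(tH = tH, s = s)
}

#' Detect open/closed state switches with a hysteresis detector
#'
#' The smoothed (and, by default, drift-detrended) normalized series is
#' scanned for 0.5 crossings; a crossing counts as a switch only when the
#' series was beyond the outer threshold (\code{high} for a falling switch,
#' \code{low} for a rising one) since the previous switch and reaches the
#' opposite threshold before the next crossing - i.e. full-amplitude
#' transitions only. The switch time is the linearly interpolated
#' 0.5 crossing. Switches closer than \code{refractoryH} hours to the
#' previous accepted one are discarded.
#'
#' @param curve a \linkS4class{NormalizedCurve} (times in seconds).
#' @param low,high hysteresis thresholds, \code{0 < low < high < 1}
#'   (defaults 0.3 / 0.7).
#' @param refractoryH refractory interval, hours (default 2).
#' @param smoothWidth moving-average width in samples (default 3, i.e.
#'   15 min at the 5-min sampling of the study).
#' @param detrend when TRUE (default), the open-plateau drift line is
#'   estimated first and subtracted before detection when estimable.
#' @param nominalPeriodH nominal period used by the internal drift
#'   estimate, hours.
#' @return Numeric vector of switch times in hours (possibly empty).
#' @export
detectSwitches <- function(curve, low = 0.3, high = 0.7, refractoryH = 2,
                           smoothWidth = 3L, detrend = TRUE,
                           nominalPeriodH = 12) {
  stopifnot(is(curve, "NormalizedCurve"))
  if (!(low > 0 && low < high && high < 1))
    stop("need 0 < low < high < 1 (got low = ", low, ", high = ", high, ")")
  slope <- 0
  if (detrend) {
    dr <- tryCatch(
      estimateDrift(curve, nominalPeriodH = nominalPeriodH, low = low,
                    high = high, smoothWidth = smoothWidth),
      error = function(e) list(estimable = FALSE))
    if (isTRUE(dr$estimable)) slope <- dr$slope_per_h
  }
  sig <- .rhythmSignal(curve, smoothWidth, slope)
  tH <- sig$tH; s <- sig$s
  d <- s - 0.5
  cross <- which(d[-length(d)] * d[-1] < 0 | (d[-length(d)] != 0 & d[-1] == 0))
  if (!length(cross)) return(numeric(0))
  accepted <- numeric(0)
  lastIdx <- 1L
  for (j in seq_along(cross)) {
    i <- cross[j]
    tx <- tH[i] + (tH[i + 1] - tH[i]) * (-d[i]) / (d[i + 1] - d[i])
    falling <- d[i] > 0 || (d[i] == 0 && d[i + 1] < 0)
    segBefore <- s[lastIdx:i]
    nxt <- if (j < length(cross)) cross[j + 1] else length(s)
    segAfter <- s[(i + 1):nxt]
    armed <- if (falling) max(segBefore) >= high else min(segBefore) <= low
    completes <- if (falling) min(segAfter) <= low else max(segAfter) >= high
    if (armed && completes &&
        (!length(accepted) || tx - accepted[length(accepted)] >= refractoryH)) {
      accepted <- c(accepted, tx)
      lastIdx <- i + 1L
    }
  }
  accepted
}

#' Estimate the mean switching period
#'
#' @param switchTimesH switch times in hours, strictly increasing.
#' @return A list with \code{estimable}, \code{mean_period_h},
#'   \code{sd_period_h} and \code{n_intervals}. With fewer than 2 switches
#'   the result is flagged not estimable.
#' @export
#' @examples
#' estimatePeriod(c(12, 24, 36))$mean_period_h  # 12
estimatePeriod <- function(switchTimesH) {
  if (length(switchTimesH) < 2)
    return(list(estimable = FALSE, mean_period_h = NA_real_,
                sd_period_h = NA_real_, n_intervals = 0L))
  dd <- diff(switchTimesH)
  list(estimable = TRUE, mean_period_h = mean(dd),
       sd_period_h = if (length(dd) > 1) stats::sd(dd) else NA_real_,
       n_intervals = length(dd))
}

#' Estimate the slow drift of the open-plateau level
#'
#' Detects switches without detrending, takes the per-cycle open plateaus
#' (segments whose median smoothed level exceeds 0.5), computes the median
#' level over the central half of each plateau, and fits a least-squares
#' line through (plateau mid-time, median level). This is robust to the
#' rhythm itself; the slope captures the gradual irreversible closure seen
#' in deteriorating preparations.
#'
#' @param curve a \linkS4class{NormalizedCurve} spanning at least two
#'   nominal periods.
#' @param nominalPeriodH nominal rhythm period, hours.
#' @param low,high,smoothWidth passed to the internal switch detection.
#' @return A list with \code{estimable}, \code{slope_per_h} (normalized
#'   brightness per hour) and \code{n_plateaus}. Fewer than 2 open plateaus
#'   gives \code{estimable = FALSE}.
#' @export
estimateDrift <- function(curve, nominalPeriodH = 12, low = 0.3,
                          high = 0.7, smoothWidth = 3L) {
  stopifnot(is(curve, "NormalizedCurve"))
  tH <- sampleTimes(curve) / 3600
  if (diff(range(tH)) < 2 * nominalPeriodH)
    stop("recording must span at least two nominal periods (",
         2 * nominalPeriodH, " h)")
  sw <- detectSwitches(curve, low = low, high = high,
                       smoothWidth = smoothWidth, detrend = FALSE,
                       nominalPeriodH = nominalPeriodH)
  sig <- .rhythmSignal(curve, smoothWidth)
  edges <- c(tH[1], sw, tH[length(tH)])
  mids <- numeric(0); levels <- numeric(0)
  for (k in seq_len(length(edges) - 1L)) {
    inSeg <- tH >= edges[k] & tH <= edges[k + 1L]
    if (sum(inSeg) < 3) next
    if (stats::median(sig$s[inSeg]) <= 0.5) next  # closed plateau
    span <- edges[k + 1L] - edges[k]
    central <- inSeg & tH >= edges[k] + span / 4 &
      tH <= edges[k + 1L] - span / 4
    if (sum(central) < 2) central <- inSeg
    # drift is measured on the unsmoothed normalized values
    mids <- c(mids, mean(tH[central]))
    levels <- c(levels, stats::median(seriesValues(curve)[central]))
  }
  if (length(mids) < 2)
    return(list(estimable = FALSE, slope_per_h = NA_real_,
                n_plateaus = length(mids)))
  fit <- stats::lm(levels ~ mids)
  list(estimable = TRUE, slope_per_h = unname(stats::coef(fit)[2]),
       n_plateaus = length(mids))
}

#' Full rhythm analysis of a constant-darkness recording
#'
#' Runs drift estimation, hysteresis switch detection and period
#' estimation, and packages the result.
#'
#' @param curve a \linkS4class{NormalizedCurve}.
#' @param low,high hysteresis thresholds.
#' @param nominalPeriodH nominal period for drift estimation, hours.
#' @param smoothWidth moving-average width, samples.
#' @return A \linkS4class{RhythmResult}.
#' @export
#' @examples
#' s <- simulateIntrinsicSeries(IntrinsicParams(), noise = NoiseModel(0.05, 7))
#' crv <- normalizeCurve(correctSeries(s, CameraCalibration(16.71, 0.58)))
#' analyzeRhythm(crv)
analyzeRhythm <- function(curve, low = 0.3, high = 0.7,
                          nominalPeriodH = 12, smoothWidth = 3L) {
  sw <- detectSwitches(curve, low = low, high = high,
                       smoothWidth = smoothWidth,
                       nominalPeriodH = nominalPeriodH)
  per <- estimatePeriod(sw)
  dr <- tryCatch(
    estimateDrift(curve, nominalPeriodH = nominalPeriodH, low = low,
                  high = high, smoothWidth = smoothWidth),
    error = function(e) list(estimable = FALSE, slope_per_h = NA_real_))
  s0 <- movingAverage(seriesValues(curve), smoothWidth)[1]
  new("RhythmResult", switchTimes = sw,
      meanPeriod = per$mean_period_h, sdPeriod = per$sd_period_h,
      nSwitches = length(sw), driftSlope = dr$slope_per_h,
      stateAtStart = if (s0 > 0.5) "open" else "closed")
}
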