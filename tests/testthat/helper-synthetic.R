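# Shared fixtures for the test suite: the study camera, an identity camera,
# and quiet pipeline wrappers (correctSeries messages about extrapolated
# values are expected on noisy series).

studyCamera <- function() CameraCalibration(A = 16.71, gamma = 0.58)
identityCamera <- function() CameraCalibration(A = 1, gamma = 1)

quietCorrect <- function(series, calib) {
  suppressMessages(correctSeries(series, calib))
}

quietPipeline <- function(series, calib, direction = NULL, ...) {
  suppressMessages(fitInducedCurve(series, calib, direction, ...))
}

# Independent brute-force oracle for integrated density: double loop over
# all pixels, 0-based pixel-centre membership.
bruteIntegratedDensity <- function(frame, cx, cy, r) {
  acc <- 0
  for (row in seq_len(nrow(frame))) {
    for (col in seq_len(ncol(frame))) {
      x <- col - 1; y <- row - 1
      if ((x - cx)^2 + (y - cy)^2 <= r^2) acc <- acc + frame[row, col]
    }
  }
  acc
}
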