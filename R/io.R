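## CSV interchange for reflectance series and per-curve parameter rows.

#' Read a reflectance series from CSV
#'
#' Expects columns \code{time_s} and \code{value}.
#'
#' @param path CSV file path.
#' @param units units flag of the stored values (default \code{"raw"}).
#' @return A \linkS4class{ReflectanceSeries}.
#' @export
readReflectanceCSV <- function(path, units = "raw") {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("CSV must have columns 'time_s' and 'value'")
  ReflectanceSeries(times = d$time_s, values = d$value, units = units)
}

#' Write a reflectance series to CSV
#'
#' @param series a \linkS4class{ReflectanceSeries}.
#' @param path output CSV path (columns \code{time_s}, \code{value}).
#' @return \code{path}, invisibly.
#' @export
writeReflectanceCSV <- function(series, path) {
  stopifnot(is(series, "ReflectanceSeries"))
  utils::write.csv(data.frame(time_s = sampleTimes(series),
                              value = seriesValues(series)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Summarise a set of fitted curves as a parameter table
#'
#' Builds the per-curve row type consumed by the statistics module from a
#' list of fits plus specimen metadata.
#'
#' @param fits list of \linkS4class{LogLogisticFit} objects.
#' @param metadata data.frame with one row per fit (columns such as
#'   \code{specimen_id}, \code{species}, \code{sex}, \code{temperature_C},
#'   \code{phase}).
#' @return The metadata with \code{b}, \code{t50_s}, \code{r_squared} and
#'   \code{converged} columns appended.
#' @export
fitTable <- function(fits, metadata) {
  stopifnot(length(fits) == nrow(metadata))
  cbind(metadata,
        b = vapply(fits, function(f) f@b, numeric(1)),
        t50_s = vapply(fits, function(f) f@t50, numeric(1)),
        r_squared = vapply(fits, rSquared, numeric(1)),
        converged = vapply(fits, function(f) f@converged, logical(1)))
}
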