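## Eye morphometry utilities: interommatidial angle from an ommatidia count
## along a half-meridian arc, algebraic circle fitting to eye outlines, and
## the packaged morphometry reference table.

#' Interommatidial angle from an arc count
#'
#' The interommatidial angle is estimated from a cross-section
#' perpendicular to the eye surface by counting the ommatidia along the
#' 180-degree arc and dividing 180 by that count.
#'
#' @param n number of ommatidia counted along the half-meridian arc
#'   (>= 1).
#' @return Angle in degrees.
#' @export
#' @examples
#' interommatidialAngle(45)  # 4 degrees
interommatidialAngle <- function(n) {
  if (any(n < 1)) stop("the ommatidia count must be >= 1")
  180 / n
}

#' Least-squares circle fit (Kasa algebraic method)
#'
#' Fits a circle to 2-d points by minimizing the algebraic residual of
#' \eqn{x^2 + y^2 = 2 a x + 2 b y + c}, a linear least-squares problem.
#' The fit is exact on noiseless circular points and needs no
#' initialization, replacing the manual circle fitting used on eye-outline
#' exports.
#'
#' @param points matrix or data.frame with two columns (x, y), at least 3
#'   non-collinear points.
#' @return A list with \code{centre} (length-2 numeric) and \code{radius}.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' fitCircle(cbind(290 * cos(th), 290 * sin(th)))$radius  # 290
fitCircle <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) < 2 || nrow(points) < 3)
    stop("at least 3 (x, y) points are required")
  x <- points[, 1]; y <- points[, 2]
  X <- cbind(2 * x, 2 * y, 1)
  if (qr(cbind(1, x, y))$rank < 3)
    stop("points are collinear; no unique circle")
  sol <- stats::lm.fit(X, x^2 + y^2)$coefficients
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate circle fit (nonpositive squared radius)")
  list(centre = unname(sol[1:2]), radius = unname(sqrt(r2)))
}

#' Packaged eye-morphometry reference table
#'
#' Per species (CP = Cydia pomonella, LB = Lobesia botrana, GM = Grapholita
#' molesta) and sex: ommatidia count, interommatidial angle, ommatidial
#' diameter, eye radius, CT-scan eye diameters (dorso-ventral and
#' antero-posterior, single individual), stereomicroscope eye diameters
#' (mean and SEM of 10 individuals), and clear-zone thickness. Used for the
#' stereo-vs-CT cross-check.
#'
#' @return A data.frame with one row per species x sex.
#' @export
#' @examples
#' head(morphometryTable())
morphometryTable <- function() {
  path <- system.file("extdata", "table1_morphometry.csv",
                      package = "PupilKinetics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cross-check stereomicroscope against CT eye widths
#'
#' Pairs every CT-scan eye diameter (dorso-ventral and antero-posterior,
#' all species x sex rows) with the corresponding stereomicroscope mean and
#' tests their Pearson correlation.
#'
#' @param table a morphometry table (default the packaged one).
#' @return As [pearsonCorrelation()].
#' @export
crossCheckEyeWidths <- function(table = morphometryTable()) {
  ct <- c(table$ct_dv_diameter_um, table$ct_ap_diameter_um)
  st <- c(table$stereo_dv_diameter_um, table$stereo_ap_diameter_um)
  pearsonCorrelation(ct, st)
}
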