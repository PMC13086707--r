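## Hierarchical Gaussian GLM selection over (sex + species + temperature)^n
## and Tukey-adjusted marginal-mean contrasts on the kinetic parameters.

.PREDICTORS <- c("sex", "species", "temperature_C")

# Coerce the design columns to factors (temperature was a two-level regime
# in the study; treatment coding throughout).
.prepRecords <- function(records, response) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(c(.PREDICTORS, response), names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  records <- records[stats::complete.cases(
    records[, c(.PREDICTORS, response)]), , drop = FALSE]
  if (!is.finite(sum(records[[response]])))
    stop("response contains non-finite values")
  for (p in .PREDICTORS) records[[p]] <- factor(records[[p]])
  records
}

# Highest interaction order supported by the cell occupancy: order k needs
# every cell of every k-way margin filled.
.maxSupportedOrder <- function(records) {
  combos <- list(1L, 2L, 3L)
  ok <- 1L
  if (all(table(records$sex, records$species) > 0) &&
      all(table(records$sex, records$temperature_C) > 0) &&
      all(table(records$species, records$temperature_C) > 0))
    ok <- 2L
  if (ok == 2L &&
      all(table(records$sex, records$species, records$temperature_C) > 0))
    ok <- 3L
  ok
}

#' Fit the hierarchical Gaussian GLM family
#'
#' Fits Gaussian-family models of the response on
#' \code{~ (sex + species + temperature_C)^n} for n = 0 (intercept only)
#' through \code{maxOrder} (default 3, three-way interactions), computes
#' AIC per model and the sequential F-test p-value between consecutive
#' orders. A Gaussian-family GLM with identity link is an ordinary
#' least-squares fit; F tests are the standard sequential-ANOVA comparison
#' for nested Gaussian models. When the design has empty cells the maximum
#' order is downgraded with a warning.
#'
#' @param records data.frame of specimen rows with columns \code{sex},
#'   \code{species}, \code{temperature_C} and the response; see
#'   [simulateSpecimenTable()] for the row type. Incomplete cases are
#'   dropped.
#' @param response response column, \code{"b"} or \code{"t50_s"} (any
#'   numeric column is accepted).
#' @param maxOrder highest interaction order requested (0-3).
#' @return A \linkS4class{ModelHierarchy}.
#' @export
#' @examples
#' rec <- simulateSpecimenTable(nPerCell = 5, seed = 2)
#' fitGlmHierarchy(rec, "b")
fitGlmHierarchy <- function(records, response = c("b", "t50_s"),
                            maxOrder = 3L) {
  response <- if (length(response) > 1) response[1] else response
  records <- .prepRecords(records, response)
  maxOrder <- as.integer(maxOrder)
  stopifnot(maxOrder >= 0L, maxOrder <= 3L)
  if (maxOrder > 0L) {
    supported <- .maxSupportedOrder(records)
    if (supported < maxOrder) {
      warning("empty design cells: downgrading maximum order from ",
              maxOrder, " to ", supported)
      maxOrder <- supported
    }
  }
  forms <- vapply(0:maxOrder, function(n) {
    if (n == 0L) paste(response, "~ 1")
    else if (n == 1L) paste(response, "~ sex + species + temperature_C")
    else sprintf("%s ~ (sex + species + temperature_C)^%d", response, n)
  }, character(1))
  models <- lapply(forms, function(f)
    stats::glm(stats::as.formula(f), family = stats::gaussian(),
               data = records))
  aic <- vapply(models, stats::AIC, numeric(1))
  ll <- vapply(models, function(m) as.numeric(stats::logLik(m)), numeric(1))
  dfr <- vapply(models, stats::df.residual, numeric(1))
  pSeq <- rep(NA_real_, length(models))
  for (i in seq_along(models)[-1]) {
    tab <- stats::anova(models[[i - 1]], models[[i]], test = "F")
    # identical designs (no new estimable terms) yield NA; keep NA
    pSeq[i] <- tab[["Pr(>F)"]][2]
  }
  new("ModelHierarchy", response = response, models = models,
      formulas = forms, aic = aic, logLik = ll, dfResidual = dfr,
      pSequential = pSeq, maxOrder = maxOrder)
}

#' Select the model order by sequential ANOVA + AIC
#'
#' Walks the hierarchy from n = 0 upward and accepts order n only when its
#' sequential p-value is below \code{alpha} AND its AIC is below the AIC of
#' the last accepted model; the last accepted order is returned (n = 0 is
#' always a valid fallback).
#'
#' @param hierarchy a \linkS4class{ModelHierarchy}.
#' @param alpha significance level (default 0.05).
#' @return The chosen order as an integer with attribute \code{"model"}
#'   holding the fitted \code{glm}.
#' @export
selectModel <- function(hierarchy, alpha = 0.05) {
  stopifnot(is(hierarchy, "ModelHierarchy"))
  chosen <- 0L
  for (n in seq_len(hierarchy@maxOrder)) {
    p <- hierarchy@pSequential[n + 1L]
    if (!is.na(p) && p < alpha &&
        hierarchy@aic[n + 1L] < hierarchy@aic[chosen + 1L])
      chosen <- n
  }
  structure(chosen, model = hierarchy@models[[chosen + 1L]])
}

# Greedy compact letter display on levels ordered by mean: each maximal run
# of consecutive levels that are pairwise non-significant gets one letter;
# runs contained in an earlier run are skipped.
.compactLetters <- function(levels, means, pmat, alpha) {
  ord <- order(means)
  k <- length(levels)
  nonsig <- function(i, j) {
    a <- levels[ord[i]]; b <- levels[ord[j]]
    p <- pmat[a, b]
    !is.finite(p) || p >= alpha
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(vapply((i:j), function(m) nonsig(m, j + 1L),
                               logical(1))))
      j <- j + 1L
    contained <- any(vapply(runs, function(r)
      i >= r[1] && j <= r[2], logical(1)))
    if (!contained) runs[[length(runs) + 1L]] <- c(i, j)
  }
  lab <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    lab[idx] <- paste0(lab[idx], letters[r])
  }
  out <- character(k)
  out[ord] <- lab
  stats::setNames(out, levels)
}

#' Tukey-adjusted pairwise marginal-mean contrasts
#'
#' Estimated marginal means of a factor (averaged over the other factors'
#' level grid), all pairwise differences with studentized-range (Tukey)
#' adjustment, and a compact letter display at \code{alpha}: levels sharing
#' no letter differ significantly. The letters are assigned greedily on the
#' mean-ordered levels, merging maximal runs of mutually non-significant
#' levels.
#'
#' @param model a fitted model (e.g. from [selectModel()]'s
#'   \code{"model"} attribute or \code{hierarchy@models}).
#' @param factor name of a factor appearing in the model.
#' @param alpha significance level for the letters (default 0.05, the
#'   level used for the Tukey comparisons).
#' @return A \linkS4class{ContrastTable}.
#' @export
#' @examples
#' rec <- simulateSpecimenTable(nPerCell = 5,
#'          speciesEffect = list(b = c(GM = 2)), seed = 3)
#' h <- fitGlmHierarchy(rec, "b", maxOrder = 1)
#' emmPairwise(h@models[[2]], "species")
emmPairwise <- function(model, factor, alpha = 0.05) {
  termLabels <- attr(stats::terms(model), "term.labels")
  if (!factor %in% unlist(strsplit(termLabels, ":")))
    stop("factor '", factor, "' is not a term of the model")
  emm <- emmeans::emmeans(model, specs = factor)
  emmDf <- as.data.frame(emm)
  class(emmDf) <- "data.frame"
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  prsDf <- as.data.frame(prs)
  class(prsDf) <- "data.frame"
  lvls <- as.character(emmDf[[factor]])
  pmat <- matrix(NA_real_, length(lvls), length(lvls),
                 dimnames = list(lvls, lvls))
  for (i in seq_len(nrow(prsDf))) {
    ab <- strsplit(as.character(prsDf$contrast[i]), " - ", fixed = TRUE)[[1]]
    ab <- gsub("^\\(|\\)$", "", ab)
    pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- prsDf$p.value[i]
  }
  letterVec <- .compactLetters(lvls, emmDf$emmean, pmat, alpha)
  emmDf$.group <- letterVec[lvls]
  new("ContrastTable", factor = factor, emmeans = emmDf,
      contrasts = prsDf, alpha = alpha)
}

#' Pearson correlation with t-based test
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return A list with \code{r}, \code{p} (two-sided), \code{df} and
#'   \code{n}.
#' @export
#' @examples
#' pearsonCorrelation(1:10, (1:10) * 2 + rnorm(10, 0, 0.1))
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}
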