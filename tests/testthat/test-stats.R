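# Hierarchical GLM selection, marginal-mean contrasts, Pearson correlation.

nullTable <- function(seed, nPerCell = 10) {
  simulateSpecimenTable(nPerCell = nPerCell, seed = seed)
}

test_that("the hierarchy is nested: logLik rises, residual SS falls", {
  rec <- nullTable(101)
  h <- fitGlmHierarchy(rec, "b")
  expect_equal(h@maxOrder, 3L)
  expect_true(all(diff(h@logLik) >= -1e-8))
  rss <- vapply(h@models, function(m) sum(stats::residuals(m)^2),
                numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
  # intercept-only AIC follows the mean + dispersion parameter convention
  expect_equal(h@aic[1], 2 * 2 - 2 * h@logLik[1])
})

test_that("empty design cells downgrade the requested order", {
  rec <- nullTable(102)
  rec <- rec[!(rec$species == "GM" & rec$sex == "male" &
                 rec$temperature_C == 15), ]
  expect_warning(h <- fitGlmHierarchy(rec, "b"), "downgrading")
  expect_lt(h@maxOrder, 3L)
})

test_that("model selection requires both significance and lower AIC", {
  mk <- function(p, aic) {
    new("ModelHierarchy", response = "b",
        models = rep(list(list()), length(p)),
        formulas = rep("", length(p)), aic = aic,
        logLik = rep(0, length(p)), dfResidual = rep(1, length(p)),
        pSequential = p, maxOrder = length(p) - 1L)
  }
  # no step significant: stay at the intercept model
  expect_equal(selectModel(mk(c(NA, 0.4, 0.6), c(10, 11, 12)))[1], 0L)
  # first step significant with lower AIC, second not
  expect_equal(selectModel(mk(c(NA, 0.01, 0.6), c(10, 8, 9)))[1], 1L)
  # significant but AIC worse: rejected
  expect_equal(selectModel(mk(c(NA, 0.01, 0.6), c(10, 12, 13)))[1], 0L)
})

test_that("a strong species effect is detected and the level separated", {
  rec <- simulateSpecimenTable(nPerCell = 20,
                               speciesEffect = list(b = c(GM = 0.8)),
                               seed = 103)
  h <- fitGlmHierarchy(rec, "b")
  n <- selectModel(h)
  expect_gte(n[1], 1L)
  ct <- emmPairwise(attr(n, "model"), "species")
  em <- ct@emmeans
  gmLetters <- strsplit(em$.group[em$species == "GM"], "")[[1]]
  otherLetters <- unlist(strsplit(em$.group[em$species != "GM"], ""))
  expect_false(any(gmLetters %in% otherLetters))
})

test_that("EMMs equal raw group means in a balanced design", {
  rec <- nullTable(104)
  h <- fitGlmHierarchy(rec, "b", maxOrder = 1)
  ct <- emmPairwise(h@models[[2]], "species")
  raw <- tapply(rec$b, rec$species, mean)
  em <- setNames(ct@emmeans$emmean, as.character(ct@emmeans$species))
  expect_equal(unname(em[names(raw)]), as.numeric(raw), tolerance = 1e-10)
})

test_that("a two-level factor reduces Tukey to the plain t-test", {
  rec <- nullTable(105)
  m <- stats::glm(b ~ sex, family = stats::gaussian(),
                  data = transform(rec, sex = factor(sex)))
  ct <- emmPairwise(m, "sex")
  pCoef <- summary(m)$coefficients[2, 4]
  expect_equal(ct@contrasts$p.value, pCoef, tolerance = 1e-10)
})

test_that("identical simulated means share one letter", {
  rec <- nullTable(106, nPerCell = 15)
  h <- fitGlmHierarchy(rec, "b", maxOrder = 1)
  ct <- emmPairwise(h@models[[2]], "species")
  expect_length(unique(ct@emmeans$.group), 1L)
})

test_that("contrast results do not depend on factor-level ordering", {
  rec <- nullTable(107)
  recFlip <- rec
  recFlip$species <- factor(recFlip$species, levels = c("LB", "GM", "CP"))
  h1 <- fitGlmHierarchy(rec, "b", maxOrder = 1)
  h2 <- fitGlmHierarchy(recFlip, "b", maxOrder = 1)
  ct1 <- emmPairwise(h1@models[[2]], "species")
  ct2 <- emmPairwise(h2@models[[2]], "species")
  em1 <- ct1@emmeans[order(as.character(ct1@emmeans$species)), ]
  em2 <- ct2@emmeans[order(as.character(ct2@emmeans$species)), ]
  expect_equal(em1$emmean, em2$emmean, tolerance = 1e-10)
  expect_equal(sort(ct1@contrasts$p.value), sort(ct2@contrasts$p.value),
               tolerance = 1e-10)
  expect_error(emmPairwise(h1@models[[2]], "phase"), "not a term")
})

test_that("Pearson correlation handles the standard and degenerate cases", {
  expect_equal(pearsonCorrelation(1:10, 2 * (1:10) + 3)$r, 1)
  set.seed(108)
  x <- rnorm(30)
  perm <- sample(x)
  res <- pearsonCorrelation(x, perm)
  expect_lt(abs(res$r), 0.4)
  expect_gt(res$p, 0.05)
  expect_error(pearsonCorrelation(1:5, 1:4), "equal length")
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "zero variance")
})
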