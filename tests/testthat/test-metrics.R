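test_that("GLM maps are smoothed per-voxel correlations", {
  design <- miniDesign(nTime = 80)
  X <- buildDesignMatrix(design)
  xEff <- as.numeric(effectiveDesign(X, c(1, -1, 0)))
  ## every voxel equal to the design signal: correlations are all 1
  Y <- matrix(rep(xEff, 20), 80, 20)
  ds <- FmriDataset(Y, dims = c(4, 5), standardize = FALSE)
  expect_equal(alphaValues(glmMap(ds, xEff)), rep(1, 20), tolerance = 1e-12)
  ## voxels orthogonal to the design stay at zero after smoothing
  y0 <- stats::residuals(lm(rnorm(80) ~ xEff))
  dsO <- FmriDataset(matrix(rep(y0, 20), 80, 20), dims = c(4, 5),
                     standardize = FALSE)
  expect_lt(max(abs(alphaValues(glmMap(dsO, xEff)))), 1e-10)
  ## independent oracle: naive smoothing pass + cor() per voxel
  set.seed(71)
  dsR <- randomDataset(80, c(5, 6), seed = 71)
  g <- unclass(gaussianFilter(2, 2))[, ]
  sm <- t(apply(fmriData(dsR), 1, function(fr)
    as.numeric(naiveConv2(matrix(fr, 5, 6), g))))
  oracle <- abs(sapply(seq_len(30), function(q) cor(sm[, q], xEff)))
  expect_lt(max(abs(alphaValues(glmMap(dsR, xEff)) - oracle)), 1e-10)
})

test_that("ROC curves group ties and match the pairwise oracle", {
  truth <- c(rep(TRUE, 5), rep(FALSE, 15))
  curve <- rocCurve(as.numeric(truth), truth)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))     # passes (0, 1)
  flat <- rocCurve(rep(1, 20), truth)
  expect_equal(flat$fpr, c(0, 1)); expect_equal(flat$tpr, c(0, 1))
  expect_error(rocCurve(rnorm(5), rep(TRUE, 5)), "both classes")
  set.seed(72)
  scores <- sample(rep(rnorm(30), 2))                    # with ties
  truthR <- runif(60) < 0.3
  expect_equal(partialAUC(rocCurve(scores, truthR), 1),
               pairwiseAUC(scores, truthR), tolerance = 1e-12)
  ## and against an established implementation
  skip_if_not_installed("pROC")
  expect_equal(partialAUC(rocCurve(scores, truthR), 1),
               as.numeric(pROC::auc(pROC::roc(truthR, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("partial AUC integrates the restricted ROC", {
  truth <- c(rep(TRUE, 50), rep(FALSE, 950))
  perfect <- rocCurve(c(rep(1, 50), rep(0, 950)), truth)
  expect_equal(partialAUC(perfect, 0.1), 0.1)
  anti <- rocCurve(c(rep(0, 50), rep(1, 950)), truth)
  expect_equal(partialAUC(anti, 0.1), 0, tolerance = 1e-9)
  ## chance level is fprMax^2 / 2
  set.seed(73)
  ch <- replicate(10, {
    truthL <- runif(1e5) < 0.1
    partialAUC(rocCurve(rnorm(1e5), truthL), 0.1)
  })
  expect_lt(abs(mean(ch) - 0.005), 0.001)
  ## partial AUC at fprMax = 1 is the full AUC; monotone in fprMax
  set.seed(74)
  sc <- rnorm(500); tr <- runif(500) < 0.2
  cv <- rocCurve(sc, tr)
  expect_equal(partialAUC(cv, 1), pairwiseAUC(sc, tr), tolerance = 1e-12)
  pa <- sapply(c(0.05, 0.1, 0.3, 0.6, 1), partialAUC, curve = cv)
  expect_true(all(diff(pa) >= 0))
  expect_error(partialAUC(cv, 0), "fprMax")
})

test_that("AUC ratios normalize kernel accuracy to the GLM baseline", {
  expect_equal(aucRatio(0.04, 0.04), 1)
  expect_equal(aucRatio(0.0573, 0.0470), 1.219, tolerance = 1e-3)
  expect_equal(aucRatio(2 * 0.03, 0.04), 2 * aucRatio(0.03, 0.04))
  expect_error(aucRatio(0.05, 0), "positive")
})

test_that("map evaluation composes ROC pieces and ignores monotone rescaling", {
  set.seed(75)
  truth <- runif(400) < 0.1
  geom <- c(20, 20)
  mk <- function(a) new("ActivationMap", alpha = a, sign = 1L,
                        absolute = TRUE, spec = kernelSpec("linear"),
                        gamma = 0, geometry = gridGeometry(geom))
  a <- runif(400)
  ev <- evaluateMap(mk(a), truth, mk(a))
  expect_equal(ev$ratioVsGlm, 1)
  expect_lte(ev$partialAuc, ev$fullAuc)
  ## perfect kernel map vs chance GLM
  ev2 <- evaluateMap(mk(as.numeric(truth)), truth, mk(a))
  expect_equal(ev2$partialAuc, 0.1)
  expect_equal(ev2$ratioVsGlm, 0.1 / ev2$glmPartialAuc)
  ## strictly monotone transforms leave the evaluation unchanged
  ev3 <- evaluateMap(mk(exp(3 * a)), truth, mk(a))
  expect_equal(ev3$partialAuc, ev$partialAuc)
})
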