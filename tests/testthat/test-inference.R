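mapFromAlpha <- function(a, dims) {
  new("ActivationMap", alpha = a, sign = 1L, absolute = TRUE,
      spec = kernelSpec("linear"), gamma = 0, geometry = gridGeometry(dims))
}

test_that("voxel shuffling reverses boundary voxels by rank", {
  ## 10 voxels with alpha ranks 9..0; top-10% = 1 activated voxel; full
  ## setting reverses the 9 non-activated: 2<->10, 3<->9, ..., 6 fixed
  a <- 9:0
  map <- mapFromAlpha(a, c(2, 5))
  ds <- FmriDataset(matrix(rep(1:10, each = 3) + 0, 3, 10), dims = c(2, 5),
                    standardize = FALSE)
  plan <- shufflePlan(map, "full")
  expect_equal(plan$qPlus, 1); expect_equal(plan$q1, 9); expect_equal(plan$q2, 1)
  shuf <- voxelShuffle(ds, plan)
  expect_equal(fmriData(shuf)[1, ], c(1, 10, 9, 8, 7, 6, 5, 4, 3, 2))
  ## involution: shuffling twice restores the data
  expect_equal(fmriData(voxelShuffle(shuf, plan)), fmriData(ds))
  ## column multiset is preserved
  expect_equal(apply(fmriData(shuf), 2, sort)[, order(fmriData(shuf)[1, ])],
               apply(fmriData(ds), 2, sort)[, order(fmriData(ds)[1, ])])
})

test_that("degenerate shuffle plans return the data unchanged with a warning", {
  a <- c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4)
  map <- mapFromAlpha(abs(a), c(2, 5))
  ds <- FmriDataset(matrix(rnorm(30), 3, 10), dims = c(2, 5))
  plan <- shufflePlan(map, "half")     # qPlus = 1 -> q1 = q2 = 0
  expect_equal(plan$q1, 0)
  expect_warning(out <- voxelShuffle(ds, plan), "no swap")
  expect_equal(fmriData(out), fmriData(ds))
})

test_that("shuffle similarity is the apparent partial AUC", {
  set.seed(61)
  a <- runif(200)
  m1 <- mapFromAlpha(a, c(10, 20))
  expect_equal(shuffleSimilarity(m1, m1), 0.1)                  # identical
  expect_equal(shuffleSimilarity(m1, mapFromAlpha(-a + 1.0001 * max(a), c(10, 20))),
               0, tolerance = 1e-8)                             # anti-ranked
  ## iid random scores sit at chance level fprMax^2/2
  sims <- sapply(1:20, function(s) {
    set.seed(s)
    shuffleSimilarity(mapFromAlpha(runif(1e4), c(100, 100)),
                      mapFromAlpha(runif(1e4), c(100, 100)))
  })
  expect_lt(abs(mean(sims) - 0.005), 0.002)
  expect_warning(shuffleSimilarity(m1, mapFromAlpha(rep(1, 200), c(10, 20))),
                 "constant")
})

test_that("robustness scoring separates signal from noise and is deterministic", {
  design <- miniDesign(nTime = 90)
  bank <- steerableBank(2)
  dims <- c(12, 30)
  scoreFor <- function(rho, seed) {
    sim <- simulateToy2D(dims = dims, rho = rho, seed = seed, design = design)
    robustnessScore(sim@dataset, bank, kernelSpec("linear"), gamma = NULL,
                    xEff = sim@xEff)
  }
  diffs <- sapply(1:5, function(s)
    scoreFor(0.25, s)$score - scoreFor(0, s + 100)$score)
  expect_gt(mean(diffs), 0)
  expect_gt(sum(diffs > 0), 3)
  ## deterministic: identical inputs give identical reports
  r1 <- scoreFor(0.2, 7); r2 <- scoreFor(0.2, 7)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$similarities, r2$similarities)
  expect_true(all(r1$similarities >= 0 & r1$similarities <= 0.1))
  ## the two boundary settings are combined with equal weights
  expect_equal(r1$score, mean(r1$similarities))
})

test_that("hyperparameter optimization is exhaustive with stable ties", {
  design <- miniDesign(nTime = 90)
  sim <- simulateToy2D(dims = c(12, 30), rho = 0.25, seed = 3, design = design)
  bank <- steerableBank(2)
  single <- list(list(spec = kernelSpec("linear"), gamma = 0.5))
  opt1 <- optimizeHyperparams(sim@dataset, bank, single, sim@xEff)
  expect_equal(opt1$index, 1)
  expect_equal(opt1$gamma, 0.5)
  ## duplicated setting scores identically and the first wins
  dup <- c(single, single)
  opt2 <- optimizeHyperparams(sim@dataset, bank, dup, sim@xEff)
  expect_equal(opt2$report$score[1], opt2$report$score[2])
  expect_equal(opt2$index, 1)
  expect_error(optimizeHyperparams(sim@dataset, bank, list(), sim@xEff), "empty")
})

test_that("a near-linear tanh kernel wins on linear signal", {
  design <- miniDesign(nTime = 90)
  bank <- steerableBank(2)
  wins <- sapply(1:3, function(s) {
    sim <- simulateToy2D(dims = c(12, 30), rho = 0.3, seed = s, design = design)
    grid <- list(list(spec = kernelSpec("tanh", b = 0.1, c = 0), gamma = NULL),
                 list(spec = kernelSpec("tanh", b = 10, c = 0), gamma = NULL))
    optimizeHyperparams(sim@dataset, bank, grid, sim@xEff)$index
  })
  expect_gte(sum(wins == 1), 2)
})

test_that("null thresholds are quantiles of the permutation pool", {
  design <- miniDesign(nTime = 90)
  sim <- simulateToy2D(dims = c(10, 24), rho = 0.2, seed = 9, design = design)
  bank <- steerableBank(2)
  res <- kccaActivation(sim@dataset, bank, kernelSpec("linear"), sim@xEff,
                        absolute = FALSE)
  ## constant vY: alpha_null is permutation invariant, so the threshold is
  ## the (1-rate) quantile of |alpha| itself
  fitC <- res$fit; fitC@vY <- rep(1, 90)
  mapC <- activationMap(sim@dataset, bank, kernelSpec("linear"), fitC,
                        sim@xEff, absolute = FALSE)
  thr <- nullThreshold(sim@dataset, bank, kernelSpec("linear"), gamma = 1,
                       xEff = sim@xEff, vY = rep(1, 90), nShuffles = 3,
                       rate = 0.05, seed = 2)
  expect_equal(thr,
               as.numeric(quantile(rep(abs(alphaValues(mapC)), 3), 0.95)),
               tolerance = 1e-10)
  ## rate = 1 gives the pool minimum
  thrMin <- nullThreshold(sim@dataset, bank, kernelSpec("linear"), gamma = 1,
                          xEff = sim@xEff, vY = rep(1, 90), nShuffles = 2,
                          rate = 1, seed = 2)
  expect_equal(thrMin, min(abs(alphaValues(mapC))), tolerance = 1e-10)
  ## monotone non-increasing in rate
  v <- res$fit@vY
  t05 <- nullThreshold(sim@dataset, bank, kernelSpec("linear"), gamma = 1,
                       xEff = sim@xEff, vY = v, nShuffles = 5, rate = 0.05, seed = 3)
  t20 <- nullThreshold(sim@dataset, bank, kernelSpec("linear"), gamma = 1,
                       xEff = sim@xEff, vY = v, nShuffles = 5, rate = 0.2, seed = 3)
  expect_gte(t05, t20)
})

test_that("GLM null threshold is calibrated on pure noise", {
  design <- miniDesign(nTime = 100)
  X <- buildDesignMatrix(design)
  xEff <- as.numeric(effectiveDesign(X, c(1, -1, 0)))
  rates <- sapply(1:10, function(s) {
    set.seed(s)
    ds <- FmriDataset(matrix(rnorm(100 * 1500), 100), dims = c(30, 50))
    thr <- glmNullThreshold(ds, xEff, nShuffles = 10, rate = 0.05, seed = s)
    mean(abs(alphaValues(glmMap(ds, xEff))) > thr)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.01)
  ## doubling the number of shuffles barely moves the threshold
  set.seed(77)
  ds <- FmriDataset(matrix(rnorm(100 * 1500), 100), dims = c(30, 50))
  t1 <- glmNullThreshold(ds, xEff, nShuffles = 20, rate = 0.05, seed = 1)
  t2 <- glmNullThreshold(ds, xEff, nShuffles = 40, rate = 0.05, seed = 1)
  expect_lt(abs(t1 - t2) / t1, 0.01)
  ## rate -> 0 drives the threshold to the pool maximum
  t0 <- glmNullThreshold(ds, xEff, nShuffles = 5, rate = 1e-9, seed = 4)
  tsmall <- glmNullThreshold(ds, xEff, nShuffles = 5, rate = 0.2, seed = 4)
  expect_gt(t0, tsmall)
})
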