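test_that("word mask rasterization hits the active-fraction band deterministically", {
  for (dims in list(c(100, 400), c(50, 200))) {
    m <- makeWordMask(dims)
    expect_equal(dim(m), dims)
    expect_gte(mean(m), 0.08); expect_lte(mean(m), 0.12)
    expect_identical(m, makeWordMask(dims))          # pure function
  }
  expect_error(makeWordMask(c(100, 400), text = ""), "empty")
  expect_error(makeWordMask(c(100, 400), text = "kern3l"), "glyph")
  expect_error(makeWordMask(c(2, 2)), "band")        # grid too small
})

test_that("noise generator produces the requested temporal correlation", {
  n1 <- genNoise(500, 40, phi = 0, seed = 81)
  ac1 <- sapply(seq_len(40), function(q) cor(n1[-1, q], n1[-500, q]))
  expect_lt(abs(mean(ac1)), 3 / sqrt(500))
  n2 <- genNoise(1e4, 8, phi = 0.4, seed = 82)
  ac2 <- sapply(seq_len(8), function(q) cor(n2[-1, q], n2[-1e4, q]))
  expect_lt(abs(mean(ac2) - 0.4), 0.03)
  ## stationary variance before standardization is 1 / (1 - phi^2)
  n3 <- genNoise(5e4, 4, phi = 0.4, seed = 83, standardize = FALSE)
  expect_lt(abs(mean(apply(n3, 2, var)) - 1 / (1 - 0.16)), 0.1)
  ## standardized output has unit columns
  expect_lt(max(abs(colMeans(n2))), 1e-12)
  expect_equal(as.numeric(apply(n2, 2, sd)), rep(1, 8), tolerance = 1e-12)
  expect_error(genNoise(10, 2, phi = 1), "phi")
})

test_that("added signal follows the perturbed contrast", {
  design <- miniDesign(nTime = 120)
  X <- buildDesignMatrix(design)
  x0 <- genAddedSignal(X, c(1, -1, 0), delta = 0, seed = 1)
  ref <- as.numeric(X %*% c(1, -1, 0))
  expect_equal(as.numeric(x0), as.numeric((ref - mean(ref)) / sd(ref)),
               tolerance = 1e-12)
  expect_lt(abs(mean(x0)), 1e-10)
  expect_equal(sd(x0), 1, tolerance = 1e-10)
  xEff <- as.numeric(effectiveDesign(X, c(1, -1, 0)))
  corAt <- function(delta) mean(sapply(1:20, function(s)
    cor(genAddedSignal(X, c(1, -1, 0), delta = delta, seed = s), xEff)))
  expect_gt(corAt(0.1), corAt(0.4))      # larger deviation decorrelates
  expect_error(genAddedSignal(X, c(1, -1, 0), delta = -1), "nonnegative")
})

test_that("assembly follows the generative model", {
  design <- miniDesign(nTime = 100)
  X <- buildDesignMatrix(design)
  xAdd <- genAddedSignal(X, c(1, -1, 0), 0, seed = 2)
  mask <- matrix(FALSE, 5, 8); mask[2:3, 2:4] <- TRUE
  noise <- genNoise(100, 40, seed = 3)
  ## rho = 0: the data are just the standardized noise
  s0 <- assembleSimulation(noise, 0, xAdd, mask)
  expect_equal(fmriData(s0), nlkcca:::colStandardize(noise), tolerance = 1e-12)
  ## pure signal in a masked voxel: the column is the added time course
  z <- matrix(0, 100, 40)
  sPure <- suppressWarnings(assembleSimulation(z + 1e-12 * noise, 1, xAdd, mask))
  expect_equal(fmriData(sPure)[, which(as.logical(mask))[1]],
               as.numeric(xAdd), tolerance = 1e-6)
  ## SNR grows with rho
  cors <- sapply(c(0.01, 0.03, 0.1), function(r) {
    s <- assembleSimulation(noise, r, xAdd, mask)
    mean(cor(fmriData(s)[, s@truthMask], as.numeric(xAdd)))
  })
  expect_true(all(diff(cors) > 0))
  expect_error(assembleSimulation(noise, 1, xAdd[-1], mask), "length")
})

test_that("2D toy simulations are reproducible and carry provenance", {
  design <- miniDesign(nTime = 90)
  s1 <- simulateToy2D(dims = c(12, 30), rho = 0.05, delta = 0.2, seed = 4,
                      design = design)
  s2 <- simulateToy2D(dims = c(12, 30), rho = 0.05, delta = 0.2, seed = 4,
                      design = design)
  expect_identical(fmriData(s1), fmriData(s2))
  expect_identical(s1@xAdd, s2@xAdd)
  s3 <- simulateToy2D(dims = c(12, 30), rho = 0.05, delta = 0.2, seed = 5,
                      design = design)
  expect_false(identical(fmriData(s1), fmriData(s3)))
  expect_equal(s1@params$rho, 0.05)
  expect_error(simulateToy2D(dims = c(12, 30), phi = 0.3, seed = 1,
                             design = design), "ar1")
  ## AR(1) noise path
  s4 <- simulateToy2D(dims = c(12, 30), rho = 0.05, phi = 0.3,
                      noiseKind = "ar1", seed = 6, design = design)
  expect_equal(nVoxels(s4), 360)
})

test_that("the emulated task design is balanced and HRF-representable", {
  td <- makeWmTaskDesign()
  expect_equal(td@nTime, 390L)
  expect_equal(sort(names(td@conditions)), c("lure", "nontarget", "target"))
  X <- buildDesignMatrix(td)
  sds <- apply(X, 2, sd)
  expect_lt(max(sds) / min(sds), 1.2)                 # balanced regressors
  xEff <- as.numeric(effectiveDesign(X, c(1, -1, 0)))
  expect_gt(cor(as.numeric(X %*% c(1, -1, 0)), xEff), 0.99)
  expect_identical(X, buildDesignMatrix(makeWmTaskDesign()))  # shared design
})

test_that("signal-strength calibration walks into the GLM band", {
  ## stubbed detectors force the documented trajectories
  gen <- function(rho, seed) rho     # generator output is ignored by stubs
  expect_equal(as.numeric(tuneRho(gen, detector = function(sim) 0.04)), 0.1)
  seq2 <- local({ i <- 0; function(sim) { i <<- i + 1; c(0.06, 0.04)[i] } })
  r <- tuneRho(gen, detector = seq2)
  expect_equal(as.numeric(r), 0.095)
  expect_equal(nrow(attr(r, "trajectory")), 2)
  up <- local({ i <- 0; function(sim) { i <<- i + 1; 0.01 } })
  expect_error(tuneRho(gen, detector = up, maxIter = 5), "did not converge")
})

test_that("3D phantom has gray-matter-contained regions at ~10% of brain", {
  sim <- makePhantom3D(rho = 0.2, seed = 91, designSeed = 1)
  tis <- sim@params$tissues
  frac <- sum(sim@truthMask) / nVoxels(sim)
  expect_gte(frac, 0.08); expect_lte(frac, 0.12)
  expect_true(all(grayMask(sim)[sim@truthMask]))       # GM containment
  ## tissue construction is sane: gray is a brain shell disjoint from white
  expect_false(any(tis$gray & tis$white))
  expect_true(all(which(tis$gray) %in% which(tis$brain)))
  expect_equal(length(geometry(sim)$maskIdx), sum(tis$brain))
})
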