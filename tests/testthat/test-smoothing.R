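test_that("Gaussian filter discretization is correct", {
  f <- gaussianFilter(2, 2)
  expect_equal(sum(f), 1)
  expect_equal(which.max(f), (49 + 1) / 2)           # center cell
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  ## center over edge-midpoint (offset 3 on one axis) ratio, closed form
  expect_equal(f[4, 4] / f[4, 7], exp(9 / (2 * sigma^2)), tolerance = 1e-12)
  expect_error(gaussianFilter(2, 2, support = 6), "odd")
  expect_error(gaussianFilter(-1, 2), "positive")
  f3 <- gaussianFilter(4, 3)
  expect_equal(sum(f3), 1)
  expect_equal(dim(f3), c(7, 7, 7))
})

test_that("steerable banks sum to the single Gaussian and are oriented", {
  b2 <- steerableBank(2)
  expect_length(filters(b2), 4)
  expect_lt(max(abs(Reduce(`+`, filters(b2)) - gaussianFilter(2, 2))), 1e-10)
  b3 <- steerableBank(3)
  expect_length(filters(b3), 7)
  expect_lt(max(abs(Reduce(`+`, filters(b3)) - gaussianFilter(4, 3))), 1e-10)
  ## rotating a 2D filter by 90 degrees gives the filter two steps away
  rot90 <- function(m) t(m)[nrow(m):1, ]
  f <- filters(b2)
  for (k in 1:4) {
    kk <- (k + 1) %% 4 + 1
    expect_equal(rot90(unclass(f[[k]])[, ]), unclass(f[[kk]])[, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(steerableBank(4), "dim")
})

test_that("apply/adjoint transform match direct convolution and each other", {
  set.seed(21)
  geom <- gridGeometry(c(5, 5))
  Y <- matrix(rnorm(3 * 25), 3, 25)
  bank <- steerableBank(2)
  ft <- applyTransform(Y, bank, geom)
  for (b in 1:4) {
    for (t in 1:3) {
      img <- matrix(Y[t, ], 5, 5)
      expect_equal(matrix(ft@blocks[[b]][t, ], 5, 5),
                   naiveConv2(img, unclass(filters(bank)[[b]])[, ]),
                   tolerance = 1e-12)
    }
  }
  ## delta bank is the identity
  ftd <- applyTransform(Y, deltaBank(2), geom)
  expect_equal(ftd@blocks[[1]], Y)
  ## single-voxel impulse response reproduces the filter
  imp <- matrix(0, 1, 25); imp[1, 13] <- 1   # center voxel of the 5x5 grid
  g <- gaussianFilter(2, 2, support = 3)
  fg <- applyTransform(imp, new("FilterBank", filters = list(g),
                                labels = "g", fwhm = 2, dim = 2L,
                                kind = "gaussian"), geom)
  expect_equal(matrix(fg@blocks[[1]], 5, 5)[2:4, 2:4], unclass(g)[, ],
               tolerance = 1e-14, ignore_attr = TRUE)
  ## adjoint identity <A(Y), V> = <Y, A'(V)>
  V <- matrix(rnorm(3 * 100), 3, 100)
  expect_lt(abs(sum(featureValues(ft) * V) -
                sum(Y * adjointTransform(V, bank, geom))), 1e-10)
  ## 3D adjoint identity on a masked grid
  set.seed(22)
  mask <- array(runif(4 * 4 * 4) > 0.3, c(4, 4, 4))
  geom3 <- gridGeometry(c(4, 4, 4), mask)
  Q3 <- length(geom3$maskIdx)
  Y3 <- matrix(rnorm(3 * Q3), 3, Q3)
  b3 <- steerableBank(3)
  ft3 <- applyTransform(Y3, b3, geom3)
  V3 <- matrix(rnorm(3 * 7 * Q3), 3)
  expect_lt(abs(sum(featureValues(ft3) * V3) -
                sum(Y3 * adjointTransform(V3, b3, geom3))), 1e-10)
  ## even (symmetric) filter: adjoint convolution equals forward convolution
  gb <- gaussianBank(2, 2)
  fwd <- applyTransform(Y, gb, geom)@blocks[[1]]
  adj <- adjointTransform(Y, gb, geom)
  expect_equal(fwd, adj, tolerance = 1e-12)
})

test_that("block-averaged steerable transform equals single-Gaussian smoothing", {
  set.seed(23)
  geom <- gridGeometry(c(6, 9))
  Y <- matrix(rnorm(4 * 54), 4, 54)
  for (d in 2:3) {
    if (d == 2) {
      bank <- steerableBank(2); gb <- gaussianBank(2, 2); g3 <- geom; Yd <- Y
    } else {
      g3 <- gridGeometry(c(4, 5, 4)); Yd <- matrix(rnorm(4 * 80), 4, 80)
      bank <- steerableBank(3); gb <- gaussianBank(4, 3)
    }
    ft <- applyTransform(Yd, bank, g3)
    avg <- Reduce(`+`, ft@blocks)   # equal-weight sum of blocks
    ref <- applyTransform(Yd, gb, g3)@blocks[[1]]
    expect_lt(max(abs(avg - ref)), 1e-10)
  }
})

test_that("masked voxels contribute zero to the transform", {
  set.seed(24)
  mask <- matrix(TRUE, 5, 5); mask[1:2, 1:2] <- FALSE
  geomM <- gridGeometry(c(5, 5), mask)
  geomF <- gridGeometry(c(5, 5))
  Yfull <- matrix(rnorm(2 * 25), 2, 25)
  Yzero <- Yfull; Yzero[, !as.logical(mask)] <- 0
  bank <- steerableBank(2)
  ftM <- applyTransform(Yfull[, geomM$maskIdx, drop = FALSE], bank, geomM)
  ftZ <- applyTransform(Yzero, bank, geomF)
  for (b in 1:4)
    expect_equal(ftM@blocks[[b]], ftZ@blocks[[b]][, geomM$maskIdx],
                 tolerance = 1e-12)
})
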