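test_that("Gram components match the forced arithmetic and the quadratic identity", {
  cc <- gramComponents(diag(2))
  expect_equal(cc@gScale, 0.5)
  expect_equal(cc@G, 2 * diag(2))
  expect_equal(cc@dScale, 2)
  expect_equal(cc@D, matrix(c(0, 1, 1, 0), 2))

  expect_warning(gramComponents(matrix(1, 3, 4)), "zero distance scale")

  set.seed(31)
  Yt <- matrix(rnorm(60), 6, 10)
  cc2 <- gramComponents(Yt)
  G0 <- tcrossprod(Yt)
  D0 <- cc2@D * cc2@dScale
  for (i in 1:6) for (j in 1:6)
    expect_equal(D0[i, j], G0[i, i] + G0[j, j] - 2 * G0[i, j],
                 tolerance = 1e-10)
})

test_that("kernel matrices follow their elementwise forms and normalizations", {
  set.seed(32)
  cc <- gramComponents(matrix(rnorm(48), 6, 8))
  for (sp in allKernelSpecs()) {
    K <- kernelGram(sp, cc)
    v <- kernelValues(K)
    expect_lt(max(abs(v - t(v))), 1e-12)                 # symmetry
    expect_equal(mean(abs(v)), 1, tolerance = 1e-12)     # post-normalization
  }
  ## gaussian: pre-normalization diagonal is exactly 1
  Kg <- kernelGram(kernelSpec("gaussian"), cc)
  expect_equal(diag(kernelValues(Kg)) * Kg@postScale, rep(1, 6))
  ## PSD families stay PSD after normalization
  for (nm in c("linear", "parabolic", "gaussian", "inverse")) {
    ev <- eigen(kernelValues(kernelGram(kernelSpec(nm), cc)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  ## small-parameter limits collapse to the linear kernel
  Kl <- kernelValues(kernelGram(kernelSpec("linear"), cc))
  Kt <- kernelValues(kernelGram(kernelSpec("tanh", b = 1e-6, c = 0), cc))
  Km <- kernelValues(kernelGram(kernelSpec("mixed_tanh", b1 = 1e-6, b2 = 0, c = 0), cc))
  expect_lt(max(abs(Kt - Kl)), 1e-4)
  expect_lt(max(abs(Km - Kl)), 1e-4)
  ## inverse kernel with b = 0 and coincident rows is a domain error
  ccEq <- suppressWarnings(gramComponents(matrix(1, 3, 4) + 0))
  expect_error(kernelGram(kernelSpec("inverse", b = 0), ccEq), "inverse kernel")
})

test_that("kernels are invariant to positive rescaling of the data", {
  set.seed(33)
  Yt <- matrix(rnorm(40), 5, 8)
  c1 <- gramComponents(Yt)
  c2 <- gramComponents(3.7 * Yt)
  expect_equal(c1@G, c2@G, tolerance = 1e-12)
  expect_equal(c1@D, c2@D, tolerance = 1e-12)
  for (sp in allKernelSpecs())
    expect_equal(kernelValues(kernelGram(sp, c1)),
                 kernelValues(kernelGram(sp, c2)), tolerance = 1e-10)
})

test_that("analytic backmap gradients match finite differences for all kernels", {
  set.seed(34)
  geom <- gridGeometry(c(2, 3))
  Y <- matrix(rnorm(4 * 6), 4, 6)
  vY <- rnorm(4)
  for (bank in list(deltaBank(2), steerableBank(2))) {
    ds <- FmriDataset(Y, dims = c(2, 3), standardize = FALSE)
    for (sp in allKernelSpecs()) {
      g1 <- kernelBackmapGradient(sp, ds, bank, vY)
      g2 <- fdBackmapGradient(sp, Y, bank, geom, vY)
      expect_lt(max(abs(g1 - g2)) / max(abs(g2)), 1e-4)
    }
  }
})

test_that("backmap gradient special cases", {
  set.seed(35)
  ds <- randomDataset(5, c(3, 4), seed = 35)
  bank <- steerableBank(2)
  ## vY = 0 gives the zero vector
  expect_equal(kernelBackmapGradient(kernelSpec("linear"), ds, bank,
                                     vY = numeric(5)), numeric(12))
  ## linear kernel gradient is a positive multiple of A A' Y' vY
  vY <- rnorm(5)
  geom <- geometry(ds)
  xf <- spatialTransform(bank, geom)
  ref <- 0
  for (b in seq_along(xf))
    ref <- ref + as.matrix(xf[[b]] %*% t(as.matrix(fmriData(ds) %*% xf[[b]])))
  ref <- as.numeric(ref %*% vY)
  g <- kernelBackmapGradient(kernelSpec("linear"), ds, bank, vY)
  ratio <- g / ref
  expect_lt(max(abs(g / sqrt(sum(g^2)) - ref / sqrt(sum(ref^2)))), 1e-8)
  expect_gt(mean(ratio), 0)
})
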