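## Shared fixtures and independent oracles, built in code at test time.

## Naive zero-padded 2D convolution by explicit double loop (oracle for the
## sparse spatial transform).
naiveConv2 <- function(img, f) {
  s <- nrow(f); half <- (s - 1) / 2
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -half:half) for (b in -half:half) {
      ii <- i - a; jj <- j - b
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + f[a + half + 1, b + half + 1] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

## Pairwise-comparison (Mann-Whitney) full AUC oracle.
pairwiseAUC <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Finite-difference oracle for the back-reconstruction gradient: perturbs
## each entry of Y, rebuilds the kernel matrix with the normalizers frozen at
## the base point, and contracts row t1 of dK with vY (the literal
## sensitivity sum).
fdBackmapGradient <- function(spec, Y, bank, geom, vY, h = 1e-5) {
  base <- gramComponents(applyTransform(Y, bank, geom))
  gs <- base@gScale; dsc <- base@dScale
  kmat <- function(Ym) {
    ft <- applyTransform(Ym, bank, geom)
    G0 <- Reduce(`+`, lapply(ft@blocks, tcrossprod))
    d <- diag(G0); D0 <- outer(d, d, "+") - 2 * G0; diag(D0) <- 0
    nlkcca:::kernelElementwise(spec, G0 / gs, D0 / dsc)$K
  }
  ps <- mean(abs(kmat(Y)))
  out <- numeric(ncol(Y))
  for (t in seq_len(nrow(Y))) for (q in seq_len(ncol(Y))) {
    Yp <- Y; Yp[t, q] <- Y[t, q] + h
    Ym <- Y; Ym[t, q] <- Y[t, q] - h
    dK <- (kmat(Yp) - kmat(Ym)) / (2 * h * ps)
    out[q] <- out[q] + sum(dK[t, ] * vY)
  }
  out
}

## Compact task design for small-T tests (three conditions, one short block
## each).
miniDesign <- function(nTime = 80, tr = 1, seed = 5) {
  makeWmTaskDesign(nTime = nTime, tr = tr, seed = seed,
                   blockDur = max(6, floor(nTime * tr / 6)), perCond = 1)
}

## Small random standardized dataset on an H x W grid.
randomDataset <- function(Tn, dims, seed = 1) {
  withr::with_seed(seed,
    FmriDataset(matrix(rnorm(Tn * prod(dims)), Tn), dims = dims))
}

allKernelSpecs <- function() list(
  kernelSpec("linear"), kernelSpec("parabolic"), kernelSpec("gaussian"),
  kernelSpec("inverse"), kernelSpec("tanh"), kernelSpec("mixed_tanh"))
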