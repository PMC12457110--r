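## Smoothing module: Gaussian and steerable filter banks and the spatial
## transform Y-tilde = Y A (with its adjoint), realized as per-filter sparse
## voxel-to-voxel matrices with zero padding outside the grid/mask.

#' Discretized isotropic Gaussian filter
#'
#' @param fwhm full width at half maximum in grid units;
#'   sigma = fwhm / (2 sqrt(2 log 2)).
#' @param dim 2 or 3.
#' @param support odd filter extent per axis (default 7).
#' @return numeric array of dimension `rep(support, dim)` with coefficients
#'   normalized to sum 1 and attribute `label = "gaussian"`.
#' @export
gaussianFilter <- function(fwhm, dim = 2, support = 7) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (!(dim %in% c(2, 3))) stop("dim must be 2 or 3")
  if (support %% 2 == 0) stop("support must be odd")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  off <- seq_len(support) - (support + 1) / 2
  g1 <- exp(-off^2 / (2 * sigma^2))
  f <- if (dim == 2) outer(g1, g1) else outer(outer(g1, g1), g1)
  f <- array(f, rep(support, dim))
  f <- f / sum(f)
  attr(f, "label") <- "gaussian"
  f
}

## Offsets from the filter center for every cell, as a (cells x dim) matrix.
filterOffsets <- function(support, dim) {
  ctr <- (support + 1) / 2
  idx <- arrayInd(seq_len(support^dim), rep(support, dim))
  idx - ctr
}

## Full (zero-padded) n-D convolution of two small arrays; used only at bank
## construction time for the energy-matching calibration.
convFull <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, da + db - 1)
  idx <- which(b != 0)
  co <- arrayInd(idx, db)
  for (k in seq_along(idx)) {
    sl <- lapply(seq_along(da), function(ax) co[k, ax] + seq_len(da[ax]) - 1)
    ref <- do.call(`[`, c(list(out), sl))
    out <- do.call(`[<-`, c(list(out), sl, list(ref + a * b[idx[k]])))
  }
  out
}

flipArray <- function(a) {
  d <- dim(a)
  do.call(`[`, c(list(a), lapply(d, function(n) n:1)))
}

#' Steerable filter bank
#'
#' Builds oriented spatial filters satisfying two properties at once:
#' \enumerate{
#'   \item the equal-weight sum of the filters equals, exactly by
#'     construction, the single Gaussian filter of the stated FWHM;
#'   \item the bank's energy operator `A A'` (which sets the effective
#'     smoothing of back-reconstructed maps) matches the single Gaussian
#'     smoothing operator as closely as possible, so kernel methods and the
#'     Gaussian-smoothing GLM baseline operate at the same smoothing level.
#' }
#' Each filter is `1/n` of the Gaussian envelope plus an oriented zero-sum
#' derivative lobe: second directional derivatives of the Gaussian at
#' orientations 0/45/90/135 degrees in 2D (mean-removed across orientations),
#' and signed first directional derivatives along the six half-axes plus one
#' radially symmetric filter in 3D. The oriented lobes cancel in the sum
#' (property 1) and their common scale is solved at construction time by
#' minimizing the distance between `A A'` and the Gaussian smoothing operator
#' (property 2).
#'
#' @param dim 2 (four filters, default FWHM 2 pixels) or 3 (seven filters,
#'   default FWHM 4 in voxel-size units).
#' @param fwhm FWHM of the equivalent single Gaussian, in grid units.
#' @param support odd filter extent per axis (default 7).
#' @return a [FilterBank-class].
#' @export
steerableBank <- function(dim = 2, fwhm = if (dim == 2) 2 else 4, support = 7) {
  if (!(dim %in% c(2, 3))) stop("dim must be 2 or 3")
  g <- gaussianFilter(fwhm, dim, support)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  offs <- filterOffsets(support, dim)
  if (dim == 2) {
    xx <- array(offs[, 1], dim(g)); yy <- array(offs[, 2], dim(g))
    Gxx <- (xx^2 / sigma^4 - 1 / sigma^2) * g
    Gyy <- (yy^2 / sigma^4 - 1 / sigma^2) * g
    Gxy <- (xx * yy / sigma^4) * g
    lobes <- lapply(0:3, function(k) {
      ph <- k * pi / 4
      cos(ph)^2 * Gxx + 2 * cos(ph) * sin(ph) * Gxy + sin(ph)^2 * Gyy
    })
    lm <- Reduce(`+`, lobes) / 4
    lobes <- lapply(lobes, function(d) sigma^2 * (d - lm))
    labels <- sprintf("theta%d", (0:3) * 45)
  } else {
    ax <- lapply(1:3, function(a) array(offs[, a], dim(g)))
    firsts <- lapply(ax, function(x) -x / sigma^2 * g)   # d g / d axis
    lobes <- c(list(array(0, dim(g))),
               lapply(1:3, function(a) sigma * firsts[[a]]),
               lapply(1:3, function(a) -sigma * firsts[[a]]))
    labels <- c("radial", "dir+x", "dir+y", "dir+z", "dir-x", "dir-y", "dir-z")
  }
  n <- length(lobes)
  ## energy calibration: A A' kernel is (g*g~)/n + c^2/n^2 sum_b d_b * d_b~;
  ## pick c so it best matches the single Gaussian smoothing kernel
  gg <- convFull(g, flipArray(g)) / n
  dd <- Reduce(`+`, lapply(lobes, function(d) convFull(d, flipArray(d)))) / n^2
  gtarget <- array(0, dim(gg))
  ctrIdx <- lapply(dim(g), function(s) (s - 1) / 2 + seq_len(s))
  gtarget <- do.call(`[<-`, c(list(gtarget), ctrIdx, list(g)))
  obj <- function(c2) {
    E <- gg + c2 * dd
    E <- E / sum(E)
    sqrt(sum((E - gtarget)^2))
  }
  c2 <- stats::optimize(obj, c(0, 100))$minimum
  fl <- lapply(seq_len(n), function(b) {
    f <- (g + sqrt(c2) * lobes[[b]]) / n
    attr(f, "label") <- labels[b]
    f
  })
  new("FilterBank", filters = fl, labels = labels, fwhm = fwhm,
      dim = as.integer(dim), kind = "steerable")
}

#' Single-filter banks
#'
#' `gaussianBank` wraps the single Gaussian filter (the GLM smoothing filter)
#' as a one-filter bank; `deltaBank` is the identity transform, useful for
#' testing and for running KCCA without spatial smoothing.
#'
#' @param fwhm Gaussian FWHM in grid units.
#' @param dim 2 or 3.
#' @param support odd filter extent per axis.
#' @return a [FilterBank-class] with a single filter.
#' @export
gaussianBank <- function(fwhm, dim = 2, support = 7) {
  f <- gaussianFilter(fwhm, dim, support)
  new("FilterBank", filters = list(f), labels = "gaussian", fwhm = fwhm,
      dim = as.integer(dim), kind = "gaussian")
}

#' @rdname gaussianBank
#' @export
deltaBank <- function(dim = 2, support = 1) {
  f <- array(0, rep(support, dim))
  f[matrix((support + 1) / 2, 1, dim)] <- 1
  attr(f, "label") <- "delta"
  new("FilterBank", filters = list(f), labels = "delta", fwhm = 1e-6,
      dim = as.integer(dim), kind = "delta")
}

#' Sparse spatial transform for a filter bank on a geometry
#'
#' Precomputes, for each filter, the sparse `Q x Q` matrix S such that
#' convolving every frame image with the filter (zero padding, out-of-mask
#' voxels contributing zero) equals right-multiplication `Y %*% S`. The full
#' transform A of the bank is the column concatenation of the S blocks.
#' Precomputing lets repeated [applyTransform()] / [adjointTransform()] calls
#' on the same geometry reuse the matrices.
#'
#' @param bank a [FilterBank-class].
#' @param geom geometry list from [gridGeometry()].
#' @return list of `dgCMatrix` objects, one per filter.
#' @export
spatialTransform <- function(bank, geom) {
  msg <- validGeometry(geom)
  if (!isTRUE(msg)) stop(msg)
  dims <- geom$dims
  if (length(dims) != bank@dim) stop("bank dimension does not match geometry")
  maskIdx <- geom$maskIdx
  Q <- length(maskIdx)
  pos <- integer(prod(dims))          # grid linear index -> column, 0 if out
  pos[maskIdx] <- seq_len(Q)
  coords <- arrayInd(maskIdx, dims)   # Q x d
  lapply(bank@filters, function(f) {
    f <- as.array(f)
    supp <- dim(f)[1]
    offs <- filterOffsets(supp, length(dims))
    iL <- jL <- xL <- vector("list", nrow(offs))
    for (k in seq_len(nrow(offs))) {
      w <- f[matrix(offs[k, ] + (supp + 1) / 2, 1)]
      if (w == 0) next
      ## convolution: out[p] = sum_o f[o] in[p - o]
      src <- sweep(coords, 2, offs[k, ], "-")
      ok <- rep(TRUE, Q)
      for (a in seq_along(dims)) ok <- ok & src[, a] >= 1 & src[, a] <= dims[a]
      if (!any(ok)) next
      srcLin <- src[ok, 1]
      if (length(dims) >= 2) srcLin <- srcLin + (src[ok, 2] - 1) * dims[1]
      if (length(dims) == 3) srcLin <- srcLin + (src[ok, 3] - 1) * dims[1] * dims[2]
      srcPos <- pos[srcLin]
      keep <- srcPos > 0
      iL[[k]] <- srcPos[keep]
      jL[[k]] <- which(ok)[keep]
      xL[[k]] <- rep(w, sum(keep))
    }
    Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(xL),
                         dims = c(Q, Q))
  })
}

#' Apply the spatial transform Y-tilde = Y A
#'
#' Convolves each frame image with every filter in the bank and stacks the
#' results into one `T x Q` block per filter.
#'
#' @param x an [FmriDataset-class] or a `T x Q` matrix (then `geom` required).
#' @param bank a [FilterBank-class].
#' @param geom geometry (taken from the dataset when omitted).
#' @param xform optional precomputed [spatialTransform()] result.
#' @return a [FeatureData-class].
#' @export
applyTransform <- function(x, bank, geom = NULL, xform = NULL) {
  if (is(x, "FmriDataset")) {
    geom <- x@geometry
    Y <- x@data
  } else {
    Y <- as.matrix(x)
    if (is.null(geom)) stop("geometry required when x is a bare matrix")
    if (ncol(Y) != length(geom$maskIdx)) stop("ncol(Y) must equal mask size")
  }
  if (is.null(xform)) xform <- spatialTransform(bank, geom)
  blocks <- lapply(xform, function(S) as.matrix(Y %*% S))
  new("FeatureData", blocks = blocks, bank = bank, geometry = geom)
}

#' Adjoint of the spatial transform
#'
#' Applies A' to a `T x P` feature-space matrix (or a P-vector): correlates
#' each block with its coordinate-flipped filter and sums the blocks, so that
#' `<applyTransform(Y), V> == <Y, adjointTransform(V)>` exactly.
#'
#' @param V `T x P` matrix or length-P vector, with P = nfilters * Q, laid out
#'   as filter blocks; a [FeatureData-class] is also accepted.
#' @param bank the [FilterBank-class] used in the forward transform.
#' @param geom geometry list.
#' @param xform optional precomputed [spatialTransform()] result.
#' @return `T x Q` matrix (or Q-vector for vector input).
#' @export
adjointTransform <- function(V, bank, geom, xform = NULL) {
  if (is(V, "FeatureData")) {
    bank <- V@bank; geom <- V@geometry
    blocks <- V@blocks
  } else {
    Q <- length(geom$maskIdx)
    nb <- length(bank@filters)
    if (is.null(dim(V))) V <- matrix(V, nrow = 1)
    if (ncol(V) != nb * Q) stop("V must have nfilters * Q columns")
    blocks <- lapply(seq_len(nb), function(b)
      V[, (b - 1) * Q + seq_len(Q), drop = FALSE])
  }
  if (is.null(xform)) xform <- spatialTransform(bank, geom)
  out <- 0
  for (b in seq_along(blocks))
    out <- out + as.matrix(blocks[[b]] %*% Matrix::t(xform[[b]]))
  if (nrow(out) == 1) as.numeric(out) else out
}

#' Flatten FeatureData to the T x P matrix
#' @param ft a [FeatureData-class].
#' @return `T x P` matrix (blocks concatenated by columns).
#' @export
featureValues <- function(ft) {
  stopifnot(is(ft, "FeatureData"))
  do.call(cbind, ft@blocks)
}
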