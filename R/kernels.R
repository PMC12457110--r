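## Kernels module: the six kernel families built from normalized linear and
## quadratic Gram structures, and their analytic derivatives with respect to
## the original voxel data (chain rule through the spatial transform A), used
## by the back-reconstruction.

#' Normalized Gram components of feature-space data
#'
#' Computes the raw linear Gram `G0 = Ytilde Ytilde'` and squared pairwise
#' distances `D0_ij = ||Ytilde_i - Ytilde_j||^2` of the feature-space rows,
#' then normalizes each to its mean absolute value (off-diagonal entries only
#' for D, whose diagonal is structurally zero). Every kernel is an elementwise
#' function of these two matrices, which keeps the derivative bookkeeping in
#' the back-reconstruction straightforward.
#'
#' @param ft a [FeatureData-class] (or a plain `T x P` matrix).
#' @return a [GramComponents-class].
#' @export
gramComponents <- function(ft) {
  if (is(ft, "FeatureData")) {
    G0 <- 0
    for (b in ft@blocks) G0 <- G0 + tcrossprod(b)
  } else {
    ft <- as.matrix(ft)
    if (!all(is.finite(ft))) stop("feature data must be finite")
    G0 <- tcrossprod(ft)
  }
  if (!all(is.finite(G0))) stop("non-finite Gram matrix")
  Tn <- nrow(G0)
  if (Tn < 2) stop("at least two time points required")
  d <- diag(G0)
  D0 <- outer(d, d, "+") - 2 * G0
  D0[D0 < 0] <- 0
  diag(D0) <- 0
  gScale <- mean(abs(G0))
  if (gScale == 0) { warning("zero Gram scale; using 1"); gScale <- 1 }
  dScale <- sum(abs(D0)) / (Tn * (Tn - 1))
  if (dScale == 0) { warning("zero distance scale; using 1"); dScale <- 1 }
  G <- G0 / gScale
  D <- D0 / dScale
  new("GramComponents", G = (G + t(G)) / 2, D = (D + t(D)) / 2,
      gScale = gScale, dScale = dScale)
}

## Elementwise kernel value and its partial derivatives with respect to the
## normalized G and D. Returns list(K, dG, dD) of T x T matrices.
kernelElementwise <- function(spec, G, D, derivatives = FALSE) {
  p <- spec@params
  kn <- spec@name
  if (kn == "linear") {
    K <- G; dG <- if (derivatives) array(1, dim(G)) else NULL; dD <- NULL
  } else if (kn == "parabolic") {
    base <- G + p[["b"]]^2
    K <- base^2
    dG <- if (derivatives) 2 * base else NULL; dD <- NULL
  } else if (kn == "gaussian") {
    K <- exp(-D / p[["sigma"]]^2)
    dG <- NULL
    dD <- if (derivatives) -K / p[["sigma"]]^2 else NULL
  } else if (kn == "inverse") {
    base <- D + p[["b"]]^2
    if (any(base <= 0))
      stop("inverse kernel undefined: b = 0 with coincident points")
    K <- 1 / sqrt(base)
    dG <- NULL
    dD <- if (derivatives) -0.5 * base^(-1.5) else NULL
  } else if (kn == "tanh") {
    K <- tanh(p[["b"]] * G + p[["c"]])
    dG <- if (derivatives) p[["b"]] * (1 - K^2) else NULL; dD <- NULL
  } else if (kn == "mixed_tanh") {
    K <- tanh(p[["b1"]] * G + p[["b2"]] * D + p[["c"]])
    u <- if (derivatives) 1 - K^2 else NULL
    dG <- if (derivatives) p[["b1"]] * u else NULL
    dD <- if (derivatives) p[["b2"]] * u else NULL
  } else stop("unknown kernel")
  list(K = K, dG = dG, dD = dD)
}

#' Normalized kernel matrix for a kernel spec
#'
#' Evaluates the chosen kernel elementwise on the normalized Gram components
#' and divides the result by its own mean absolute value, so that
#' `mean(|K|) = 1` regardless of the kernel family or hyperparameters. With
#' this scheme the hyperbolic tangent kernel converges to the linear kernel as
#' `b -> 0` with `c = 0`, and the mixed hyperbolic tangent does so as
#' `b1 -> 0` with `b2 = c = 0`.
#'
#' @param spec a [KernelSpec-class].
#' @param comps a [GramComponents-class].
#' @return a [KernelGram-class].
#' @export
kernelGram <- function(spec, comps) {
  stopifnot(is(spec, "KernelSpec"), is(comps, "GramComponents"))
  K <- kernelElementwise(spec, comps@G, comps@D)$K
  if (!all(is.finite(K))) stop("non-finite kernel matrix")
  ps <- mean(abs(K))
  if (ps == 0) { warning("zero kernel scale; using 1"); ps <- 1 }
  new("KernelGram", values = K / ps, spec = spec, postScale = ps)
}

#' Back-reconstruction gradient of the kernel matrix
#'
#' Computes the unsigned voxel-space sensitivity
#' `sum_{t1,t2} d(K_Y)_{t1,t2} / dY_{t1} (v_Y)_{t2}`, a Q-vector, analytically:
#' the elementwise outer derivative of the kernel with respect to the
#' normalized Gram components is chained through `dG0_ij/dYtilde_i = Ytilde_j`
#' (plus an extra `Ytilde_i` on the diagonal, where the derivative is
#' `2 Ytilde_i`) and `dD0_ij/dYtilde_i = 2 (Ytilde_i - Ytilde_j)`, scaled by
#' the (constant) normalizers `1/gScale`, `1/dScale`, `1/postScale`, and the
#' result is mapped from the `T x P` feature space back to `T x Q` voxel space
#' through the adjoint of the spatial transform. The normalizers are treated
#' as constants during differentiation. Cost is O(T^2) for the kernel terms
#' plus O(T Q) per filter for the final contraction.
#'
#' @param spec a [KernelSpec-class].
#' @param x an [FmriDataset-class] or a precomputed [FeatureData-class].
#' @param bank [FilterBank-class] (ignored when `x` is FeatureData).
#' @param vY canonical weight vector of length T.
#' @param comps optional precomputed [GramComponents-class].
#' @param postScale optional precomputed kernel post-normalizer.
#' @param xform optional precomputed [spatialTransform()].
#' @return numeric Q-vector (no sign applied; see [activationMap()]).
#' @export
kernelBackmapGradient <- function(spec, x, bank = NULL, vY, comps = NULL,
                                  postScale = NULL, xform = NULL) {
  ft <- if (is(x, "FeatureData")) x else {
    if (is.null(bank)) stop("bank required when x is a dataset")
    applyTransform(x, bank, xform = xform)
  }
  Tn <- nrow(ft@blocks[[1]])
  if (length(vY) != Tn) stop("vY must have length T")
  if (is.null(comps)) comps <- gramComponents(ft)
  kd <- kernelElementwise(spec, comps@G, comps@D, derivatives = TRUE)
  if (is.null(postScale)) {
    postScale <- mean(abs(kd$K))
    if (postScale == 0) postScale <- 1
  }
  ## coefficient c such that the feature-space gradient is Ytilde' c
  cc <- numeric(Tn)
  if (!is.null(kd$dG)) {
    WG <- kd$dG / comps@gScale
    cc <- cc + (colSums(WG) + diag(WG)) * vY
  }
  if (!is.null(kd$dD)) {
    WD <- kd$dD / comps@dScale
    diag(WD) <- 0
    cc <- cc + 2 * as.numeric(WD %*% vY) - 2 * colSums(WD) * vY
  }
  cc <- cc / postScale
  if (is.null(xform)) xform <- spatialTransform(ft@bank, ft@geometry)
  out <- 0
  for (b in seq_along(ft@blocks)) {
    mb <- crossprod(ft@blocks[[b]], cc)          # Q x 1 feature-block gradient
    out <- out + as.numeric(xform[[b]] %*% mb)   # S_b %*% m_b = adjoint block
  }
  out
}
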