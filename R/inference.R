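## Inference module: hyperparameter optimization by voxel-shuffling
## robustness, and permutation null thresholds for KCCA and GLM maps.

#' Boundary voxel-shuffle plan
#'
#' Declares the activated set (top 10% of voxels by the map's alpha values),
#' and the counts of boundary voxels to reverse on each side: `q1`
#' non-activated voxels with the largest alpha and `q2` activated voxels with
#' the smallest alpha. Two standard settings are used: "half"
#' (`q1 = q2 = 0.5 Q+`, rounded to the nearest even count so pairing is
#' complete) and "full" (`q1 = Q_non`, `q2 = Q+`).
#'
#' @param map an [ActivationMap-class] (ranking uses its stored alpha values,
#'   absolute or signed per the map's convention).
#' @param setting "half" or "full".
#' @param topFraction fraction of voxels declared activated (default 0.10).
#' @return list with `qPlus`, `qNon`, `q1`, `q2`, `setting`, `order` (voxel
#'   indices sorted by decreasing alpha, ties broken by index).
#' @export
shufflePlan <- function(map, setting = c("half", "full"), topFraction = 0.10) {
  setting <- match.arg(setting)
  a <- alphaValues(map)
  Q <- length(a)
  qPlus <- round(topFraction * Q)
  qNon <- Q - qPlus
  if (setting == "half") {
    q1 <- q2 <- 2 * round(0.5 * qPlus / 2)   # nearest even count
  } else {
    q1 <- qNon; q2 <- qPlus
  }
  ord <- order(a, seq_along(a), decreasing = c(TRUE, FALSE), method = "radix")
  list(qPlus = qPlus, qNon = qNon, q1 = min(q1, qNon), q2 = min(q2, qPlus),
       setting = setting, order = ord)
}

#' Shuffle voxel time series near the decision boundary
#'
#' Selects the `q1` non-activated voxels with the largest alpha and the `q2`
#' activated voxels with the smallest alpha, and reverses the voxel order
#' within each group by alpha rank (largest swaps with smallest, second
#' largest with second smallest, ...), swapping the corresponding columns of
#' the data. The multiset of voxel time series is preserved; applying the
#' same plan twice restores the original data.
#'
#' @param dataset an [FmriDataset-class].
#' @param plan result of [shufflePlan()].
#' @return a new [FmriDataset-class] with permuted columns.
#' @export
voxelShuffle <- function(dataset, plan) {
  if (plan$q1 < 2 && plan$q2 < 2) {
    warning("fewer than two voxels on each boundary side; no swap performed")
    return(dataset)
  }
  perm <- seq_len(nVoxels(dataset))
  act <- plan$order[seq_len(plan$qPlus)]
  non <- plan$order[(plan$qPlus + 1):length(plan$order)]
  if (plan$q2 >= 2) {
    g2 <- act[(plan$qPlus - plan$q2 + 1):plan$qPlus]  # smallest-alpha activated
    perm[g2] <- rev(g2)
  }
  if (plan$q1 >= 2) {
    g1 <- non[seq_len(plan$q1)]                       # largest-alpha non-activated
    perm[g1] <- rev(g1)
  }
  out <- dataset
  out@data <- dataset@data[, perm, drop = FALSE]
  if (length(out@grayMask)) out@grayMask <- dataset@grayMask[perm]
  out
}

#' Apparent similarity between original and shuffled activation
#'
#' Treats the top 10% of voxels of the original map as ground truth and
#' scores the shuffled map against it with the partial AUC at FPR < 0.1 (the
#' apparent ROC). Ranges over [0, 0.1]; 0.1 means the activation pattern is
#' fully robust to the shuffle.
#'
#' @param map original [ActivationMap-class].
#' @param mapShuffled map recomputed on the shuffled data with identical
#'   kernel and hyperparameters.
#' @param topFraction fraction of voxels treated as ground truth.
#' @param fprMax partial-AUC bound.
#' @return similarity in [0, fprMax].
#' @export
shuffleSimilarity <- function(map, mapShuffled, topFraction = 0.10, fprMax = 0.1) {
  a <- alphaValues(map)
  b <- alphaValues(mapShuffled)
  if (length(a) != length(b)) stop("maps must have equal length")
  ord <- order(a, seq_along(a), decreasing = c(TRUE, FALSE), method = "radix")
  truth <- logical(length(a))
  truth[ord[seq_len(round(topFraction * length(a)))]] <- TRUE
  if (length(unique(b)) == 1) {
    warning("shuffled map is constant; chance-level similarity returned")
    return(fprMax^2 / 2)
  }
  partialAUC(rocCurve(b, truth), fprMax)
}

#' Voxel-shuffling robustness of a kernel/hyperparameter setting
#'
#' Computes the activation map, shuffles the data under both boundary
#' settings ("half" and "full"), recomputes the map with identical kernel and
#' hyperparameters, and averages the two apparent similarities with equal
#' weights. Hyperparameter settings whose activation survives the shuffles
#' score higher. The procedure is fully deterministic.
#'
#' @param dataset an [FmriDataset-class].
#' @param bank a [FilterBank-class].
#' @param spec a [KernelSpec-class].
#' @param gamma regularization (NULL for the default).
#' @param xEff effective design signal.
#' @param absolute map convention used for ranking.
#' @param xform optional precomputed [spatialTransform()].
#' @param feature,comps optional precomputed [applyTransform()] /
#'   [gramComponents()] of the unshuffled dataset.
#' @return list with `score` (mean similarity), `similarities` (per setting),
#'   `spec`, `gamma`.
#' @export
robustnessScore <- function(dataset, bank, spec, gamma = NULL, xEff,
                            absolute = TRUE, xform = NULL, feature = NULL,
                            comps = NULL) {
  if (is.null(xform)) xform <- spatialTransform(bank, geometry(dataset))
  if (is.null(feature)) feature <- applyTransform(dataset, bank, xform = xform)
  if (is.null(comps)) comps <- gramComponents(feature)
  kern <- kernelGram(spec, comps)
  fit <- kccaSolve(NULL, kern, gamma = gamma, xEff = xEff)
  baseMap <- activationMap(feature, spec = spec, fit = fit, xEff = xEff,
                           absolute = absolute, comps = comps, kern = kern,
                           xform = xform)
  base <- list(map = baseMap, fit = fit)
  gammaUsed <- base$fit@gamma
  sims <- vapply(c("half", "full"), function(set) {
    plan <- shufflePlan(base$map, setting = set)
    shuffled <- voxelShuffle(dataset, plan)
    redo <- kccaActivation(shuffled, bank, spec, xEff, gamma = gammaUsed,
                           absolute = absolute, xform = xform)
    shuffleSimilarity(base$map, redo$map)
  }, numeric(1))
  list(score = mean(sims), similarities = sims, spec = spec, gamma = gammaUsed)
}

#' Hyperparameter selection by shuffle robustness
#'
#' Exhaustively evaluates [robustnessScore()] over a grid of kernel
#' spec/gamma settings and returns the most robust one. Ties resolve to the
#' earliest grid entry, so order grids from the most linear-like setting
#' outward.
#'
#' @param dataset an [FmriDataset-class].
#' @param bank a [FilterBank-class].
#' @param grid list of `list(spec = KernelSpec, gamma = numeric)` entries.
#' @param xEff effective design signal.
#' @param absolute ranking convention.
#' @param xform optional precomputed transform.
#' @return list with `spec`, `gamma`, `score`, `index`, and `report` (the
#'   per-setting scores).
#' @export
optimizeHyperparams <- function(dataset, bank, grid, xEff, absolute = TRUE,
                                xform = NULL) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  if (is.null(xform)) xform <- spatialTransform(bank, geometry(dataset))
  ## the unshuffled feature data and Gram components are shared across the
  ## whole grid; only the shuffled recomputations depend on the setting
  feature <- applyTransform(dataset, bank, xform = xform)
  comps <- gramComponents(feature)
  scores <- vapply(grid, function(g)
    robustnessScore(dataset, bank, g$spec, g$gamma, xEff,
                    absolute = absolute, xform = xform, feature = feature,
                    comps = comps)$score, numeric(1))
  best <- which.max(scores)   # first maximum: most linear-like on ties
  list(spec = grid[[best]]$spec, gamma = grid[[best]]$gamma,
       score = scores[best], index = best,
       report = data.frame(
         setting = vapply(grid, function(g) {
           p <- g$spec@params
           sprintf("%s(%s) gamma=%.4g", g$spec@name,
                   paste(names(p), signif(p, 3), sep = "=", collapse = ","),
                   g$gamma %||% NA_real_)
         }, character(1)),
         score = scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hyperparameter grid
#'
#' Builds the default search grid: regularization
#' `gamma in {1e-3, 1e-2, 1e-1, 1} * mean(diag(K_linear))` crossed with, per
#' kernel family, tanh `b in {0.1, 0.3, 1, 3}` (c = 0), mixed tanh
#' `(b1, b2) in {0.1, 0.3, 1}^2` (c = 0), Gaussian `sigma^2 in {0.5, 1, 2}`,
#' parabolic/inverse `b^2 in {0.5, 1, 2}`, on the normalized Gram/distance
#' scale.
#'
#' @param kernels kernel family names to include.
#' @param meanDiag mean diagonal of the normalized linear kernel (scales the
#'   gamma grid); compute it from `gramComponents` as `mean(diag(G))`.
#' @return list of `list(spec, gamma)` entries, ordered most-linear-first
#'   within each family.
#' @export
defaultGrid <- function(kernels = "mixed_tanh", meanDiag = 1) {
  gammas <- c(1e-3, 1e-2, 1e-1, 1) * meanDiag
  out <- list()
  for (kn in kernels) {
    specs <- switch(kn,
      linear = list(kernelSpec("linear")),
      tanh = lapply(c(0.1, 0.3, 1, 3), function(b) kernelSpec("tanh", b = b, c = 0)),
      mixed_tanh = {
        pp <- expand.grid(b1 = c(0.1, 0.3, 1), b2 = c(0.1, 0.3, 1))
        pp <- pp[order(pp$b1 + pp$b2), ]
        lapply(seq_len(nrow(pp)), function(i)
          kernelSpec("mixed_tanh", b1 = pp$b1[i], b2 = pp$b2[i], c = 0))
      },
      gaussian = lapply(sqrt(c(0.5, 1, 2)), function(s) kernelSpec("gaussian", sigma = s)),
      parabolic = lapply(sqrt(c(0.5, 1, 2)), function(b) kernelSpec("parabolic", b = b)),
      inverse = lapply(sqrt(c(0.5, 1, 2)), function(b) kernelSpec("inverse", b = b)),
      stop("unknown kernel family: ", kn))
    for (sp in specs) for (g in gammas)
      out[[length(out) + 1L]] <- list(spec = sp, gamma = g)
  }
  out
}

#' Null activation threshold by permuting the canonical weights
#'
#' Forms an approximate null by randomly permuting the entries of `v_Y` (time
#' shuffling in the kernel dimension), recomputing the signed activation map
#' for each permutation through the identical kernel path, pooling all
#' `|alpha_null|` values, and returning the `(1 - rate)` quantile. Voxels
#' whose |alpha| exceeds the threshold are declared active at the per-voxel
#' uncorrected level `rate`.
#'
#' @param dataset an [FmriDataset-class].
#' @param bank a [FilterBank-class].
#' @param spec a [KernelSpec-class].
#' @param gamma regularization used in the fit (provenance only).
#' @param xEff effective design signal.
#' @param vY fitted canonical weight vector.
#' @param nShuffles number of permutations (default 20).
#' @param rate false-activation rate (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param xform optional precomputed transform.
#' @return the threshold (numeric scalar) with attribute "pool" omitted.
#' @export
nullThreshold <- function(dataset, bank, spec, gamma = NULL, xEff, vY,
                          nShuffles = 20, rate = 0.05, seed = NULL,
                          xform = NULL) {
  if (nShuffles < 1) stop("nShuffles must be at least 1")
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]")
  if (is.null(xform)) xform <- spatialTransform(bank, geometry(dataset))
  ft <- applyTransform(dataset, bank, xform = xform)
  comps <- gramComponents(ft)
  kern <- kernelGram(spec, comps)
  Tn <- length(vY)
  pool <- withSeed(seed, {
    unlist(lapply(seq_len(nShuffles), function(i) {
      vNull <- vY[sample.int(Tn)]
      s <- tryCatch(activationSign(xEff, kern, vNull), error = function(e) 1L)
      abs(s * kernelBackmapGradient(spec, ft, vY = vNull, comps = comps,
                                    postScale = kern@postScale, xform = xform))
    }))
  })
  as.numeric(quantile(pool, probs = 1 - rate, names = FALSE, type = 7))
}

#' Null threshold for the GLM baseline
#'
#' Permutes the effective design signal in time, recomputes the smoothed
#' per-voxel correlation map for each permutation, pools the absolute values
#' and returns the `(1 - rate)` quantile.
#'
#' @param dataset an [FmriDataset-class].
#' @param xEff effective design signal.
#' @param fwhm Gaussian FWHM (defaults by dimensionality as in [glmMap()]).
#' @param nShuffles,rate,seed as in [nullThreshold()].
#' @return the threshold.
#' @export
glmNullThreshold <- function(dataset, xEff, fwhm = NULL, nShuffles = 20,
                             rate = 0.05, seed = NULL) {
  if (nShuffles < 1) stop("nShuffles must be at least 1")
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]")
  d <- length(geometry(dataset)$dims)
  if (is.null(fwhm)) fwhm <- if (d == 2) 2 else 4
  bank <- gaussianBank(fwhm, dim = d)
  ft <- applyTransform(dataset, bank)
  x <- as.numeric(xEff)
  pool <- withSeed(seed, {
    unlist(lapply(seq_len(nShuffles), function(i)
      abs(corVec(x[sample.int(length(x))], ft@blocks[[1]]))))
  })
  as.numeric(quantile(pool, probs = 1 - rate, names = FALSE, type = 7))
}
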