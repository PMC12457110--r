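## Replication experiments on the 2D toy model. These bundle the full study
## procedures (pilot hyperparameter selection by shuffle robustness, then
## replicate-averaged evaluation) so that reported quantities are computed
## the same way everywhere (tests, acceptance script, user analyses).

#' GLM calibration experiment
#'
#' Generates replicates of the 2D toy dataset at a fixed signal strength and
#' returns the replicate partial AUCs (FPR < 0.1) of the Gaussian-smoothing
#' GLM baseline against the ground-truth mask. Under the calibrated
#' simulation conditions the mean lands in the [0.035, 0.05] band at
#' `rho ~ 0.03`.
#'
#' @param nReps number of replicates (default 50).
#' @param dims grid extents (default `c(100, 400)`).
#' @param rho signal strength (default 0.03).
#' @param seed master seed (one sub-seed per replicate).
#' @return list with `paucs` (per replicate) and `mean`.
#' @export
glmCalibration <- function(nReps = 50, dims = c(100, 400), rho = 0.03,
                           seed = 1) {
  geom <- gridGeometry(dims)
  gxf <- spatialTransform(gaussianBank(2, dim = 2), geom)
  seeds <- seedStreams(seed, nReps)
  paucs <- vapply(seq_len(nReps), function(i) {
    sim <- simulateToy2D(dims = dims, rho = rho, seed = seeds[[i]])
    g <- glmMap(sim@dataset, sim@xEff, xform = gxf)
    partialAUC(rocCurve(alphaValues(g), sim@truthMask))
  }, numeric(1))
  list(paucs = paucs, mean = mean(paucs))
}

## Pilot hyperparameter selection, two-stage: (1) the regularization gamma
## is selected on the linear kernel's gamma grid; (2) the mixed hyperbolic
## tangent (b1, b2) pair is selected at that gamma. Robustness scores are
## averaged over the pilot replicates before each argmax (the score
## differences between neighboring settings are small, so a single pilot
## can flip the selection). The gamma grid is scaled by the mean diagonal
## of the normalized linear Gram for every kernel, which keeps all kernels
## regularized on a common scale.
pilotHyperparams <- function(dims, rho, delta, seeds, bank, xform) {
  sims <- lapply(seeds, function(s)
    simulateToy2D(dims = dims, rho = rho, delta = delta, seed = s))
  pieces <- lapply(sims, function(sim) {
    ft <- applyTransform(sim@dataset, bank, xform = xform)
    list(sim = sim, ft = ft, cc = gramComponents(ft))
  })
  md <- mean(vapply(pieces, function(p) mean(diag(p$cc@G)), numeric(1)))
  selectBest <- function(grid) {
    scores <- vapply(grid, function(g) {
      mean(vapply(pieces, function(p)
        robustnessScore(p$sim@dataset, bank, g$spec, g$gamma, p$sim@xEff,
                        xform = xform, feature = p$ft, comps = p$cc)$score,
        numeric(1)))
    }, numeric(1))
    grid[[which.max(scores)]]
  }
  bestL <- selectBest(defaultGrid("linear", md))
  bGrid <- expand.grid(b1 = c(0.1, 0.3, 1), b2 = c(0.1, 0.3, 1))
  bGrid <- bGrid[order(bGrid$b1 + bGrid$b2), ]
  mixedGrid <- lapply(seq_len(nrow(bGrid)), function(i)
    list(spec = kernelSpec("mixed_tanh", b1 = bGrid$b1[i], b2 = bGrid$b2[i],
                           c = 0), gamma = bestL$gamma))
  bestM <- selectBest(mixedGrid)
  list(linearGamma = bestL$gamma, mixedSpec = bestM$spec,
       mixedGamma = bestM$gamma)
}

#' Sign-effect experiment
#'
#' The absolute-value-versus-signed comparison on the 2D toy model: at
#' `rho = 0.035`, `delta = 0`, Gaussian noise, hyperparameters are chosen
#' once by voxel-shuffling robustness on a pilot replicate (the gamma grid
#' for the linear kernel; the full `(b1, b2, gamma)` grid for the mixed
#' hyperbolic tangent kernel) and held fixed. Each replicate is then scored
#' by the partial AUC (FPR < 0.1) of the |alpha| and signed-alpha maps for
#' both kernels, plus the GLM baseline, against the ground truth.
#'
#' @param nReps number of replicates (default 50).
#' @param dims grid extents (default `c(50, 200)`).
#' @param rho signal strength (default 0.035).
#' @param seed master seed.
#' @param nPilots pilot replicates averaged in the robustness selection.
#' @return list with the replicate-mean quantities `linearAbs`, `mixedAbs`,
#'   `linearSgn`, `mixedSgn`, `glm`, the mean normalized improvements (in
#'   percent, absolute-value maps) `imprLinearPct`, `imprMixedPct`, the
#'   chosen hyperparameters, and the per-replicate table `perRep`.
#' @export
signEffectExperiment <- function(nReps = 50, dims = c(50, 200), rho = 0.035,
                                 seed = 1, nPilots = 2) {
  bank <- steerableBank(2)
  geom <- gridGeometry(dims)
  xf <- spatialTransform(bank, geom)
  gxf <- spatialTransform(gaussianBank(2, dim = 2), geom)
  seeds <- seedStreams(seed, nReps + nPilots)
  hp <- pilotHyperparams(dims, rho, 0, seeds[nReps + seq_len(nPilots)],
                         bank, xf)
  rows <- lapply(seq_len(nReps), function(i) {
    sim <- simulateToy2D(dims = dims, rho = rho, seed = seeds[[i]])
    tm <- sim@truthMask
    g <- glmMap(sim@dataset, sim@xEff, xform = gxf)
    ft <- applyTransform(sim@dataset, bank, xform = xf)
    cc <- gramComponents(ft)
    out <- c(glm = partialAUC(rocCurve(alphaValues(g), tm)))
    for (m in list(list(nm = "linear", spec = kernelSpec("linear"),
                        gamma = hp$linearGamma),
                   list(nm = "mixed", spec = hp$mixedSpec,
                        gamma = hp$mixedGamma))) {
      kern <- kernelGram(m$spec, cc)
      fit <- kccaSolve(NULL, kern, gamma = m$gamma, xEff = sim@xEff)
      map <- activationMap(ft, spec = m$spec, fit = fit, xEff = sim@xEff,
                           absolute = FALSE, comps = cc, kern = kern,
                           xform = xf)
      out[paste0(m$nm, "Sgn")] <- partialAUC(rocCurve(alphaValues(map), tm))
      out[paste0(m$nm, "Abs")] <- partialAUC(rocCurve(abs(alphaValues(map)), tm))
    }
    out
  })
  perRep <- do.call(rbind, rows)
  list(linearAbs = mean(perRep[, "linearAbs"]),
       mixedAbs = mean(perRep[, "mixedAbs"]),
       linearSgn = mean(perRep[, "linearSgn"]),
       mixedSgn = mean(perRep[, "mixedSgn"]),
       glm = mean(perRep[, "glm"]),
       imprLinearPct = 100 * (mean(perRep[, "linearAbs"] / perRep[, "glm"]) - 1),
       imprMixedPct = 100 * (mean(perRep[, "mixedAbs"] / perRep[, "glm"]) - 1),
       hyperparams = hp, perRep = as.data.frame(perRep))
}

#' Deviation-effect experiment
#'
#' Measures the advantage of the mixed hyperbolic tangent kernel over the
#' linear kernel when the added signal deviates from the effective design:
#' at `rho = 0.03`, Gaussian noise, and large contrast perturbations
#' (`delta = 0.4, 0.5` by default), hyperparameters are chosen by shuffle
#' robustness on a pilot replicate per delta, and the per-replicate
#' GLM-normalized difference `(pAUC_mixed - pAUC_linear) / pAUC_GLM * 100`
#' is averaged (absolute-value maps).
#'
#' @param deltas perturbation scales.
#' @param nReps replicates per delta (default 50).
#' @param dims grid extents (default `c(50, 200)`).
#' @param rho signal strength (default 0.03).
#' @param seed master seed.
#' @param pilotDelta deviation used for the shared hyperparameter pilot
#'   (default: midpoint of `deltas`).
#' @param nPilots number of pilot replicates whose robustness scores are
#'   averaged before the argmax (default 4).
#' @return list with `meanImprovementPct` (across all deltas), `perDelta`
#'   (data.frame), and the chosen hyperparameters (shared across deltas).
#' @export
deviationExperiment <- function(deltas = c(0.4, 0.5), nReps = 50,
                                dims = c(50, 200), rho = 0.03, seed = 1,
                                pilotDelta = mean(deltas), nPilots = 4) {
  bank <- steerableBank(2)
  geom <- gridGeometry(dims)
  xf <- spatialTransform(bank, geom)
  gxf <- spatialTransform(gaussianBank(2, dim = 2), geom)
  seeds <- seedStreams(seed, length(deltas) * nReps + nPilots)
  hp <- pilotHyperparams(dims, rho, pilotDelta,
                         seeds[length(deltas) * nReps + seq_len(nPilots)],
                         bank, xf)
  k <- 0
  perDelta <- list()
  for (dl in deltas) {
    k <- k + 1
    vals <- vapply(seq_len(nReps), function(i) {
      sim <- simulateToy2D(dims = dims, rho = rho, delta = dl,
                           seed = seeds[[(k - 1) * nReps + i]])
      tm <- sim@truthMask
      g <- partialAUC(rocCurve(alphaValues(
        glmMap(sim@dataset, sim@xEff, xform = gxf)), tm))
      ft <- applyTransform(sim@dataset, bank, xform = xf)
      cc <- gramComponents(ft)
      pa <- vapply(list(list(spec = kernelSpec("linear"), gamma = hp$linearGamma),
                        list(spec = hp$mixedSpec, gamma = hp$mixedGamma)),
                   function(m) {
        kern <- kernelGram(m$spec, cc)
        fit <- kccaSolve(NULL, kern, gamma = m$gamma, xEff = sim@xEff)
        map <- activationMap(ft, spec = m$spec, fit = fit, xEff = sim@xEff,
                             absolute = TRUE, comps = cc, kern = kern,
                             xform = xf)
        partialAUC(rocCurve(alphaValues(map), tm))
      }, numeric(1))
      100 * (pa[2] - pa[1]) / g
    }, numeric(1))
    perDelta[[as.character(dl)]] <- data.frame(delta = dl,
                                               meanImprovementPct = mean(vals))
  }
  perDelta <- do.call(rbind, perDelta)
  list(meanImprovementPct = mean(perDelta$meanImprovementPct),
       perDelta = perDelta, hyperparams = hp)
}
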