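## Backmap module: signed voxel-space activation maps from a KCCA fit via the
## derivative-based back-reconstruction.

#' Sign of the activation
#'
#' Returns the sign of the Pearson correlation between the effective design
#' signal and the kernel-space data signal `KY vY`. An exact zero correlation
#' (a measure-zero tie) resolves to +1 with a warning.
#'
#' @param xEff single-column effective design signal, length T.
#' @param KY a [KernelGram-class] or `T x T` matrix.
#' @param vY canonical weight vector.
#' @return `-1L` or `+1L`.
#' @export
activationSign <- function(xEff, KY, vY) {
  KYm <- if (is(KY, "KernelGram")) KY@values else as.matrix(KY)
  z <- as.numeric(KYm %*% vY)
  if (sd(z) == 0) stop("degenerate kernel-space signal: KY vY is constant")
  r <- cor(as.numeric(xEff), z)
  if (r == 0) { warning("zero correlation; sign resolved to +1"); return(1L) }
  if (r > 0) 1L else -1L
}

#' Voxel-space activation map from a KCCA fit
#'
#' Back-reconstructs the per-voxel activation
#' `alpha = s * sum_{t1,t2} d(K_Y)_{t1,t2}/dY_{t1} (v_Y)_{t2}` where
#' `s = sign(corr(X_eff, K_Y v_Y))`. With `absolute = TRUE` (the simulation
#' convention) the absolute value is taken; real-data analyses retain the
#' sign. The map is in arbitrary units and is deliberately not rescaled:
#' downstream evaluation is threshold-sweep based and therefore scale-free.
#'
#' @param x an [FmriDataset-class] or precomputed [FeatureData-class].
#' @param bank [FilterBank-class] (ignored when `x` is FeatureData).
#' @param spec [KernelSpec-class].
#' @param fit [KccaFit-class] obtained from the same data/bank/spec.
#' @param xEff effective design signal (single column).
#' @param absolute take |alpha| (default TRUE).
#' @param comps,kern,xform optional precomputed pieces ([gramComponents()],
#'   [kernelGram()], [spatialTransform()]) to avoid recomputation.
#' @return an [ActivationMap-class].
#' @export
activationMap <- function(x, bank = NULL, spec, fit, xEff, absolute = TRUE,
                          comps = NULL, kern = NULL, xform = NULL) {
  ft <- if (is(x, "FeatureData")) x else {
    if (is.null(bank)) stop("bank required when x is a dataset")
    applyTransform(x, bank, xform = xform)
  }
  if (is.null(comps)) comps <- gramComponents(ft)
  if (is.null(kern)) kern <- kernelGram(spec, comps)
  s <- activationSign(xEff, kern, fit@vY)
  grad <- kernelBackmapGradient(spec, ft, vY = fit@vY, comps = comps,
                                postScale = kern@postScale, xform = xform)
  alpha <- s * grad
  if (absolute) alpha <- abs(alpha)
  new("ActivationMap", alpha = alpha, sign = s, absolute = absolute,
      spec = spec, gamma = fit@gamma, geometry = ft@geometry)
}

#' One-call KCCA activation pipeline
#'
#' Convenience wrapper: spatial transform, Gram components, kernel matrix,
#' KCCA fit, and back-reconstruction in one call.
#'
#' @param dataset an [FmriDataset-class] (standardized).
#' @param bank a [FilterBank-class].
#' @param spec a [KernelSpec-class].
#' @param xEff effective design signal.
#' @param gamma regularization; `NULL` for the default
#'   `0.1 * mean(diag(K_Y))`.
#' @param absolute take |alpha|.
#' @param xform optional precomputed [spatialTransform()].
#' @return list with elements `map` ([ActivationMap-class]) and `fit`
#'   ([KccaFit-class]).
#' @export
kccaActivation <- function(dataset, bank, spec, xEff, gamma = NULL,
                           absolute = TRUE, xform = NULL) {
  if (is.null(xform)) xform <- spatialTransform(bank, geometry(dataset))
  ft <- applyTransform(dataset, bank, xform = xform)
  comps <- gramComponents(ft)
  kern <- kernelGram(spec, comps)
  fit <- kccaSolve(NULL, kern, gamma = gamma, xEff = xEff)
  map <- activationMap(ft, spec = spec, fit = fit, xEff = xEff,
                       absolute = absolute, comps = comps, kern = kern,
                       xform = xform)
  list(map = map, fit = fit)
}
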