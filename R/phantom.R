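## 3D phantom: a synthetic volumetric dataset with gray/white/CSF tissue
## labels and bilateral ellipsoidal activation regions, emulating the
## structure of a region-based volumetric simulation. All tissue geometry is
## synthetic (no atlas or acquired data is used).

## Ellipsoid indicator on a grid: center ctr (voxel coords), semi-axes ax.
ellipsoidMask <- function(dims, ctr, ax) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- ((co[, 1] - ctr[1]) / ax[1])^2 + ((co[, 2] - ctr[2]) / ax[2])^2 +
        ((co[, 3] - ctr[3]) / ax[3])^2
  array(d2 <= 1, dims)
}

#' Synthetic tissue labels for the 3D phantom
#'
#' Builds a brain-shaped ellipsoid with an inner white-matter core, small
#' central CSF ventricles, and a gray-matter shell (brain minus white minus
#' CSF, roughly half the brain volume).
#'
#' @param dims volume extents (default `c(32, 38, 32)`).
#' @return list of logical arrays `brain`, `gray`, `white`, `csf`.
#' @export
phantomTissues <- function(dims = c(32, 38, 32)) {
  ctr <- (dims + 1) / 2
  brainAx <- dims / 2 - 1.5
  brain <- ellipsoidMask(dims, ctr, brainAx)
  white <- ellipsoidMask(dims, ctr, brainAx * 0.78)
  csf <- ellipsoidMask(dims, ctr, brainAx * 0.22)
  white <- white & !csf
  gray <- brain & !white & !csf
  list(brain = brain, gray = gray, white = white, csf = csf & brain)
}

#' Simulate the 3D phantom dataset
#'
#' Places six bilateral ellipsoidal activation regions inside the gray-matter
#' shell (three mirrored pairs across the sagittal midline), scaled so the
#' active voxels total ~10% of the brain, and assembles
#' `Y = noise + rho * signal` with AR(1) temporal noise (`phi = 0.2`),
#' Gaussian spatial noise correlation (FWHM `spatialFwhm` mm), an
#' HRF-convolved design with contrast `[1, -1, 0]` and a per-dataset contrast
#' perturbation `delta = 0.1`. When `rho` is `NULL` it is calibrated with
#' [tuneRho()] so the GLM partial AUC lands in [0.035, 0.05].
#'
#' @param dims volume extents (default `c(32, 38, 32)`).
#' @param nTime frames (default 390, matching the emulated design).
#' @param voxelSize mm per axis (default 2 mm isotropic).
#' @param rho signal strength; `NULL` calibrates it automatically.
#' @param delta contrast perturbation scale (default 0.1).
#' @param phi AR(1) coefficient of the temporal noise (default 0.2).
#' @param spatialFwhm FWHM (mm) of the spatial correlation imposed on the
#'   noise (default 3).
#' @param seed master seed.
#' @param designSeed seed of the shared design.
#' @return a [SimulatedDataset-class] whose dataset carries the gray-matter
#'   mask; `params` records the tissue labels and all generating values.
#' @export
makePhantom3D <- function(dims = c(32, 38, 32), nTime = 390,
                          voxelSize = c(2, 2, 2), rho = NULL, delta = 0.1,
                          phi = 0.2, spatialFwhm = 3, seed = NULL,
                          designSeed = 1) {
  tis <- phantomTissues(dims)
  brainIdx <- which(tis$brain)
  nBrain <- length(brainIdx)
  ctr <- (dims + 1) / 2
  brainAx <- dims / 2 - 1.5
  ## six bilateral regions: three mirrored pairs at fixed angular positions
  ## in the gray shell; radii scaled until ~10% of brain voxels are active
  shellR <- 0.88
  angles <- c(0.6, 1.9, 3.6)
  centers <- do.call(rbind, lapply(angles, function(a) {
    off <- c(cos(a) * 0.55, sin(a) * 0.7, sin(2 * a) * 0.45) * shellR
    rbind(ctr + off * brainAx, ctr + c(-off[1], off[2], off[3]) * brainAx)
  }))
  scale <- 2.2
  act <- NULL
  for (iter in 1:40) {
    act <- array(FALSE, dims)
    for (k in seq_len(nrow(centers)))
      act <- act | ellipsoidMask(dims, centers[k, ], rep(scale, 3))
    act <- act & tis$gray
    fr <- sum(act) / nBrain
    if (fr >= 0.08 && fr <= 0.12) break
    scale <- scale * if (fr < 0.08) 1.06 else 1 / 1.06
  }
  fr <- sum(act) / nBrain
  if (fr < 0.08 || fr > 0.12)
    stop(sprintf("could not place regions at ~10%% of brain voxels (got %.3f)", fr))

  design <- makeWmTaskDesign(nTime = nTime, seed = designSeed)
  X <- buildDesignMatrix(design)
  baseContrast <- c(1, -1, 0)
  xEff <- as.numeric(effectiveDesign(X, baseContrast))
  geom <- gridGeometry(dims, tis$brain)
  smoother <- spatialTransform(
    gaussianBank(spatialFwhm / voxelSize[1], dim = 3), geom)[[1]]

  generate <- function(rhoVal, s) {
    ss <- seedStreams(s, 2)
    noise <- genNoise(nTime, nBrain, phi = phi, seed = ss[[1]],
                      standardize = FALSE)
    noise <- colStandardize(as.matrix(noise %*% smoother))
    xAdd <- genAddedSignal(X, baseContrast, delta = delta, seed = ss[[2]])
    sim <- assembleSimulation(noise, rhoVal, xAdd, mask = act[brainIdx],
                              geom = geom, X = X, xEff = xEff, tr = design@tr,
                              params = list(delta = delta, phi = phi,
                                            spatialFwhm = spatialFwhm,
                                            seed = s, rho = rhoVal))
    sim@dataset@grayMask <- tis$gray[brainIdx]
    validObject(sim@dataset)
    sim
  }

  seeds <- seedStreams(seed, 2)
  rhoTrajectory <- NULL
  if (is.null(rho)) {
    ## the GLM detector smooths at FWHM 4 mm expressed in voxel units
    detector <- function(sim) {
      g <- glmMap(sim@dataset, sim@xEff, fwhm = 4 / voxelSize[1],
                  absolute = TRUE)
      partialAUC(rocCurve(alphaValues(g), sim@truthMask), 0.1)
    }
    rho <- tuneRho(function(r, s) generate(r, s), detector = detector,
                   seed = seeds[[1]])
    rhoTrajectory <- attr(rho, "trajectory")
    rho <- as.numeric(rho)
  }
  sim <- generate(rho, seeds[[2]])
  sim@dataset@voxelSize <- as.numeric(voxelSize)
  sim@params <- c(sim@params,
                  list(tissues = tis, rhoTrajectory = rhoTrajectory,
                       designSeed = designSeed, voxelSize = voxelSize))
  sim
}
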