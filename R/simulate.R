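## Simulation module: 2D word-mask toy datasets, noise and added-signal
## generators, the data assembly Y = noise + rho * signal, and the automatic
## signal-strength calibration against the GLM baseline.

## 5 x 7 glyph bitmaps (rows top to bottom, "1" = ink) for the letters used by
## the default activation word. Rendering is resolution-independent: glyphs
## are rasterized by nearest-neighbor lookup at any scale.
.glyphs <- list(
  K = c("10001", "10010", "10100", "11000", "10100", "10010", "10001"),
  E = c("11111", "10000", "10000", "11110", "10000", "10000", "11111"),
  R = c("11110", "10001", "10001", "11110", "10100", "10010", "10001"),
  N = c("10001", "11001", "10101", "10011", "10001", "10001", "10001"),
  L = c("10000", "10000", "10000", "10000", "10000", "10000", "11111")
)

glyphMatrix <- function(ch) {
  g <- .glyphs[[toupper(ch)]]
  if (is.null(g)) stop(sprintf("no glyph for character '%s'", ch))
  do.call(rbind, lapply(g, function(row) as.integer(strsplit(row, "")[[1]])))
}

#' Rasterize a word into a binary activation mask
#'
#' Renders the text (default "kernel") centered on the grid from built-in
#' 5 x 7 glyph bitmaps, choosing the glyph scale so the active fraction lands
#' in the target band (~10% of voxels, asserted within [8%, 12%]). The result
#' is a pure function of the grid size and text: identical across runs.
#'
#' @param dims grid extents, e.g. `c(100, 400)` (rows, columns).
#' @param text word to rasterize (letters with built-in glyphs).
#' @param targetFraction desired active fraction (default 0.10).
#' @param band acceptable fraction band (default `c(0.08, 0.12)`).
#' @return logical matrix of dimension `dims`.
#' @export
makeWordMask <- function(dims, text = "kernel", targetFraction = 0.10,
                         band = c(0.08, 0.12)) {
  if (nchar(text) == 0) stop("empty text would give a zero mask")
  chars <- strsplit(text, "")[[1]]
  glyphs <- lapply(chars, glyphMatrix)
  nc <- length(glyphs)
  baseH <- 7L
  baseW <- 5L * nc + (nc - 1L)              # one-cell gaps between glyphs
  base <- matrix(0L, baseH, baseW)
  for (k in seq_len(nc))
    base[, (k - 1L) * 6L + 1:5] <- glyphs[[k]]
  ## bold rendering: upsample x2 and thicken strokes twice so the rasterized
  ## letters have solid strokes; thin strokes would consist mostly of edge
  ## voxels whose added signal is diluted under spatial smoothing, which
  ## would break the published GLM calibration of the simulation
  base <- base[rep(seq_len(baseH), each = 2), rep(seq_len(baseW), each = 2)]
  for (it in 1:2) {
    dil <- base
    dil[-1, ] <- pmax(dil[-1, ], base[-nrow(base), ])
    dil[-nrow(dil), ] <- pmax(dil[-nrow(dil), ], base[-1, ])
    dil[, -1] <- pmax(dil[, -1], base[, -ncol(base)])
    dil[, -ncol(dil)] <- pmax(dil[, -ncol(dil)], base[, -1])
    base <- dil
  }
  baseH <- nrow(base); baseW <- ncol(base)
  ink <- sum(base)
  if (ink == 0) stop("text rasterizes to a zero mask")
  H <- dims[1]; W <- dims[2]
  s <- sqrt(targetFraction * H * W / ink)
  render <- function(s) {
    bh <- min(H, max(1, round(baseH * s)))
    bw <- min(W, max(1, round(baseW * s)))
    i0 <- floor((H - bh) / 2); j0 <- floor((W - bw) / 2)
    m <- matrix(FALSE, H, W)
    ii <- pmin(baseH, pmax(1, ceiling((seq_len(bh) - 0.5) / bh * baseH)))
    jj <- pmin(baseW, pmax(1, ceiling((seq_len(bw) - 0.5) / bw * baseW)))
    m[i0 + seq_len(bh), j0 + seq_len(bw)] <- base[ii, jj] == 1L
    m
  }
  for (iter in 1:40) {
    m <- render(s)
    fr <- mean(m)
    if (fr >= band[1] && fr <= band[2]) return(m)
    if (fr < band[1]) s <- s * 1.04 else s <- s / 1.04
    if (baseH * s > H || baseW * s > W)
      break
  }
  m <- render(s)
  fr <- mean(m)
  if (fr < band[1] || fr > band[2])
    stop(sprintf("cannot reach active fraction band [%g, %g] on a %dx%d grid (got %.3f)",
                 band[1], band[2], H, W, fr))
  m
}

#' Generate temporal noise
#'
#' Independent standard-normal noise (`phi = 0`) or column-wise AR(1) noise
#' `x_t = phi x_{t-1} + N(0, 1)` initialized from the stationary distribution
#' (variance `1 / (1 - phi^2)`). Columns are standardized to mean 0,
#' variance 1 afterwards.
#'
#' @param nTime,nVoxels matrix dimensions.
#' @param phi AR(1) coefficient in [0, 1).
#' @param seed RNG seed.
#' @param standardize standardize columns (default TRUE).
#' @return `nTime x nVoxels` matrix.
#' @export
genNoise <- function(nTime, nVoxels, phi = 0, seed = NULL, standardize = TRUE) {
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  E <- withSeed(seed, {
    E <- matrix(rnorm(nTime * nVoxels), nTime, nVoxels)
    if (phi > 0) {
      E[1, ] <- E[1, ] / sqrt(1 - phi^2)
      for (t in 2:nTime) E[t, ] <- phi * E[t - 1, ] + E[t, ]
    }
    E
  })
  if (standardize) colStandardize(E) else E
}

#' Generate the added signal with contrast perturbation
#'
#' Draws one perturbation per dataset ("per subject"): the added signal is
#' `X (c + delta * eps)` with `eps ~ N(0, I)`, standardized to mean 0,
#' variance 1. `delta` controls how far the true activation time course
#' deviates from the effective design signal; at `delta = 0` the added signal
#' is the deterministic contrast course.
#'
#' @param X design matrix, `T x K`.
#' @param baseContrast length-K contrast vector.
#' @param delta nonnegative perturbation scale.
#' @param seed RNG seed.
#' @return standardized length-T vector; attribute "contrastUsed" stores the
#'   perturbed contrast.
#' @export
genAddedSignal <- function(X, baseContrast, delta = 0, seed = NULL) {
  if (delta < 0) stop("delta must be nonnegative")
  X <- as.matrix(X)
  if (length(baseContrast) != ncol(X)) stop("contrast length must match design columns")
  withSeed(seed, {
    for (attempt in 1:10) {
      ct <- baseContrast + if (delta > 0) delta * rnorm(length(baseContrast)) else 0
      xa <- as.numeric(X %*% ct)
      if (sd(xa) > 0) {
        out <- stdVector(xa)
        attr(out, "contrastUsed") <- ct
        return(out)
      }
      warning("degenerate added signal; redrawing perturbation")
    }
    stop("could not draw a non-degenerate added signal in 10 attempts")
  })
}

#' Assemble a simulated dataset
#'
#' The literal generative model: `Y = Y_noise + rho * Y_signal`, where the
#' signal columns equal the added time course on masked voxels and 0
#' elsewhere, followed by per-voxel standardization (the preprocessing
#' convention for real data).
#'
#' @param noise `T x Q` noise matrix (columns standardized).
#' @param rho signal strength.
#' @param xAdd standardized added signal, length T.
#' @param mask logical activation indicator (length Q, or a full-grid matrix
#'   whose dimensions provide the geometry).
#' @param dims grid extents (taken from `mask` when it is a matrix/array).
#' @param geom optional geometry list when the data cover only in-mask voxels
#'   of a larger grid (e.g. brain-masked volumes).
#' @param X,xEff optional design matrix and effective design for provenance.
#' @param tr repetition time.
#' @param params extra provenance entries.
#' @return a [SimulatedDataset-class].
#' @export
assembleSimulation <- function(noise, rho, xAdd, mask, dims = NULL, geom = NULL,
                               X = NULL, xEff = NULL, tr = 1, params = list()) {
  if (!is.null(dim(mask))) { dims <- dim(mask); mask <- as.logical(mask) }
  if (is.null(dims) && is.null(geom)) stop("grid dims required when mask is a bare vector")
  if (length(mask) != ncol(noise)) stop("mask length must equal ncol(noise)")
  if (length(xAdd) != nrow(noise)) stop("xAdd length must equal nrow(noise)")
  Y <- noise
  Y[, mask] <- Y[, mask] + rho * as.numeric(xAdd)
  if (!is.null(geom)) {
    full <- logical(prod(geom$dims))
    full[geom$maskIdx] <- TRUE
    ds <- FmriDataset(Y, dims = geom$dims, mask = full, tr = tr, standardize = TRUE)
  } else {
    ds <- FmriDataset(Y, dims = dims, tr = tr, standardize = TRUE)
  }
  new("SimulatedDataset", dataset = ds, truthMask = mask,
      X = if (is.null(X)) matrix(0, nrow(noise), 0) else as.matrix(X),
      xEff = if (is.null(xEff)) numeric(0) else as.numeric(xEff),
      xAdd = as.numeric(xAdd),
      params = c(list(rho = rho), params))
}

#' Emulated working-memory task design
#'
#' A seeded block design standing in for a working-memory run: nine 22 s
#' condition blocks (three per condition, seeded random order) separated by
#' ~8 s fixation gaps, at TR = 0.72 s over T = 390 frames. The balanced block
#' structure keeps the three HRF-convolved regressors comparable in scale and
#' only weakly correlated, so the contrast time course `X c` stays closely
#' aligned with the effective design signal -- the regime in which the
#' published GLM calibration of the simulation holds.
#'
#' @param nTime number of frames (default 390).
#' @param tr repetition time in seconds (default 0.72).
#' @param seed design seed (default 1; fix it to share one design across
#'   replicates, as one run is shared across subjects).
#' @param blockDur block duration in seconds.
#' @param perCond number of blocks per condition.
#' @return a [TaskDesign-class] with conditions `target`, `nontarget`, `lure`.
#' @export
makeWmTaskDesign <- function(nTime = 390, tr = 0.72, seed = 1,
                             blockDur = 22, perCond = 3) {
  total <- nTime * tr
  conditionNames <- c("target", "nontarget", "lure")
  nBlocks <- perCond * length(conditionNames)
  gap <- (total - nBlocks * blockDur) / (nBlocks + 1)
  if (gap < 0) stop("run too short for the block layout")
  rows <- withSeed(seed, {
    types <- sample(rep(conditionNames, perCond))
    do.call(rbind, lapply(seq_len(nBlocks), function(b)
      data.frame(condition = types[b],
                 onset_s = gap * b + blockDur * (b - 1),
                 duration_s = blockDur)))
  })
  td <- onsetsToDesign(rows, nTime, tr)
  td@conditions <- td@conditions[conditionNames]
  td
}

#' Simulate the 2D toy dataset
#'
#' Generates the full 2D benchmark: word-shaped activation mask (~10% of the
#' grid), Gaussian or AR(1) noise, an HRF-convolved 3-condition design with
#' contrast `[1, -1, 0]`, a per-dataset contrast perturbation of scale
#' `delta`, and the assembly `Y = noise + rho * signal` with per-voxel
#' standardization. A master seed is split into independent sub-streams for
#' noise and perturbation; the design uses its own fixed seed so every
#' replicate shares one design.
#'
#' @param dims grid extents (default `c(100, 400)`).
#' @param rho signal strength (default 0.03).
#' @param delta contrast perturbation scale (default 0).
#' @param phi AR(1) noise coefficient (default 0; implies Gaussian noise).
#' @param noiseKind "gaussian" or "ar1"; consistency-checked against `phi`.
#' @param seed master seed for the replicate.
#' @param design a [TaskDesign-class]; default is [makeWmTaskDesign()] with
#'   `designSeed`.
#' @param baseContrast contrast vector (default `c(1, -1, 0)`).
#' @param designSeed seed of the shared default design.
#' @param text mask word.
#' @return a [SimulatedDataset-class]; `params` records every input.
#' @export
simulateToy2D <- function(dims = c(100, 400), rho = 0.03, delta = 0, phi = 0,
                          noiseKind = c("gaussian", "ar1"), seed = NULL,
                          design = NULL, baseContrast = c(1, -1, 0),
                          designSeed = 1, text = "kernel") {
  noiseKind <- match.arg(noiseKind)
  if (noiseKind == "gaussian" && phi != 0)
    stop("gaussian noise requires phi = 0 (use noiseKind = 'ar1')")
  if (noiseKind == "ar1" && phi == 0)
    noiseKind <- "gaussian"
  if (is.null(design)) design <- makeWmTaskDesign(seed = designSeed)
  X <- buildDesignMatrix(design)
  xEff <- as.numeric(effectiveDesign(X, baseContrast))
  mask <- makeWordMask(dims, text = text)
  seeds <- seedStreams(seed, 2)
  noise <- genNoise(design@nTime, prod(dims), phi = phi, seed = seeds[[1]])
  xAdd <- genAddedSignal(X, baseContrast, delta = delta, seed = seeds[[2]])
  sim <- assembleSimulation(noise, rho, xAdd, mask, X = X, xEff = xEff,
                            tr = design@tr,
                            params = list(delta = delta, phi = phi,
                                          noiseKind = noiseKind, seed = seed,
                                          designSeed = designSeed,
                                          baseContrast = baseContrast,
                                          dims = dims, text = text,
                                          subSeeds = seeds))
  sim
}

#' Calibrate the signal strength against the GLM baseline
#'
#' Iterative calibration: starting from `rho = 0.1`, regenerate the dataset,
#' evaluate the detector (by default the GLM partial AUC at FPR < 0.1 against
#' the ground truth), and step `rho` by +0.005 while the partial AUC is below
#' 0.035 or -0.005 while above 0.05, stopping inside the band. Each step
#' regenerates the data with a fresh sub-seed.
#'
#' @param generator function `(rho, seed) -> SimulatedDataset`.
#' @param detector function `SimulatedDataset -> partial AUC`; `NULL` uses
#'   the GLM baseline with the default FWHM.
#' @param rhoInit starting signal strength.
#' @param band target partial-AUC band.
#' @param step rho increment.
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   trajectory.
#' @param seed master seed (split into one sub-seed per iteration).
#' @return the calibrated rho, with attribute "trajectory" (data.frame of
#'   rho and partial AUC per iteration).
#' @export
tuneRho <- function(generator, detector = NULL, rhoInit = 0.1,
                    band = c(0.035, 0.05), step = 0.005, maxIter = 100,
                    seed = NULL) {
  if (is.null(detector)) {
    detector <- function(sim) {
      g <- glmMap(sim@dataset, sim@xEff, absolute = TRUE)
      partialAUC(rocCurve(alphaValues(g), sim@truthMask), 0.1)
    }
  }
  seeds <- seedStreams(seed, maxIter)
  rho <- rhoInit
  traj <- data.frame(rho = numeric(0), pauc = numeric(0))
  for (i in seq_len(maxIter)) {
    sim <- generator(rho, seeds[[i]])
    pauc <- detector(sim)
    traj <- rbind(traj, data.frame(rho = rho, pauc = pauc))
    if (pauc < band[1]) {
      rho <- rho + step
    } else if (pauc > band[2]) {
      rho <- rho - step
    } else {
      attr(rho, "trajectory") <- traj
      return(rho)
    }
    if (rho <= 0) stop("rho calibration drove rho to zero; trajectory:\n",
                       paste(utils::capture.output(print(traj)), collapse = "\n"))
  }
  stop("rho calibration did not converge in ", maxIter, " iterations; trajectory:\n",
       paste(utils::capture.output(print(traj)), collapse = "\n"))
}
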