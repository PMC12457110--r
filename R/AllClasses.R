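#' @import methods
#' @importFrom Matrix sparseMatrix t
#' @importFrom stats cor quantile rnorm runif sd var
NULL

## Central S4 containers. Geometry is a plain list shared by several classes:
##   dims    - integer grid extents (H x W for 2D, X x Y x Z for 3D)
##   maskIdx - sorted linear indices of in-mask voxels (columns of the data)
## Q = length(maskIdx) always equals ncol of the time x voxel matrix.

validGeometry <- function(g) {
  if (!is.list(g) || is.null(g$dims) || is.null(g$maskIdx))
    return("geometry must be a list with elements 'dims' and 'maskIdx'")
  d <- g$dims
  if (!(length(d) %in% c(2L, 3L)) || any(d < 1))
    return("geometry$dims must have length 2 or 3 with positive extents")
  m <- g$maskIdx
  if (length(m) < 1 || any(m < 1) || any(m > prod(d)))
    return("geometry$maskIdx out of range for the grid")
  if (is.unsorted(m, strictly = TRUE))
    return("geometry$maskIdx must be strictly increasing")
  TRUE
}

#' Grid geometry descriptor
#'
#' Builds the geometry list used by [FmriDataset-class]: grid extents plus the
#' linear indices of in-mask voxels (the voxel-to-column map).
#'
#' @param dims integer vector of grid extents, length 2 (H, W) or 3 (X, Y, Z).
#' @param mask optional logical array/vector over the full grid; `NULL` keeps
#'   every grid cell in the mask.
#' @return a list with elements `dims` and `maskIdx`.
#' @export
gridGeometry <- function(dims, mask = NULL) {
  dims <- as.integer(dims)
  if (is.null(mask)) {
    maskIdx <- seq_len(prod(dims))
  } else {
    mask <- as.logical(mask)
    if (length(mask) != prod(dims))
      stop("mask length does not match grid size")
    maskIdx <- which(mask)
  }
  g <- list(dims = dims, maskIdx = as.integer(maskIdx))
  msg <- validGeometry(g)
  if (!isTRUE(msg)) stop(msg)
  g
}

#' FmriDataset: time-by-voxel fMRI data with grid geometry
#'
#' Holds a `T x Q` real matrix of (typically standardized) fMRI time series,
#' the grid geometry mapping columns to voxels, the voxel size, the repetition
#' time, and an optional gray-matter indicator over the in-mask voxels.
#'
#' @slot data numeric matrix, time points in rows, voxels in columns.
#' @slot geometry list from [gridGeometry()].
#' @slot voxelSize numeric, physical units per axis (pixels in 2D, mm in 3D).
#' @slot tr numeric, seconds per frame.
#' @slot grayMask logical vector of length Q (or length 0 when absent).
#' @export
setClass("FmriDataset", representation(
  data = "matrix", geometry = "list", voxelSize = "numeric",
  tr = "numeric", grayMask = "logical"
), validity = function(object) {
  msg <- validGeometry(object@geometry)
  if (!isTRUE(msg)) return(msg)
  if (!is.numeric(object@data)) return("data must be numeric")
  if (!all(is.finite(object@data))) return("data must be finite")
  Q <- length(object@geometry$maskIdx)
  if (ncol(object@data) != Q)
    return(sprintf("ncol(data) = %d but mask has %d voxels", ncol(object@data), Q))
  if (length(object@voxelSize) != length(object@geometry$dims))
    return("voxelSize must have one entry per grid axis")
  if (length(object@tr) != 1 || object@tr <= 0) return("tr must be a positive scalar")
  if (length(object@grayMask) > 0 && length(object@grayMask) != Q)
    return("grayMask must have length Q (or 0)")
  TRUE
})

#' Construct an FmriDataset
#'
#' @param data `T x Q` numeric matrix (or `T x prod(dims)` when `mask` given as
#'   a full-grid array, in which case out-of-mask columns are dropped).
#' @param dims grid extents.
#' @param mask optional full-grid logical mask.
#' @param voxelSize physical units per axis.
#' @param tr repetition time (s/frame).
#' @param grayMask optional logical gray-matter indicator, either over the full
#'   grid or over the in-mask voxels.
#' @param standardize if `TRUE` (default) each voxel time series is rescaled to
#'   temporal mean 0, variance 1; constant voxels are removed from the mask
#'   with a warning.
#' @return an [FmriDataset-class] object.
#' @export
FmriDataset <- function(data, dims, mask = NULL, voxelSize = rep(1, length(dims)),
                        tr = 1, grayMask = NULL, standardize = TRUE) {
  data <- as.matrix(data)
  geom <- gridGeometry(dims, mask)
  if (ncol(data) == prod(as.integer(dims)) &&
      length(geom$maskIdx) != ncol(data)) {
    data <- data[, geom$maskIdx, drop = FALSE]
  }
  if (!is.null(grayMask)) {
    grayMask <- as.logical(grayMask)
    if (length(grayMask) == prod(geom$dims)) grayMask <- grayMask[geom$maskIdx]
  } else grayMask <- logical(0)
  if (standardize) {
    sds <- colSds(data)
    keep <- sds > 0
    if (!all(keep)) {
      warning(sprintf("removing %d constant voxel(s) from the mask", sum(!keep)))
      geom$maskIdx <- geom$maskIdx[keep]
      data <- data[, keep, drop = FALSE]
      if (length(grayMask)) grayMask <- grayMask[keep]
    }
    data <- colStandardize(data)
  }
  new("FmriDataset", data = data, geometry = geom,
      voxelSize = as.numeric(voxelSize), tr = as.numeric(tr),
      grayMask = grayMask)
}

#' TaskDesign: binary condition onset series
#'
#' @slot nTime integer number of frames T.
#' @slot tr seconds per frame.
#' @slot conditions named list of 0/1 integer vectors of length T.
#' @export
setClass("TaskDesign", representation(
  nTime = "integer", tr = "numeric", conditions = "list"
), validity = function(object) {
  if (object@nTime < 1) return("nTime must be positive")
  if (object@tr <= 0) return("tr must be positive")
  if (length(object@conditions) < 1) return("at least one condition required")
  if (is.null(names(object@conditions)) || any(names(object@conditions) == ""))
    return("conditions must be named")
  for (nm in names(object@conditions)) {
    s <- object@conditions[[nm]]
    if (length(s) != object@nTime)
      return(sprintf("condition '%s' has length %d, expected %d", nm, length(s), object@nTime))
    if (!all(s %in% c(0, 1)))
      return(sprintf("condition '%s' must be a 0/1 series", nm))
  }
  if (!any(vapply(object@conditions, function(s) any(s == 1), logical(1))))
    return("at least one condition must contain an event")
  TRUE
})

#' Construct a TaskDesign
#' @param conditions named list of 0/1 event series, all of length `nTime`.
#' @param tr seconds per frame.
#' @param nTime number of frames; defaults to the series length.
#' @return a [TaskDesign-class] object.
#' @export
taskDesign <- function(conditions, tr, nTime = length(conditions[[1]])) {
  new("TaskDesign", nTime = as.integer(nTime), tr = as.numeric(tr),
      conditions = lapply(conditions, function(s) as.integer(round(s))))
}

#' FilterBank: spatial filters whose equal-weight sum is one Gaussian
#'
#' A bank of 2D (7 x 7) or 3D (7 x 7 x 7) spatial filters. For the steerable
#' banks the equal-weight sum of the oriented filters equals, by construction,
#' the single Gaussian filter of the stated FWHM; this invariant is asserted
#' at validity time with tolerance 1e-10.
#'
#' @slot filters list of numeric arrays, one per orientation.
#' @slot labels character orientation names.
#' @slot fwhm full width at half maximum of the equivalent Gaussian, in grid
#'   units (pixels for 2D, voxel-size units for 3D).
#' @slot dim 2 or 3.
#' @slot kind "steerable", "gaussian", or "delta".
#' @export
setClass("FilterBank", representation(
  filters = "list", labels = "character", fwhm = "numeric",
  dim = "integer", kind = "character"
), validity = function(object) {
  n <- length(object@filters)
  if (n < 1) return("empty filter bank")
  if (length(object@labels) != n) return("labels must match filters")
  for (f in object@filters) {
    d <- dim(as.array(f))
    if (length(d) != object@dim) return("filter dimensionality mismatch")
    if (any(d %% 2 == 0)) return("filter support must be odd per axis")
    if (!all(is.finite(f))) return("filter coefficients must be finite")
  }
  if (object@kind %in% c("steerable", "gaussian")) {
    s <- dim(as.array(object@filters[[1]]))[1]
    g <- gaussianFilter(object@fwhm, object@dim, support = s)
    tot <- Reduce(`+`, object@filters)
    if (max(abs(tot - g)) >= 1e-10)
      return("equal-weight filter sum does not match the Gaussian of the stated FWHM")
  }
  TRUE
})

#' FeatureData: spatially transformed data Y-tilde = Y A
#'
#' Stores the feature-space data as one `T x Q` block per filter; the
#' concatenation of the blocks is the `T x P` matrix with P = nfilters * Q.
#'
#' @slot blocks list of `T x Q` matrices, one per filter in the bank.
#' @slot bank the [FilterBank-class] that generated the transform.
#' @slot geometry parent grid geometry.
#' @export
setClass("FeatureData", representation(
  blocks = "list", bank = "FilterBank", geometry = "list"
), validity = function(object) {
  if (length(object@blocks) != length(object@bank@filters))
    return("one block per filter required")
  Q <- length(object@geometry$maskIdx)
  for (b in object@blocks) {
    if (!is.matrix(b) || ncol(b) != Q) return("block dimensions must be T x Q")
    if (!all(is.finite(b))) return("feature data must be finite")
  }
  TRUE
})

#' GramComponents: normalized linear and quadratic Gram structures
#'
#' The building blocks of all six kernels: the linear Gram `G` and the squared
#' pairwise distances `D` of the feature-space rows, each divided by its mean
#' absolute value (off-diagonal entries only for `D`, whose diagonal is
#' structurally zero).
#'
#' @slot G normalized `T x T` linear Gram matrix.
#' @slot D normalized `T x T` squared-distance matrix, zero diagonal.
#' @slot gScale,dScale the positive mean-absolute-value normalizers.
#' @export
setClass("GramComponents", representation(
  G = "matrix", D = "matrix", gScale = "numeric", dScale = "numeric"
), validity = function(object) {
  if (!isTRUE(all.equal(object@G, t(object@G), tolerance = 1e-8)))
    return("G must be symmetric")
  if (!isTRUE(all.equal(object@D, t(object@D), tolerance = 1e-8)))
    return("D must be symmetric")
  if (any(abs(diag(object@D)) > 1e-10)) return("D must have zero diagonal")
  if (min(object@D) < -1e-8) return("D must be nonnegative")
  if (object@gScale <= 0 || object@dScale <= 0) return("scales must be positive")
  TRUE
})

#' KernelSpec: a kernel family with its hyperparameters
#'
#' @slot name one of "linear", "parabolic", "gaussian", "inverse", "tanh",
#'   "mixed_tanh".
#' @slot params named numeric hyperparameters (among b, c, sigma, b1, b2) on
#'   the normalized Gram/distance scale.
#' @export
setClass("KernelSpec", representation(name = "character", params = "numeric"),
  validity = function(object) {
    kn <- object@name
    if (!(kn %in% kernelNames())) return(sprintf("unknown kernel '%s'", kn))
    p <- object@params
    need <- switch(kn, linear = character(0), parabolic = "b",
                   gaussian = "sigma", inverse = "b", tanh = c("b", "c"),
                   mixed_tanh = c("b1", "b2", "c"))
    if (!all(need %in% names(p)))
      return(sprintf("kernel '%s' requires parameters: %s", kn, paste(need, collapse = ", ")))
    if (kn == "gaussian" && p[["sigma"]] <= 0) return("sigma must be positive")
    TRUE
  })

kernelNames <- function() c("linear", "parabolic", "gaussian", "inverse",
                            "tanh", "mixed_tanh")

#' Construct a KernelSpec
#'
#' Defaults, on the normalized Gram/distance scale, seed the hyperparameter
#' grid when no optimization is run: parabolic/inverse `b = 1`, Gaussian
#' `sigma = 1`, tanh `b = 1, c = 0`, mixed tanh `b1 = b2 = 0.5, c = 0`.
#'
#' @param name kernel family name.
#' @param ... named hyperparameter overrides (b, c, sigma, b1, b2).
#' @return a [KernelSpec-class] object.
#' @export
kernelSpec <- function(name = kernelNames(), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    linear = numeric(0),
    parabolic = c(b = 1),
    gaussian = c(sigma = 1),
    inverse = c(b = 1),
    tanh = c(b = 1, c = 0),
    mixed_tanh = c(b1 = 0.5, b2 = 0.5, c = 0))
  ov <- unlist(list(...))
  if (length(ov)) defaults[names(ov)] <- ov
  new("KernelSpec", name = name, params = defaults)
}

#' KernelGram: a normalized T x T kernel matrix
#'
#' The elementwise kernel of Table-style form applied to the normalized Gram
#' components, then divided by its own mean absolute value (`postScale`) so
#' that mean(|K|) = 1.
#'
#' @slot values symmetric `T x T` matrix.
#' @slot spec the generating [KernelSpec-class].
#' @slot postScale the positive post-normalizer.
#' @export
setClass("KernelGram", representation(
  values = "matrix", spec = "KernelSpec", postScale = "numeric"
), validity = function(object) {
  if (!all(is.finite(object@values))) return("kernel matrix must be finite")
  if (!isTRUE(all.equal(object@values, t(object@values), tolerance = 1e-8)))
    return("kernel matrix must be symmetric")
  if (object@postScale <= 0) return("postScale must be positive")
  TRUE
})

#' KccaFit: regularized KCCA solution
#'
#' @slot vX,vY canonical weight vectors of length T.
#' @slot r canonical correlation in [0, 1].
#' @slot gamma the regularization parameter used.
#' @export
setClass("KccaFit", representation(
  vX = "numeric", vY = "numeric", r = "numeric", gamma = "numeric"
), validity = function(object) {
  if (length(object@vX) != length(object@vY)) return("vX and vY must have equal length")
  if (!all(is.finite(object@vY)) || all(object@vY == 0))
    return("vY must be finite and not all zero")
  if (object@gamma < 0) return("gamma must be nonnegative")
  if (object@r < -1e-10 || object@r > 1 + 1e-8) return("r must lie in [0, 1]")
  TRUE
})

#' ActivationMap: signed per-voxel activation with provenance
#'
#' @slot alpha numeric vector of length Q (absolute-valued when `absolute`).
#' @slot sign the correlation sign s applied during back-reconstruction.
#' @slot absolute whether |alpha| was taken.
#' @slot spec generating [KernelSpec-class].
#' @slot gamma regularization used in the fit.
#' @slot geometry parent grid geometry.
#' @export
setClass("ActivationMap", representation(
  alpha = "numeric", sign = "integer", absolute = "logical",
  spec = "KernelSpec", gamma = "numeric", geometry = "list"
), validity = function(object) {
  if (!all(is.finite(object@alpha))) return("alpha must be finite")
  if (length(object@alpha) != length(object@geometry$maskIdx))
    return("alpha length must equal the number of in-mask voxels")
  if (!(object@sign %in% c(-1L, 1L))) return("sign must be -1 or +1")
  if (object@absolute && any(object@alpha < 0))
    return("absolute map must be nonnegative")
  TRUE
})

#' SimulatedDataset: simulation output bundle
#'
#' @slot dataset the standardized [FmriDataset-class].
#' @slot truthMask logical ground-truth activation indicator over voxels.
#' @slot X HRF-convolved design matrix (may be empty for bare assemblies).
#' @slot xEff effective design signal (may be empty).
#' @slot xAdd the standardized added signal of length T.
#' @slot params list of all generating parameters and seeds.
#' @export
setClass("SimulatedDataset", representation(
  dataset = "FmriDataset", truthMask = "logical", X = "matrix",
  xEff = "numeric", xAdd = "numeric", params = "list"
), validity = function(object) {
  Q <- length(object@dataset@geometry$maskIdx)
  if (length(object@truthMask) != Q) return("truthMask must have length Q")
  Tn <- nrow(object@dataset@data)
  if (length(object@xAdd) != Tn) return("xAdd must have length T")
  if (length(object@xEff) > 0 && length(object@xEff) != Tn)
    return("xEff must have length T")
  TRUE
})
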