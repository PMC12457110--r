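#' Accessors for nlkcca classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `fmriData` returns the time-by-voxel matrix, `geometry` the grid geometry
#' list, `nTime`/`nVoxels` the problem sizes, `grayMask`/`truthMask` the voxel
#' indicator vectors, `alphaValues` the per-voxel activation, `kernelValues`
#' the normalized kernel matrix, and `kernelName`/`kernelParams` the kernel
#' provenance.
#'
#' @param x an nlkcca object.
#' @return the corresponding component (matrix, list, or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fmriData", function(x) standardGeneric("fmriData"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("nTime", function(x) standardGeneric("nTime"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("grayMask", function(x) standardGeneric("grayMask"))
#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setGeneric("alphaValues", function(x) standardGeneric("alphaValues"))
#' @rdname accessors
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))
#' @rdname accessors
#' @export
setGeneric("kernelName", function(x) standardGeneric("kernelName"))
#' @rdname accessors
#' @export
setGeneric("kernelParams", function(x) standardGeneric("kernelParams"))
#' @rdname accessors
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))

setMethod("fmriData", "FmriDataset", function(x) x@data)
setMethod("fmriData", "SimulatedDataset", function(x) x@dataset@data)
setMethod("geometry", "FmriDataset", function(x) x@geometry)
setMethod("geometry", "FeatureData", function(x) x@geometry)
setMethod("geometry", "ActivationMap", function(x) x@geometry)
setMethod("geometry", "SimulatedDataset", function(x) x@dataset@geometry)
setMethod("nTime", "FmriDataset", function(x) nrow(x@data))
setMethod("nTime", "TaskDesign", function(x) x@nTime)
setMethod("nTime", "SimulatedDataset", function(x) nrow(x@dataset@data))
setMethod("nVoxels", "FmriDataset", function(x) ncol(x@data))
setMethod("nVoxels", "ActivationMap", function(x) length(x@alpha))
setMethod("nVoxels", "SimulatedDataset", function(x) ncol(x@dataset@data))
setMethod("grayMask", "FmriDataset", function(x) x@grayMask)
setMethod("grayMask", "SimulatedDataset", function(x) x@dataset@grayMask)
setMethod("truthMask", "SimulatedDataset", function(x) x@truthMask)
setMethod("alphaValues", "ActivationMap", function(x) x@alpha)
setMethod("kernelValues", "KernelGram", function(x) x@values)
setMethod("kernelName", "KernelSpec", function(x) x@name)
setMethod("kernelName", "KernelGram", function(x) x@spec@name)
setMethod("kernelName", "ActivationMap", function(x) x@spec@name)
setMethod("kernelParams", "KernelSpec", function(x) x@params)
setMethod("kernelParams", "KernelGram", function(x) x@spec@params)
setMethod("filters", "FilterBank", function(x) x@filters)

setMethod("show", "FmriDataset", function(object) {
  g <- object@geometry
  cat(sprintf("FmriDataset: %d frames x %d voxels (grid %s, TR %.3g s)\n",
              nrow(object@data), ncol(object@data),
              paste(g$dims, collapse = "x"), object@tr))
  if (length(object@grayMask))
    cat(sprintf("  gray-matter mask: %d voxels\n", sum(object@grayMask)))
  invisible(object)
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank: %d %s filter(s), dim %d, FWHM %.3g (%s)\n",
              length(object@filters),
              paste(dim(as.array(object@filters[[1]])), collapse = "x"),
              object@dim, object@fwhm, object@kind))
  invisible(object)
})

setMethod("show", "KernelSpec", function(object) {
  p <- object@params
  cat(sprintf("KernelSpec: %s(%s)\n", object@name,
              if (length(p)) paste(names(p), signif(p, 4), sep = "=", collapse = ", ")
              else ""))
  invisible(object)
})

setMethod("show", "KernelGram", function(object) {
  cat(sprintf("KernelGram: %dx%d, kernel %s, post-scale %.4g\n",
              nrow(object@values), ncol(object@values), object@spec@name,
              object@postScale))
  invisible(object)
})

setMethod("show", "KccaFit", function(object) {
  cat(sprintf("KccaFit: r = %.4f (gamma = %.4g, T = %d)\n",
              object@r, object@gamma, length(object@vY)))
  invisible(object)
})

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d voxels, kernel %s, sign %+d%s\n",
              length(object@alpha), object@spec@name, object@sign,
              if (object@absolute) ", |alpha|" else ""))
  invisible(object)
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d frames x %d voxels, %.1f%% active\n",
              nTime(object), nVoxels(object),
              100 * mean(object@truthMask)))
  invisible(object)
})
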