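## I/O and preprocessing glue: NIfTI and delimited-grid readers/writers,
## high-pass drift removal, and JSON sidecars.

#' Load an fMRI dataset from disk
#'
#' Reads a 4D NIfTI volume (`.nii` / `.nii.gz`) or the package's delimited 2D
#' grid format, flattens it to a time-by-voxel matrix over the mask, and
#' records the grid geometry and voxel size. The delimited format starts with
#' a header line `#nlkcca2d T=<T> H=<H> W=<W> TR=<tr>` followed by T rows of
#' H*W tab-separated values (column-major voxel order).
#'
#' @param path data file.
#' @param maskPath optional NIfTI/delimited 0/1 brain mask.
#' @param grayPath optional 0/1 gray-matter mask.
#' @param tr repetition time override (s); required if the file metadata
#'   lacks one.
#' @param standardize standardize voxel time series (default TRUE).
#' @return an [FmriDataset-class].
#' @export
loadFmri <- function(path, maskPath = NULL, grayPath = NULL, tr = NULL,
                     standardize = TRUE) {
  readMask <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("\\.nii(\\.gz)?$", p)) as.array(RNifti::readNifti(p)) > 0.5
    else as.matrix(utils::read.table(p)) > 0.5
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 4) stop("expected a 3D/4D NIfTI volume")
    dims <- dim(arr)[1:3]
    is2d <- dims[3] == 1
    if (is2d) dims <- dims[1:2]
    Tn <- dim(arr)[4]
    pix <- RNifti::pixdim(img)
    if (is.null(tr)) {
      tr <- if (length(pix) >= 4 && pix[4] > 0) pix[4] else
        stop("TR missing from NIfTI header (pixdim[4]); pass tr explicitly")
    }
    voxelSize <- pix[seq_along(dims)]
    Y <- t(matrix(arr, prod(dim(arr)[1:3]), Tn))
  } else {
    hdr <- readLines(path, n = 1)
    if (!grepl("^#nlkcca2d", hdr))
      stop("delimited grid file must start with an '#nlkcca2d' header ",
           "naming T, H, W and TR")
    gv <- function(k) {
      m <- regmatches(hdr, regexpr(sprintf("%s=[0-9.eE+-]+", k), hdr))
      if (!length(m)) stop("header missing field ", k)
      as.numeric(sub(".*=", "", m))
    }
    Tn <- gv("T"); dims <- c(gv("H"), gv("W"))
    if (is.null(tr)) tr <- gv("TR")
    Y <- as.matrix(utils::read.table(path, skip = 1))
    if (nrow(Y) != Tn || ncol(Y) != prod(dims))
      stop("data block does not match the header dimensions")
    voxelSize <- c(1, 1)
  }
  mask <- readMask(maskPath)
  gray <- readMask(grayPath)
  dimnames(Y) <- NULL
  FmriDataset(Y, dims = dims, mask = mask, voxelSize = as.numeric(voxelSize),
              tr = tr, grayMask = gray, standardize = standardize)
}

#' Write an fMRI dataset
#'
#' Writes NIfTI for 3D geometries (or on request) and the delimited grid
#' format for 2D, with a JSON sidecar recording geometry, TR, and any extra
#' provenance.
#'
#' @param dataset an [FmriDataset-class] (or [SimulatedDataset-class], whose
#'   truth mask is then written alongside as `<path>.truth`).
#' @param path output file (`.nii.gz` or `.tsv`).
#' @param sidecar extra named entries for the JSON sidecar (written to
#'   `<path>.json`); `NULL` suppresses the sidecar.
#' @return `path`, invisibly.
#' @export
writeFmri <- function(dataset, path, sidecar = list()) {
  truth <- NULL
  if (is(dataset, "SimulatedDataset")) {
    truth <- dataset@truthMask
    sidecar <- c(sidecar, dataset@params[setdiff(names(dataset@params),
                                                 c("tissues", "rhoTrajectory"))])
    dataset <- dataset@dataset
  }
  g <- dataset@geometry
  full <- matrix(0, nrow(dataset@data), prod(g$dims))
  full[, g$maskIdx] <- dataset@data
  if (grepl("\\.nii(\\.gz)?$", path)) {
    dims3 <- if (length(g$dims) == 2) c(g$dims, 1L) else g$dims
    arr <- array(t(full), c(dims3, nrow(dataset@data)))
    img <- RNifti::asNifti(arr)
    pd <- c(dataset@voxelSize, if (length(g$dims) == 2) 1, dataset@tr)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path)
  } else {
    hdr <- sprintf("#nlkcca2d T=%d H=%d W=%d TR=%g", nrow(full),
                   g$dims[1], g$dims[2], dataset@tr)
    writeLines(hdr, path)
    utils::write.table(format(full, digits = 8, trim = TRUE), path,
                       append = TRUE, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth)) {
    tm <- matrix(0L, 1, prod(g$dims))
    tm[g$maskIdx[truth]] <- 1L
    utils::write.table(matrix(tm, g$dims[1]), paste0(path, ".truth"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(sidecar))
    jsonlite::write_json(c(list(dims = g$dims, tr = dataset@tr,
                                nVoxels = ncol(dataset@data)), sidecar),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an activation map
#'
#' 3D maps go to NIfTI; 2D maps to a delimited grid. A JSON sidecar records
#' the kernel spec, gamma, sign and absolute-value flag.
#'
#' @param map an [ActivationMap-class].
#' @param path output file.
#' @param normalize divide by max |alpha| for display (default FALSE; the
#'   map's native scale is arbitrary).
#' @return `path`, invisibly.
#' @export
writeActivationMap <- function(map, path, normalize = FALSE) {
  g <- map@geometry
  a <- map@alpha
  if (normalize && max(abs(a)) > 0) a <- a / max(abs(a))
  full <- numeric(prod(g$dims))
  full[g$maskIdx] <- a
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(array(full, g$dims)), path)
  } else {
    utils::write.table(matrix(full, g$dims[1]), path, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  p <- map@spec@params
  jsonlite::write_json(list(kernel = map@spec@name, params = as.list(p),
                            gamma = map@gamma, sign = map@sign,
                            absolute = map@absolute, normalized = normalize),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' High-pass temporal filtering by discrete-cosine drift removal
#'
#' Removes slow temporal drift by regressing out the discrete cosine basis
#' functions with frequency below the cutoff (default 1/120 Hz), then
#' re-standardizes every voxel time series.
#'
#' @param dataset an [FmriDataset-class].
#' @param cutoffHz cutoff frequency in Hz; 0 is the identity (up to
#'   re-standardization).
#' @return a filtered [FmriDataset-class].
#' @export
highpass <- function(dataset, cutoffHz = 1 / 120) {
  Tn <- nTime(dataset)
  tr <- dataset@tr
  if (cutoffHz < 0) stop("cutoff must be nonnegative")
  if (cutoffHz > 1 / (2 * tr)) stop("cutoff above the Nyquist frequency")
  nBasis <- floor(2 * Tn * tr * cutoffHz)
  out <- dataset
  if (nBasis >= 1) {
    t0 <- seq_len(Tn) - 0.5
    B <- vapply(seq_len(nBasis), function(k) cos(pi * k * t0 / Tn), numeric(Tn))
    resid <- dataset@data - B %*% qr.solve(B, dataset@data)
    sds <- colSds(resid)
    if (any(sds == 0)) {
      warning("voxel(s) with zero residual variance after filtering; left centred")
      sds[sds == 0] <- 1
    }
    out@data <- sweep(sweep(resid, 2, colMeans(resid), "-"), 2, sds, "/")
  } else {
    out@data <- colStandardize(dataset@data)
  }
  out
}
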