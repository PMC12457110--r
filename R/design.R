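## Design module: canonical HRF, HRF-convolved design matrices, the effective
## design signal for a contrast, and the linear design-side kernel K_X.

#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the canonical HRF used throughout the package: a difference of
#' two gamma densities with response delay 6 s, undershoot delay 16 s, unit
#' dispersions and undershoot ratio 1/6, supported on [0, 32] s. This is the
#' de-facto canonical shape in standard fMRI analysis software.
#'
#' @param timeGrid nonnegative, strictly increasing vector of seconds.
#' @param delay,undershoot peak times (s) of the response and undershoot gamma
#'   components (shape = delay/dispersion).
#' @param dispersionResponse,dispersionUndershoot gamma scale parameters (s).
#' @param ratio response-to-undershoot amplitude ratio; `Inf` (or 0 undershoot
#'   weight via `ratio = Inf`) removes the undershoot term.
#' @param support response length in seconds; amplitudes beyond it are 0.
#' @return numeric vector of HRF amplitudes on `timeGrid` (peak scaled to 1).
#' @examples
#' h <- hrfCanonical(seq(0, 32, by = 0.72))
#' @export
hrfCanonical <- function(timeGrid, delay = 6, undershoot = 16,
                         dispersionResponse = 1, dispersionUndershoot = 1,
                         ratio = 6, support = 32) {
  if (any(timeGrid < 0)) stop("timeGrid must be nonnegative")
  if (length(timeGrid) > 1 && any(diff(timeGrid) <= 0))
    stop("timeGrid must be strictly increasing")
  g1 <- stats::dgamma(timeGrid, shape = delay / dispersionResponse,
                      scale = dispersionResponse)
  g2 <- stats::dgamma(timeGrid, shape = undershoot / dispersionUndershoot,
                      scale = dispersionUndershoot)
  h <- g1 - if (is.finite(ratio) && ratio > 0) g2 / ratio else 0
  h[timeGrid > support] <- 0
  m <- max(abs(h))
  if (m > 0) h <- h / m
  h
}

#' Build an HRF-convolved design matrix
#'
#' Convolves each binary condition series with the HRF (causal, zero initial
#' history) and truncates to T frames, yielding one regressor per condition.
#'
#' @param task a [TaskDesign-class].
#' @param hrf HRF amplitudes sampled at the task TR; defaults to the canonical
#'   double-gamma on a 0..32 s grid at the task TR.
#' @return `T x K` numeric matrix with condition names as column names.
#' @export
buildDesignMatrix <- function(task, hrf = NULL) {
  stopifnot(is(task, "TaskDesign"))
  if (length(task@conditions) == 0) stop("task has no conditions")
  if (is.null(hrf))
    hrf <- hrfCanonical(seq(0, 32, by = task@tr))
  Tn <- task@nTime
  X <- vapply(task@conditions, function(s) {
    if (!any(s == 1)) stop("all-zero condition series is not allowed")
    full <- convolve(as.numeric(s), rev(hrf), type = "open")
    full[seq_len(Tn)]
  }, numeric(Tn))
  colnames(X) <- names(task@conditions)
  if (any(colSds(X) == 0)) stop("design column with zero variance")
  X
}

#' Effective design signal for a contrast
#'
#' Collapses a `T x K` design matrix and a K-row contrast into the single
#' regressor (or `T x m` matrix for an m-column contrast) that carries the
#' contrast effect: `X (X'X)^-1 C [C' (X'X)^-1 C]^-1`.
#'
#' @param X design matrix, `T x K`.
#' @param C contrast vector or `K x m` matrix with at least one nonzero entry.
#' @return `T x m` matrix of class "matrix" (drop to a vector with
#'   `drop = TRUE` downstream); attribute "contrast" stores C.
#' @export
effectiveDesign <- function(X, C) {
  X <- as.matrix(X)
  C <- as.matrix(C)
  if (nrow(C) != ncol(X))
    stop("contrast must have one row per design column")
  if (all(C == 0)) stop("contrast must have a nonzero entry")
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("rank-deficient design: X'X is (near-)singular")
  XtXinvC <- solve(XtX, C)
  inner <- crossprod(C, XtXinvC)
  if (rcond(as.matrix(inner)) < 1e-12)
    stop("rank-deficient contrast: C'(X'X)^-1 C is (near-)singular")
  out <- X %*% XtXinvC %*% solve(inner)
  attr(out, "contrast") <- C
  out
}

#' Linear design-side kernel
#'
#' Maps the effective design into the linear kernel space:
#' `K_X = X_eff X_eff'`, a symmetric PSD `T x T` matrix of rank at most the
#' number of contrast columns.
#'
#' @param xEff effective design signal (length-T vector or `T x m` matrix).
#' @return symmetric `T x T` matrix.
#' @export
designKernel <- function(xEff) {
  xEff <- as.matrix(xEff)
  if (!all(is.finite(xEff))) stop("xEff must be finite")
  tcrossprod(xEff)
}

#' Read a task onset table
#'
#' Reads a tab-separated onset table with columns `condition`, `onset_s`,
#' `duration_s` and converts it to binary frame series at the dataset TR.
#'
#' @param path TSV file path.
#' @param nTime number of frames T.
#' @param tr seconds per frame.
#' @return a [TaskDesign-class].
#' @export
readOnsets <- function(path, nTime, tr) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "onset_s", "duration_s")
  if (!all(need %in% names(tab)))
    stop("onset table must have columns: ", paste(need, collapse = ", "))
  onsetsToDesign(tab, nTime, tr)
}

## Shared converter: onset rows -> binary frame series.
onsetsToDesign <- function(tab, nTime, tr) {
  frameTimes <- (seq_len(nTime) - 1) * tr
  eps <- tr * 1e-6        # guards against rounding of onsets written as text
  conds <- lapply(split(tab, tab$condition), function(rows) {
    s <- integer(nTime)
    for (k in seq_len(nrow(rows))) {
      on <- rows$onset_s[k]
      s[frameTimes >= on - eps & frameTimes < on + rows$duration_s[k] - eps] <- 1L
    }
    s
  })
  ## condition (and hence design-column) order follows first appearance in
  ## the table, so contrasts refer to a predictable order
  conds <- conds[unique(tab$condition)]
  taskDesign(conds, tr = tr, nTime = nTime)
}
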