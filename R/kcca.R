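## KCCA module: the regularized two-view kernel CCA objective and its solver.
## The design-side kernel K_X = X_eff X_eff' is rank one for a single-column
## contrast, which admits an exact closed form; a generalized-eigenproblem
## path covers arbitrary PSD K_X.

#' Regularized canonical correlation objective
#'
#' Evaluates
#' `r = vX' KX KY vY / sqrt(vX'(KX^2 + g KX)vX * vY'(KY^2 + g KY)vY)`.
#'
#' @param KX,KY symmetric `T x T` kernel matrices.
#' @param vX,vY weight vectors of length T.
#' @param gamma nonnegative regularization parameter.
#' @return the (signed) correlation value.
#' @export
canonicalCorrelation <- function(KX, KY, vX, vY, gamma = 0) {
  if (gamma < 0) stop("gamma must be nonnegative")
  KXv <- KX %*% vX
  KYv <- KY %*% vY
  denX <- sum(KXv^2) + gamma * sum(vX * KXv)
  denY <- sum(KYv^2) + gamma * sum(vY * KYv)
  if (denX <= 0 || denY <= 0)
    stop("degenerate direction: zero or negative regularized denominator")
  as.numeric(crossprod(KXv, KYv)) / sqrt(denX * denY)
}

## Pseudo-inverse action helper: given the eigendecomposition of a symmetric
## K, returns U diag(w) U' x with w = f(lambda) and a relative floor on the
## magnitude of the regularized eigenvalues.
pinvApply <- function(U, w, x) as.numeric(U %*% (w * crossprod(U, x)))

#' Solve the regularized KCCA problem
#'
#' Finds the leading canonical pair maximizing the regularized correlation.
#' For rank-one `K_X = x x'` (the single-contrast case) the solution is
#' closed-form: `vY` is proportional to `(KY^2 + g KY)^+ KY x` (pseudo-inverse
#' via eigendecomposition with a relative magnitude floor of `1e-10 |KY|^2` on
#' the regularized eigenvalues, which tolerates indefinite tanh kernels) and
#' `vX = x / ||x||^2`. For general `K_X` the symmetric whitened singular-value
#' formulation of the two-view problem is solved and the leading pair is
#' returned. `vY` is normalized so that `||KY vY|| = 1`; its sign is left
#' unconstrained (the activation sign is determined downstream).
#'
#' @param KX design-side kernel (`T x T`), or the result of [designKernel()].
#' @param KY a [KernelGram-class] or a symmetric `T x T` matrix.
#' @param gamma nonnegative regularization; default `0.1 * mean(diag(KY))`.
#' @param xEff optional effective design signal; when supplied, the rank-one
#'   closed form is used directly with `x = xEff`.
#' @param method "auto" (rank-one shortcut when applicable), or force the
#'   "rank1" closed form / "general" whitened-SVD path.
#' @return a [KccaFit-class].
#' @export
kccaSolve <- function(KX, KY, gamma = NULL, xEff = NULL,
                      method = c("auto", "rank1", "general")) {
  method <- match.arg(method)
  KYm <- if (is(KY, "KernelGram")) KY@values else as.matrix(KY)
  if (is.null(gamma)) gamma <- 0.1 * mean(diag(KYm))
  if (gamma < 0) stop("gamma must be nonnegative")
  Tn <- nrow(KYm)

  x <- NULL
  if (!is.null(xEff) && method != "general") {
    x <- as.numeric(xEff)
    if (all(x == 0)) stop("all-zero effective design")
    KX <- tcrossprod(x)
  } else {
    if (!is.null(xEff)) KX <- tcrossprod(as.numeric(xEff))
    KX <- as.matrix(KX)
    ex <- eigen((KX + t(KX)) / 2, symmetric = TRUE)
    if (ex$values[1] <= 0) stop("all-zero or non-PSD design kernel")
    if (method != "general" &&
        (Tn == 1 || ex$values[2] <= 1e-10 * ex$values[1]))
      x <- ex$vectors[, 1] * sqrt(ex$values[1])
    if (method == "rank1" && is.null(x))
      stop("rank1 method requested but the design kernel is not rank one")
  }

  ey <- eigen((KYm + t(KYm)) / 2, symmetric = TRUE)
  lam <- ey$values
  reg <- lam^2 + gamma * lam
  floorv <- 1e-10 * max(abs(lam))^2
  wInv <- ifelse(reg > floorv, 1 / reg, 0)   # components below the floor (incl. negative) are dropped

  if (!is.null(x)) {
    ## rank-one closed form: vY prop. (KY^2 + g KY)^+ KY x
    KYx <- as.numeric(KYm %*% x)
    vY <- pinvApply(ey$vectors, wInv, KYx)
    if (all(vY == 0)) stop("degenerate direction: KY x lies in the null space of KY")
    vX <- x / sum(x^2)
  } else {
    ## general PSD K_X: whitened SVD formulation
    ex <- eigen(KX, symmetric = TRUE)
    regx <- ex$values^2 + gamma * ex$values
    floorx <- 1e-10 * max(abs(ex$values))^2
    wxInvSqrt <- wyInvSqrt <- numeric(Tn)
    okx <- regx > floorx; oky <- reg > floorv
    wxInvSqrt[okx] <- 1 / sqrt(regx[okx])
    wyInvSqrt[oky] <- 1 / sqrt(reg[oky])
    WX <- ex$vectors %*% (wxInvSqrt * t(ex$vectors))
    WY <- ey$vectors %*% (wyInvSqrt * t(ey$vectors))
    M <- WX %*% KX %*% KYm %*% WY
    sv <- svd(M, nu = 1, nv = 1)
    vX <- as.numeric(WX %*% sv$u[, 1])
    vY <- as.numeric(WY %*% sv$v[, 1])
  }

  nrm <- sqrt(sum((KYm %*% vY)^2))
  if (nrm > 0) vY <- vY / nrm
  r <- canonicalCorrelation(KX, KYm, vX, vY, gamma)
  if (r < 0) { vY <- -vY; r <- -r }
  new("KccaFit", vX = vX, vY = vY, r = min(r, 1), gamma = gamma)
}
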