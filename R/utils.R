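## Internal numerical helpers.

colSds <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  sqrt(pmax(0, colSums(M^2) / n - mu^2) * n / (n - 1))
}

## Column-wise standardization to mean 0, variance 1 (sample variance).
## Constant columns are left centred at 0 (caller decides how to treat them).
colStandardize <- function(M) {
  M <- sweep(M, 2, colMeans(M), "-")
  s <- colSds(M)
  s[s == 0] <- 1
  sweep(M, 2, s, "/")
}

stdVector <- function(x) {
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop("cannot standardize a constant vector")
  x / s
}

## Split a master seed into n independent sub-stream seeds (< 2^31).
seedStreams <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

## Pearson correlations between a single vector and every column of M.
corVec <- function(x, M, warnConstant = FALSE) {
  x <- x - mean(x)
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("correlation undefined for a constant reference vector")
  Mc <- sweep(M, 2, colMeans(M), "-")
  nm <- sqrt(colSums(Mc^2))
  bad <- nm == 0
  if (any(bad) && warnConstant)
    warning(sprintf("%d constant column(s); correlation set to 0", sum(bad)))
  nm[bad] <- 1
  r <- as.numeric(crossprod(x, Mc)) / (nx * nm)
  r[bad] <- 0
  r
}
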