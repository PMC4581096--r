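#' Shrinkage estimate of the covariance matrix
#'
#' Schafer-Strimmer-style shrinkage of the empirical correlation matrix
#' toward the identity (unit-correlation diagonal target), with the optimal
#' intensity computed analytically from the Ledoit-Wolf lemma:
#' \deqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) / \sum_{i \ne j} r_{ij}^2,}
#' clamped to [0, 1]. Off-diagonal correlations are multiplied by
#' \eqn{1 - \lambda^*} and recombined with the (unbiased) empirical
#' variances. For any \eqn{\lambda^* > 0} the result is positive definite
#' and hence invertible, even when variables outnumber observations.
#'
#' @param x numeric matrix, n observations x N variables, n >= 3.
#' @return covariance matrix with attribute `"lambda"` (the shrinkage
#'   intensity actually used).
#' @examples
#' x <- matrix(rnorm(50 * 5), 50, 5)
#' cv <- shrinkageCovariance(x)
#' attr(cv, "lambda")
#' @export
shrinkageCovariance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3) stop("need at least 3 observations")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance variable(s): ", paste(bad, collapse = ", "))
  }
  xs <- scale(x)                      # standardised: r = crossprod(xs)/(n-1)
  r <- crossprod(xs) / (n - 1)
  # unbiased estimate of Var(r_ij) from the centred products w_kij
  wbar <- r * (n - 1) / n
  sumw2 <- crossprod(xs^2)            # sum_k (xs_ki xs_kj)^2
  varr <- n / (n - 1)^3 * (sumw2 - n * wbar^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom == 0) 1 else sum(varr[off]) / denom
  lambda <- min(1, max(0, lambda))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  sdv <- sqrt(v)
  cv <- rs * (sdv %o% sdv)
  dimnames(cv) <- list(colnames(x), colnames(x))
  attr(cv, "lambda") <- lambda
  cv
}

#' Partial correlations from a covariance matrix
#'
#' Inverts the covariance and scales:
#' \eqn{\rho_{ik} = - C^{-1}_{ik} / \sqrt{C^{-1}_{ii} C^{-1}_{kk}}}.
#' The diagonal is set to 1 by convention (the raw formula gives the
#' uninformative value -1 there); downstream uses ignore the diagonal.
#'
#' @param cov symmetric positive-definite covariance matrix (e.g. from
#'   [shrinkageCovariance()]).
#' @return symmetric matrix of partial correlations, unit diagonal.
#' @export
partialCorrelations <- function(cov) {
  cov <- unclass(cov)
  attr(cov, "lambda") <- NULL
  ci <- tryCatch(chol2inv(chol(cov)), error = function(e)
    stop("covariance matrix is singular or not positive definite; ",
         "apply shrinkage (shrinkageCovariance) first"))
  d <- sqrt(diag(ci))
  rho <- -ci / (d %o% d)
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- dimnames(cov)
  rho
}

#' Rescale partial correlations into the [0, 1] guidance matrix tau
#'
#' Min-max rescaling of the absolute partial correlations over the
#' off-diagonal entries:
#' \deqn{\tau_{ik} = (|\rho_{ik}| - \min|\rho|) / (\max|\rho| - \min|\rho|).}
#' The strongest partial correlation maps to 1 (evidence for an edge), the
#' weakest to 0 (evidence against), 0.5 is uninformative. The diagonal is
#' fixed at 0 and excluded from all downstream sums (self-edges are
#' forbidden in a DAG). The result is symmetric: a graphical Gaussian model
#' carries no direction information, so both orientations of a pair receive
#' identical guidance.
#'
#' @param rho symmetric partial-correlation matrix.
#' @return symmetric matrix with off-diagonal entries in [0, 1], zero
#'   diagonal.
#' @examples
#' rho <- diag(3)
#' rho[1, 2] <- rho[2, 1] <- 0.5
#' rho[1, 3] <- rho[3, 1] <- 0.25
#' rescaleTau(rho)
#' @export
rescaleTau <- function(rho) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop("'rho' must be a square matrix")
  a <- abs(rho)
  off <- row(a) != col(a)
  lo <- min(a[off])
  hi <- max(a[off])
  if (hi == lo)
    stop("all off-diagonal |rho| are equal; tau is undefined ",
         "(consider the uninformative prior tau = 0.5 everywhere)")
  tau <- (a - lo) / (hi - lo)
  diag(tau) <- 0
  tau[!off] <- 0
  dimnames(tau) <- dimnames(rho)
  tau
}

#' GGM guidance matrix straight from data
#'
#' Convenience pipeline: shrinkage covariance, partial correlations, then
#' min-max rescaling to tau.
#'
#' @param x data matrix (observations x variables).
#' @return tau matrix as from [rescaleTau()].
#' @export
ggmTau <- function(x) {
  rescaleTau(partialCorrelations(shrinkageCovariance(x)))
}
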