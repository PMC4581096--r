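#' Simulate linear-Gaussian data from a DAG
#'
#' Each node is drawn, in topological order, from a Normal distribution
#' whose mean is the weighted sum of its parents' values and whose variance
#' is \code{sigma2}: \eqn{X_i \sim N(\sum_k w_{ik} x_k, \sigma^2)}, the sum
#' running over the parents of node \eqn{i}. Parentless nodes have mean 0
#' (the empty sum). This is sampling from the multivariate Gaussian implied
#' by the DAG, so it matches the BGe score's model family exactly.
#'
#' Defaults reproduce the benchmark regime for this class of simulation:
#' a common edge weight of 1, dynamic-noise variance 0.01 and 100
#' observations per data set.
#'
#' @param dag binary adjacency matrix (`dag[i, k] == 1` means edge i -> k).
#' @param nSamples number of observations to draw (default 100).
#' @param weight scalar edge weight applied to every present edge
#'   (default 1), or an NxN numeric matrix of per-edge weights.
#' @param sigma2 noise variance, > 0 (default 0.01).
#' @param seed optional integer seed.
#' @return numeric `nSamples` x N matrix; columns named after the DAG nodes.
#' @examples
#' g <- randomDAG(5, 5, seed = 1)
#' x <- simulateGaussian(g, nSamples = 100, seed = 2)
#' dim(x)
#' @export
simulateGaussian <- function(dag, nSamples = 100, weight = 1,
                             sigma2 = 0.01, seed = NULL) {
  .checkAdjacency(dag, "dag")
  stopifnot(sigma2 > 0, nSamples >= 2)
  n <- nrow(dag)
  w <- if (is.matrix(weight)) {
    stopifnot(all(dim(weight) == dim(dag)))
    weight * dag
  } else dag * weight
  ord <- topologicalOrder(dag)      # errors on cyclic input
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, nSamples, n)
  sd <- sqrt(sigma2)
  for (i in ord) {
    parents <- which(dag[, i] == 1)
    mu <- if (length(parents))
      x[, parents, drop = FALSE] %*% w[parents, i] else 0
    x[, i] <- stats::rnorm(nSamples, mean = mu, sd = sd)
  }
  colnames(x) <- colnames(dag)
  x
}

#' Quantile-normalise each variable to standard-normal quantiles
#'
#' Per column independently, the observed values are replaced by quantiles
#' of the standard normal N(0, 1) according to rank: the value of rank
#' \eqn{r} (smallest = 1) among \eqn{n} becomes
#' \eqn{\Phi^{-1}((r - 0.5)/n)}. Ranks of tied values are averaged, so ties
#' map to a common quantile. The transform preserves rank order and always
#' yields finite values; a constant column (all values tied) maps entirely
#' to the median quantile 0, with a warning.
#'
#' Intended for data whose marginals are not Gaussian (e.g. output of
#' nonlinear ODE simulators or raw measurements) before BGe scoring.
#'
#' @param x numeric matrix, observations in rows, variables in columns;
#'   at least 2 rows.
#' @return matrix of the same shape with standard-normal-quantile entries.
#' @examples
#' x <- matrix(rexp(300), 100, 3)
#' q <- quantileNormalize(x)
#' round(colMeans(q), 3)
#' @export
quantileNormalize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations per variable")
  if (!all(is.finite(x))) stop("input must be finite")
  n <- nrow(x)
  out <- apply(x, 2, function(col) {
    if (length(unique(col)) == 1L) {
      warning("constant column: all values map to the median quantile 0")
      return(rep(0, n))
    }
    r <- rank(col, ties.method = "average")
    stats::qnorm((r - 0.5) / n)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Read / write expression-style data matrices
#'
#' Delimited text with observations in rows and a header row of variable
#' labels. Separator is auto-detected (comma vs whitespace/tab) on read.
#'
#' @param file path.
#' @return numeric matrix with column names.
#' @export
readExpressionMatrix <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  m <- as.matrix(utils::read.table(file, sep = sep, header = TRUE,
                                   check.names = FALSE))
  if (!is.numeric(m)) stop("non-numeric entries in data matrix")
  if (!all(is.finite(m))) stop("non-finite entries in data matrix")
  m
}

#' @rdname readExpressionMatrix
#' @param x numeric matrix to write.
#' @param sep field separator (default tab).
#' @export
writeExpressionMatrix <- function(x, file, sep = "\t") {
  utils::write.table(x, file, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}
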