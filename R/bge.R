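#' BGe marginal likelihood
#'
#' The BGe score is the closed-form marginal likelihood
#' \eqn{P(D | G) = \int P(D | q, G) P(q | G) dq} of a Gaussian Bayesian
#' network under a Gaussian-inverse-Wishart parameter prior. It decomposes
#' over nodes: the graph score is the sum of local scores, one per
#' (node, parent-set) pair, each a ratio of set-marginal likelihoods. The
#' score is "likelihood equivalent": all DAGs in one Markov-equivalence
#' class receive identical scores.
#'
#' @name bge-score
NULL

# Precompute the sufficient statistics shared by all local scores on one
# data set: the posterior scale matrix R = T0 + S_n + k (xbar-mu0)(xbar-mu0)'
# with k = n*alphaMu/(n+alphaMu), plus constants.
.bgePrecompute <- function(x, hyper) {
  x <- as.matrix(x)
  n <- nrow(x)
  N <- ncol(x)
  stopifnot(length(hyper@mu0) == N, n >= 1)
  xbar <- colMeans(x)
  xc <- sweep(x, 2, xbar)
  s <- crossprod(xc)
  d <- xbar - hyper@mu0
  rmat <- hyper@t0 + s + (n * hyper@alphaMu / (n + hyper@alphaMu)) * (d %o% d)
  list(r = rmat, t0 = hyper@t0, n = n, N = N,
       alphaMu = hyper@alphaMu, alphaW = hyper@alphaW,
       labels = colnames(x))
}

# log multivariate gamma function Gamma_l(a)
.lmvgamma <- function(a, l) {
  if (l == 0) return(0)
  l * (l - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(l)) / 2))
}

.logdetSub <- function(m, idx) {
  if (length(idx) == 0) return(0)
  if (length(idx) == 1) return(log(m[idx, idx]))
  ch <- tryCatch(chol(m[idx, idx, drop = FALSE]), error = function(e)
    stop("posterior scale submatrix not positive definite ",
         "(numerical failure in BGe score)"))
  2 * sum(log(diag(ch)))
}

# log marginal likelihood of the data restricted to variable set Y
.logMarginalSet <- function(idx, pre) {
  l <- length(idx)
  if (l == 0) return(0)
  n <- pre$n
  N <- pre$N
  aw <- pre$alphaW
  am <- pre$alphaMu
  -n * l / 2 * log(pi) + l / 2 * log(am / (am + n)) +
    .lmvgamma((aw + n - N + l) / 2, l) - .lmvgamma((aw - N + l) / 2, l) +
    ((aw - N + l) / 2) * .logdetSub(pre$t0, idx) -
    ((aw + n - N + l) / 2) * .logdetSub(pre$r, idx)
}

#' Local BGe score of one node given a parent set
#'
#' @param node column index of the child variable.
#' @param parents integer vector of parent column indices (possibly empty).
#' @param x data matrix (observations x variables).
#' @param hyper a [BGeHyperparams-class] object (default constructed from
#'   `x`).
#' @param cache optional score cache from [newScoreCache()]; consulted and
#'   updated.
#' @return finite log local score (log of the marginal-likelihood factor
#'   for this node).
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' localBGe(1, c(2, 3), x)
#' @export
localBGe <- function(node, parents, x, hyper = bgeHyperparams(x),
                     cache = NULL) {
  parents <- as.integer(parents)
  node <- as.integer(node)
  if (node %in% parents) stop("a node cannot be its own parent")
  pre <- .bgePrecompute(x, hyper)
  .localBGe(node, parents, pre, cache)
}

# internal hot path: precomputed stats, optional environment cache
.localBGe <- function(node, parents, pre, cache = NULL) {
  if (!is.null(cache)) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- .logMarginalSet(c(parents, node), pre) -
    .logMarginalSet(parents, pre)
  if (!is.finite(val)) stop("non-finite local BGe score for node ", node)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Create an empty local-score cache
#'
#' A hashed environment mapping (node, parent-set) keys to log local
#' scores; values are bit-identical to recomputation. One cache is valid
#' for one (data set, hyperparameter) pair.
#'
#' @return an environment usable as the `cache` argument of [localBGe()]
#'   and [graphLogScore()].
#' @export
newScoreCache <- function() new.env(hash = TRUE, parent = emptyenv())

#' Log BGe score of a whole DAG
#'
#' Sum over nodes of the local scores given each node's parent set in the
#' graph: \eqn{\log P(D|G) = \sum_i \log s(i, \pi_i[G])}.
#'
#' @param dag binary adjacency matrix (`dag[i, k] == 1`: edge i -> k).
#' @inheritParams localBGe
#' @return log marginal likelihood of the data given the DAG.
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' g <- randomDAG(3, 2, seed = 1)
#' graphLogScore(g, x)
#' @export
graphLogScore <- function(dag, x, hyper = bgeHyperparams(x),
                          cache = NULL) {
  .checkAdjacency(dag, "dag")
  if (!isAcyclic(dag)) stop("'dag' contains a cycle")
  pre <- .bgePrecompute(x, hyper)
  sum(vapply(seq_len(ncol(x)), function(i)
    .localBGe(i, which(dag[, i] == 1), pre, cache), numeric(1)))
}
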