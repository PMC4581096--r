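#' @import methods
NULL

#' BGe score hyperparameters
#'
#' Parameters of the Gaussian-inverse-Wishart parameter prior behind the
#' BGe marginal likelihood: prior mean vector \code{mu0}, mean-precision
#' weight \code{alphaMu} (> 0), Wishart degrees of freedom \code{alphaW}
#' (> N + 1) and the positive-definite parametric prior scale matrix
#' \code{t0}.
#'
#' @slot mu0 numeric N-vector, prior mean.
#' @slot alphaMu positive scalar, equivalent sample size for the mean.
#' @slot alphaW scalar > N + 1, Wishart degrees of freedom.
#' @slot t0 N x N symmetric positive-definite prior scale matrix.
#' @seealso [bgeHyperparams()]
#' @export
setClass("BGeHyperparams",
  representation(mu0 = "numeric", alphaMu = "numeric",
                 alphaW = "numeric", t0 = "matrix"))

setValidity("BGeHyperparams", function(object) {
  n <- length(object@mu0)
  msg <- character(0)
  if (length(object@alphaMu) != 1 || object@alphaMu <= 0)
    msg <- c(msg, "alphaMu must be a single positive number")
  if (length(object@alphaW) != 1 || object@alphaW <= n + 1)
    msg <- c(msg, "alphaW must exceed N + 1")
  if (!all(dim(object@t0) == c(n, n)))
    msg <- c(msg, "t0 must be N x N")
  else {
    if (max(abs(object@t0 - t(object@t0))) > 1e-8)
      msg <- c(msg, "t0 must be symmetric")
    ev <- tryCatch(min(eigen(object@t0, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -Inf)
    if (ev <= 0) msg <- c(msg, "t0 must be positive definite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct BGe hyperparameters for a data set
#'
#' Defaults follow the standard weak, proper, score-equivalence-preserving
#' construction: \code{mu0} = the column means of the data, \code{alphaMu}
#' = 1, \code{alphaW} = N + 2, and \code{t0} = t I with
#' \code{t = alphaMu * (alphaW - N - 1) / (alphaMu + 1)}, the scaled
#' identity that makes the implied prior marginal variance of each variable
#' equal 1.
#'
#' @param x data matrix (observations x variables), used for its dimension
#'   and column means.
#' @param mu0 prior mean vector (default column means of `x`).
#' @param alphaMu mean-precision weight (default 1).
#' @param alphaW Wishart degrees of freedom (default N + 2).
#' @param t0Scale scalar multiplier of the identity prior scale matrix
#'   (default the equivalent-sample-size value above).
#' @param t0 full prior scale matrix, overriding `t0Scale`.
#' @return a [BGeHyperparams-class] object.
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' bgeHyperparams(x)
#' @export
bgeHyperparams <- function(x, mu0 = colMeans(x), alphaMu = 1,
                           alphaW = ncol(x) + 2, t0Scale = NULL,
                           t0 = NULL) {
  n <- ncol(x)
  if (is.null(t0)) {
    if (is.null(t0Scale))
      t0Scale <- alphaMu * (alphaW - n - 1) / (alphaMu + 1)
    t0 <- diag(t0Scale, n)
  }
  new("BGeHyperparams", mu0 = as.numeric(mu0), alphaMu = alphaMu,
      alphaW = alphaW, t0 = t0)
}

setMethod("show", "BGeHyperparams", function(object) {
  n <- length(object@mu0)
  cat("BGeHyperparams for N =", n, "variables\n")
  cat("  alphaMu =", object@alphaMu, " alphaW =", object@alphaW, "\n")
  cat("  t0: ", if (isTRUE(all.equal(object@t0,
                                     diag(object@t0[1, 1], n))))
    paste0(format(object@t0[1, 1], digits = 4), " * I")
    else "full matrix", "\n")
})

#' MCMC chain trace
#'
#' Thinned record of a structure-MCMC run: sampled adjacency matrices, the
#' inverse-temperature trace, the log marginal-likelihood trace and the
#' prior-energy trace, plus per-move-type acceptance counts and the run
#' configuration.
#'
#' @slot adjacency integer N x N x S array of sampled adjacency matrices.
#' @slot beta numeric length-S inverse-temperature trace (all zero in
#'   `"bn"` mode).
#' @slot logScore numeric length-S log BGe score trace.
#' @slot energy numeric length-S prior energy trace (zero in `"bn"` mode).
#' @slot step integer length-S MCMC step index of each stored sample.
#' @slot acceptance named list of proposed/accepted counts per move type.
#' @slot config named list: mode, nSteps, thin, burnInFraction, seed,
#'   beta bounds and proposal half-width.
#' @seealso [runChain()], [edgePosterior()]
#' @export
setClass("ChainTrace",
  representation(adjacency = "array", beta = "numeric",
                 logScore = "numeric", energy = "numeric",
                 step = "integer", acceptance = "list", config = "list"))

setValidity("ChainTrace", function(object) {
  d <- dim(object@adjacency)
  s <- length(object@step)
  msg <- character(0)
  if (length(d) != 3 || d[1] != d[2])
    msg <- c(msg, "adjacency must be an N x N x S array")
  else if (d[3] != s)
    msg <- c(msg, "adjacency sample count must match step length")
  for (sl in c("beta", "logScore", "energy"))
    if (length(slot(object, sl)) != s)
      msg <- c(msg, paste(sl, "trace length must match step length"))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChainTrace", function(object) {
  d <- dim(object@adjacency)
  cfg <- object@config
  cat("ChainTrace:", d[3], "samples of", d[1], "nodes",
      sprintf("(mode = %s, %d steps, thin %d)\n",
              cfg$mode, cfg$nSteps, cfg$thin))
  cat("  final log score:", format(utils::tail(object@logScore, 1)), "\n")
  if (cfg$mode == "bnggm")
    cat("  beta range: [", format(min(object@beta), digits = 3), ",",
        format(max(object@beta), digits = 3), "]\n")
  acc <- vapply(object@acceptance, function(a)
    if (a[["proposed"]] > 0) a[["accepted"]] / a[["proposed"]] else NA_real_,
    numeric(1))
  cat("  acceptance rates:",
      paste(names(acc), format(acc, digits = 2), collapse = ", "), "\n")
})

#' @describeIn ChainTrace-class number of stored samples.
#' @param x,object a `ChainTrace`.
#' @export
traceLength <- function(x) length(x@step)

#' @describeIn ChainTrace-class the N x N x S array of sampled adjacencies.
#' @export
adjacencySamples <- function(x) x@adjacency

#' @describeIn ChainTrace-class inverse-temperature trace.
#' @export
betaTrace <- function(x) x@beta

#' @describeIn ChainTrace-class log BGe score trace.
#' @export
scoreTrace <- function(x) x@logScore

#' @describeIn ChainTrace-class prior energy trace.
#' @export
energyTrace <- function(x) x@energy

#' @describeIn ChainTrace-class MCMC step index of each stored sample.
#' @export
sampleSteps <- function(x) x@step

#' @describeIn ChainTrace-class run configuration list.
#' @export
traceConfig <- function(x) x@config
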