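#' Structure-MCMC samplers
#'
#' Metropolis-Hastings random walks in DAG space with single-edge
#' add/delete/reverse proposals. In `"bn"` mode the structure prior is
#' flat. In `"bnggm"` mode the prior is the Gibbs distribution
#' \eqn{P(G | \beta) = e^{-\beta E(G)} / Z(\beta)} whose energy
#' \eqn{E(G) = \sum_{i \ne k} |\tau_{ik} - g_{ik}|} measures the mismatch
#' between the graph and the GGM guidance matrix tau, and whose
#' inverse-temperature hyperparameter \eqn{\beta} is sampled in a second
#' sub-move using an edge-factorised upper bound on the partition function.
#'
#' @name samplers
NULL

# Given adjacency A and its reflexive reachability R, the three validity
# masks. Adding i->k is valid iff no path k => i exists. In a DAG, a path
# i => k of length >= 2 never uses the edge i->k itself (that would close a
# cycle), so reversing i->k is valid iff (A %*% R)[i, k] counts only the
# direct edge.
.moveMasks <- function(adj, reach) {
  p <- adj %*% reach
  list(add = adj == 0 & t(reach) == 0,
       del = adj == 1,
       rev = adj == 1 & p == 1)
}

#' Enumerate the single-edge neighbourhood of a DAG
#'
#' All acyclicity-preserving single-edge additions, all deletions, and all
#' acyclicity-preserving reversals.
#'
#' @param dag binary adjacency matrix of a DAG.
#' @return data frame with columns `type` ("add", "delete", "reverse"),
#'   `from`, `to` (node indices of the affected edge).
#' @examples
#' g <- matrix(0, 2, 2)
#' neighborhoodMoves(g)  # the two possible additions
#' @export
neighborhoodMoves <- function(dag) {
  .checkAdjacency(dag, "dag")
  if (!isAcyclic(dag)) stop("'dag' contains a cycle")
  m <- .moveMasks(dag, .reachability(dag))
  out <- do.call(rbind, lapply(c("add", "del", "rev"), function(ty) {
    w <- which(m[[ty]], arr.ind = TRUE)
    if (nrow(w) == 0) return(NULL)
    data.frame(type = c(add = "add", del = "delete", rev = "reverse")[[ty]],
               from = w[, 1], to = w[, 2], row.names = NULL)
  }))
  if (is.null(out))
    out <- data.frame(type = character(0), from = integer(0),
                      to = integer(0))
  out
}

.neighborhoodSize <- function(adj, reach = .reachability(adj)) {
  m <- .moveMasks(adj, reach)
  sum(m$add) + sum(m$del) + sum(m$rev)
}

#' Energy of a network relative to the guidance matrix
#'
#' \eqn{E(G) = \sum_{i \ne k} |\tau_{ik} - g_{ik}|} over ordered
#' off-diagonal pairs. Zero iff the adjacency reproduces tau exactly;
#' graphs similar to the GGM guidance have low energy.
#'
#' @param dag binary adjacency matrix.
#' @param tau guidance matrix from [rescaleTau()] (entries in [0, 1], zero
#'   diagonal).
#' @return non-negative scalar.
#' @export
networkEnergy <- function(dag, tau) {
  if (!all(dim(dag) == dim(tau)))
    stop("'dag' and 'tau' must have the same dimensions")
  off <- row(dag) != col(dag)
  sum(abs(tau[off] - dag[off]))
}

# stable elementwise log(exp(-b*t) + exp(-b*(1-t))) summed over the
# off-diagonal tau entries
.logZbound <- function(tauOff, beta) {
  a <- -beta * tauOff
  b <- -beta * (1 - tauOff)
  m <- pmax(a, b)
  sum(m + log1p(exp(pmin(a, b) - m)))
}

#' Edge-factorised upper bound on the log partition function
#'
#' The Gibbs-prior normaliser \eqn{Z(\beta) = \sum_G e^{-\beta E(G)}} sums
#' over all DAGs, which is super-exponential. Relaxing acyclicity so every
#' directed graph is admitted factorises the sum over ordered node pairs:
#' \deqn{\log Z_{bound}(\beta) = \sum_{i \ne k}
#'   \log(e^{-\beta \tau_{ik}} + e^{-\beta |\tau_{ik} - 1|}),}
#' a polynomial-time upper bound on the true partition function, exact at
#' N = 2 where no multi-edge cycle constraint bites beyond the pairwise
#' one. Computed in log space; stable for any beta in the prior's support.
#'
#' @param tau guidance matrix (zero diagonal).
#' @param beta inverse temperature, >= 0.
#' @return scalar log upper bound.
#' @examples
#' tau <- matrix(0.3, 3, 3); diag(tau) <- 0
#' logPartitionBound(tau, 0) == 6 * log(2)
#' @export
logPartitionBound <- function(tau, beta) {
  stopifnot(beta >= 0)
  off <- row(tau) != col(tau)
  .logZbound(tau[off], beta)
}

#' Symmetric reflected-uniform proposal for beta
#'
#' Proposes beta' uniform on `[beta - halfWidth, beta + halfWidth]`,
#' reflected at the prior bounds so the proposal density stays symmetric
#' (R(beta'|beta) = R(beta|beta')) and the proposal never leaves the
#' support.
#'
#' @param beta current value, inside `bounds`.
#' @param halfWidth proposal half-width (> 0).
#' @param bounds length-2 numeric, the support of the uniform prior on
#'   beta (default `c(0, 30)`).
#' @return proposed value inside `bounds`.
#' @export
proposeBeta <- function(beta, halfWidth = 0.5, bounds = c(0, 30)) {
  stopifnot(halfWidth > 0, beta >= bounds[1], beta <= bounds[2])
  b <- beta + stats::runif(1, -halfWidth, halfWidth)
  while (b < bounds[1] || b > bounds[2]) {
    if (b < bounds[1]) b <- 2 * bounds[1] - b
    if (b > bounds[2]) b <- 2 * bounds[2] - b
  }
  b
}

#' One Metropolis-Hastings beta sub-move
#'
#' With the structure fixed, proposes beta' from the symmetric reflected
#' proposal and accepts with probability
#' \deqn{\min\{ e^{-E(G)(\beta' - \beta)} Z(\beta)/Z(\beta'), 1 \},}
#' the uniform prior on beta cancelling; Z is the edge-factorised bound
#' ([logPartitionBound()]), used consistently in numerator and denominator.
#' All arithmetic in log space.
#'
#' @param beta current inverse temperature.
#' @param energy current graph energy E(G).
#' @param tau guidance matrix.
#' @param halfWidth proposal half-width.
#' @param bounds beta prior support.
#' @return list with `beta` (new value), `accepted` (logical) and
#'   `proposal` (the proposed value).
#' @export
betaMove <- function(beta, energy, tau, halfWidth = 0.5,
                     bounds = c(0, 30)) {
  off <- row(tau) != col(tau)
  tauOff <- tau[off]
  b2 <- proposeBeta(beta, halfWidth, bounds)
  logA <- -energy * (b2 - beta) +
    .logZbound(tauOff, beta) - .logZbound(tauOff, b2)
  acc <- log(stats::runif(1)) < logA
  list(beta = if (acc) b2 else beta, accepted = acc, proposal = b2)
}

# apply a move to an adjacency matrix (no validity check)
.applyMove <- function(adj, type, i, k) {
  if (type == 1L) adj[i, k] <- 1L            # add
  else if (type == 2L) adj[i, k] <- 0L       # delete
  else { adj[i, k] <- 0L; adj[k, i] <- 1L }  # reverse
  adj
}

#' Run a structure-MCMC chain
#'
#' Metropolis-Hastings sampling of DAGs scored by the BGe marginal
#' likelihood. Each step proposes uniformly from the acyclicity-valid
#' single-edge neighbourhood and accepts with probability
#' \eqn{\min\{1, e^{\Delta \log P(D|G) + \Delta \log P(G)} |N(G)|/|N(G')|\}};
#' the Hastings factor corrects for unequal neighbourhood sizes. In
#' `"bnggm"` mode the prior term is \eqn{-\beta \Delta E} and every step
#' additionally performs one beta sub-move ([betaMove()]). The chain
#' starts from the empty graph unless `initDag` says otherwise; beta
#' starts from a uniform draw on its prior support unless `betaInit` is
#' given.
#'
#' @param x data matrix (observations x variables).
#' @param mode `"bn"` (flat structure prior) or `"bnggm"` (GGM-guided
#'   Gibbs prior; requires `tau`).
#' @param tau guidance matrix from [rescaleTau()]/[ggmTau()].
#' @param nSteps number of MCMC steps (default 1e4).
#' @param thin store every `thin`-th step (default 10).
#' @param burnInFraction fraction of the run treated as burn-in by
#'   downstream summaries (default 0.5); recorded in the trace config.
#' @param hyper BGe hyperparameters (default [bgeHyperparams()] of `x`).
#' @param betaBounds support of the uniform prior on beta (default
#'   `c(0, 30)`).
#' @param betaHalfWidth beta proposal half-width (default 0.5).
#' @param betaInit initial beta (default: uniform draw from `betaBounds`).
#' @param sampleBeta if `FALSE`, beta is held fixed at its initial value
#'   (no beta sub-moves); useful for conditional runs.
#' @param initDag optional starting adjacency matrix (default: the empty
#'   graph). Convergence diagnostics compare chains started from
#'   different initialisations.
#' @param seed optional integer seed.
#' @return a [ChainTrace-class] object.
#' @examples
#' g <- randomDAG(4, 4, seed = 1)
#' x <- simulateGaussian(g, nSamples = 100, seed = 2)
#' tr <- runChain(x, mode = "bn", nSteps = 500, thin = 10, seed = 3)
#' tr
#' @export
runChain <- function(x, mode = c("bn", "bnggm"), tau = NULL,
                     nSteps = 10000, thin = 10, burnInFraction = 0.5,
                     hyper = bgeHyperparams(x), betaBounds = c(0, 30),
                     betaHalfWidth = 0.5, betaInit = NULL,
                     sampleBeta = TRUE, initDag = NULL, seed = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  nNodes <- ncol(x)
  stopifnot(nSteps >= 1, thin >= 1, burnInFraction > 0, burnInFraction < 1,
            nNodes >= 2)
  if (mode == "bnggm") {
    if (is.null(tau)) stop("mode 'bnggm' requires a tau matrix")
    if (!all(dim(tau) == c(nNodes, nNodes)))
      stop("tau dimensions do not match the data")
    off <- row(tau) != col(tau)
    tauOff <- tau[off]
  }
  if (!is.null(seed)) set.seed(seed)

  pre <- .bgePrecompute(x, hyper)
  cache <- newScoreCache()
  if (is.null(initDag)) {
    adj <- matrix(0L, nNodes, nNodes)
  } else {
    .checkAdjacency(initDag, "initDag")
    if (!isAcyclic(initDag)) stop("'initDag' contains a cycle")
    adj <- initDag
    storage.mode(adj) <- "integer"
    dimnames(adj) <- NULL
  }
  local <- vapply(seq_len(nNodes), function(i)
    .localBGe(i, which(adj[, i] == 1), pre, cache), numeric(1))
  logScore <- sum(local)
  if (mode == "bnggm") {
    beta <- if (is.null(betaInit))
      stats::runif(1, betaBounds[1], betaBounds[2]) else betaInit
    energy <- networkEnergy(adj, tau)
  } else {
    beta <- 0
    energy <- 0
  }

  nOut <- nSteps %/% thin
  outAdj <- array(0L, c(nNodes, nNodes, nOut))
  outBeta <- numeric(nOut)
  outScore <- numeric(nOut)
  outEnergy <- numeric(nOut)
  outStep <- integer(nOut)
  counts <- list(add = c(proposed = 0, accepted = 0),
                 delete = c(proposed = 0, accepted = 0),
                 reverse = c(proposed = 0, accepted = 0),
                 beta = c(proposed = 0, accepted = 0))

  reach <- .reachability(adj)
  nN <- .neighborhoodSize(adj, reach)
  iOut <- 0L
  for (step in seq_len(nSteps)) {
    ## --- structure sub-move ---
    masks <- .moveMasks(adj, reach)
    nAdd <- sum(masks$add); nDel <- sum(masks$del); nRev <- sum(masks$rev)
    nN <- nAdd + nDel + nRev
    u <- sample.int(nN, 1L)
    if (u <= nAdd) {
      type <- 1L; lin <- which(masks$add)[u]
    } else if (u <= nAdd + nDel) {
      type <- 2L; lin <- which(masks$del)[u - nAdd]
    } else {
      type <- 3L; lin <- which(masks$rev)[u - nAdd - nDel]
    }
    i <- (lin - 1L) %% nNodes + 1L
    k <- (lin - 1L) %/% nNodes + 1L
    adj2 <- .applyMove(adj, type, i, k)
    reach2 <- .reachability(adj2)
    nN2 <- .neighborhoodSize(adj2, reach2)

    if (type == 3L) {
      newLocK <- .localBGe(k, which(adj2[, k] == 1), pre, cache)
      newLocI <- .localBGe(i, which(adj2[, i] == 1), pre, cache)
      dScore <- (newLocK - local[k]) + (newLocI - local[i])
    } else {
      newLocK <- .localBGe(k, which(adj2[, k] == 1), pre, cache)
      dScore <- newLocK - local[k]
    }
    dE <- 0
    if (mode == "bnggm") {
      dE <- if (type == 1L) 1 - 2 * tau[i, k]
      else if (type == 2L) 2 * tau[i, k] - 1
      else (2 * tau[i, k] - 1) + (1 - 2 * tau[k, i])
    }
    logA <- dScore - beta * dE + log(nN) - log(nN2)
    tyName <- c("add", "delete", "reverse")[type]
    counts[[tyName]]["proposed"] <- counts[[tyName]]["proposed"] + 1
    if (log(stats::runif(1)) < logA) {
      counts[[tyName]]["accepted"] <- counts[[tyName]]["accepted"] + 1
      adj <- adj2
      reach <- reach2
      local[k] <- newLocK
      if (type == 3L) local[i] <- newLocI
      logScore <- logScore + dScore
      energy <- energy + dE
    }

    ## --- beta sub-move ---
    if (mode == "bnggm" && sampleBeta) {
      b2 <- proposeBeta(beta, betaHalfWidth, betaBounds)
      logAb <- -energy * (b2 - beta) +
        .logZbound(tauOff, beta) - .logZbound(tauOff, b2)
      counts$beta["proposed"] <- counts$beta["proposed"] + 1
      if (log(stats::runif(1)) < logAb) {
        counts$beta["accepted"] <- counts$beta["accepted"] + 1
        beta <- b2
      }
    }

    if (step %% thin == 0L && iOut < nOut) {
      iOut <- iOut + 1L
      outAdj[, , iOut] <- adj
      outBeta[iOut] <- beta
      outScore[iOut] <- logScore
      outEnergy[iOut] <- energy
      outStep[iOut] <- step
    }
  }
  if (!is.finite(logScore)) stop("non-finite score at end of run")
  dimnames(outAdj) <- list(colnames(x), colnames(x), NULL)
  new("ChainTrace", adjacency = outAdj, beta = outBeta,
      logScore = outScore, energy = outEnergy, step = outStep,
      acceptance = counts,
      config = list(mode = mode, nSteps = nSteps, thin = thin,
                    burnInFraction = burnInFraction, seed = seed,
                    betaBounds = betaBounds,
                    betaHalfWidth = betaHalfWidth,
                    sampleBeta = sampleBeta))
}
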