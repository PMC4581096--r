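# Independent oracles used across the suite. Deliberately naive
# implementations that share no code with the package internals.

# cycle detection by depth-first search with colouring
dfsAcyclic <- function(adj) {
  n <- nrow(adj)
  colour <- integer(n)  # 0 white, 1 grey, 2 black
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return()
    colour[v] <<- 1L
    for (w in which(adj[v, ] == 1)) {
      if (colour[w] == 1L) { ok <<- FALSE; return() }
      if (colour[w] == 0L) visit(w)
    }
    colour[v] <<- 2L
  }
  for (v in seq_len(n)) if (colour[v] == 0L) visit(v)
  ok
}

# every directed graph (cyclic ones included) on n nodes
allDirectedGraphs <- function(n) {
  offIdx <- which(row(diag(n)) != col(diag(n)))
  lapply(0:(2^length(offIdx) - 1), function(code) {
    adj <- matrix(0L, n, n)
    adj[offIdx] <- as.integer(intToBits(code))[seq_along(offIdx)]
    adj
  })
}

# DAG enumeration through the DFS oracle
enumDAGsOracle <- function(n) {
  Filter(dfsAcyclic, allDirectedGraphs(n))
}

# Markov-equivalence class key: skeleton + unshielded colliders
equivClassKey <- function(adj) {
  skel <- 1 * ((adj + t(adj)) > 0)
  n <- nrow(adj)
  vs <- character(0)
  for (k in seq_len(n)) {
    pa <- which(adj[, k] == 1)
    if (length(pa) >= 2) {
      cmb <- utils::combn(pa, 2)
      for (c in seq_len(ncol(cmb))) {
        i <- cmb[1, c]; j <- cmb[2, c]
        if (skel[i, j] == 0)
          vs <- c(vs, paste(sort(c(i, j)), k, sep = "-"))
      }
    }
  }
  paste(paste(skel, collapse = ""), paste(sort(vs), collapse = ";"))
}

# AUC by brute-force pair counting (Mann-Whitney, ties count 1/2)
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# partial correlations by regressing out all remaining variables
pcorRegressionOracle <- function(x) {
  n <- ncol(x)
  out <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rest <- setdiff(seq_len(n), c(i, j))
    ri <- if (length(rest)) stats::resid(stats::lm(x[, i] ~ x[, rest]))
      else x[, i] - mean(x[, i])
    rj <- if (length(rest)) stats::resid(stats::lm(x[, j] ~ x[, rest]))
      else x[, j] - mean(x[, j])
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}

# closed-form covariance implied by linear-Gaussian propagation:
# x = B' x + e  =>  Cov = sigma2 * (I - B')^{-1} (I - B)^{-1}
linGaussCovOracle <- function(adj, weight = 1, sigma2 = 0.01) {
  n <- nrow(adj)
  b <- adj * weight
  inv <- solve(diag(n) - t(b))
  sigma2 * inv %*% t(inv)
}

# brute-force Gibbs-prior sum over an explicit graph list
gibbsSumOracle <- function(graphs, tau, beta) {
  sum(vapply(graphs, function(g) {
    off <- row(g) != col(g)
    exp(-beta * sum(abs(tau[off] - g[off])))
  }, numeric(1)))
}

# build a ChainTrace by hand from a list of adjacency matrices
makeTrace <- function(adjList, beta = NULL, logScore = NULL,
                      mode = "bn", thin = 10, burnInFraction = 0.5) {
  s <- length(adjList)
  n <- nrow(adjList[[1]])
  arr <- array(0L, c(n, n, s))
  for (j in seq_len(s)) arr[, , j] <- adjList[[j]]
  if (is.null(beta)) beta <- numeric(s)
  if (is.null(logScore)) logScore <- numeric(s)
  new("ChainTrace", adjacency = arr, beta = beta, logScore = logScore,
      energy = numeric(s), step = as.integer(seq_len(s) * thin),
      acceptance = list(),
      config = list(mode = mode, nSteps = s * thin, thin = thin,
                    burnInFraction = burnInFraction, seed = NULL,
                    betaBounds = c(0, 30), betaHalfWidth = 0.5,
                    sampleBeta = FALSE))
}
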