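test_that("neighbourhood enumeration matches brute force on small graphs", {
  # 2-node empty graph: exactly the two possible additions
  mv <- neighborhoodMoves(matrix(0L, 2, 2))
  expect_equal(nrow(mv), 2)
  expect_setequal(mv$type, "add")

  # complete 3-node chain with shortcut 1->3: reversing 1->2 and 2->3 is
  # legal, reversing 1->3 would close the cycle 3->1->2->3
  g <- matrix(0L, 3, 3)
  g[1, 2] <- g[2, 3] <- g[1, 3] <- 1L
  mv <- neighborhoodMoves(g)
  revs <- mv[mv$type == "reverse", ]
  expect_true(any(revs$from == 1 & revs$to == 2))
  expect_true(any(revs$from == 2 & revs$to == 3))
  expect_false(any(revs$from == 1 & revs$to == 3))

  # against exhaustive single-edge modification + DFS oracle
  applyMoveOracle <- function(adj, type, i, k) {
    if (type == "add") adj[i, k] <- 1L
    else if (type == "delete") adj[i, k] <- 0L
    else { adj[i, k] <- 0L; adj[k, i] <- 1L }
    adj
  }
  for (s in 1:12) {
    adj <- randomDAG(5, sample(0:9, 1), seed = 300 + s)
    mv <- neighborhoodMoves(adj)
    # every listed move yields a DAG differing by exactly that operation
    for (r in seq_len(nrow(mv)))
      expect_true(dfsAcyclic(applyMoveOracle(adj, mv$type[r],
                                             mv$from[r], mv$to[r])))
    # and the count matches brute force over all candidate operations
    n <- nrow(adj)
    cnt <- 0
    for (i in 1:n) for (k in 1:n) {
      if (i == k) next
      if (adj[i, k] == 0 &&
          dfsAcyclic(applyMoveOracle(adj, "add", i, k))) cnt <- cnt + 1
      if (adj[i, k] == 1) {
        cnt <- cnt + 1                               # deletions always legal
        if (dfsAcyclic(applyMoveOracle(adj, "reverse", i, k)))
          cnt <- cnt + 1
      }
    }
    expect_equal(nrow(mv), cnt)
  }
})

test_that("networkEnergy is the L1 mismatch over ordered off-diagonal pairs", {
  tau <- matrix(0, 2, 2)
  tau[1, 2] <- tau[2, 1] <- 0.8
  g <- matrix(0L, 2, 2); g[1, 2] <- 1L
  expect_equal(networkEnergy(g, tau), abs(0.8 - 1) + abs(0.8 - 0))

  # binary tau equal to the adjacency: zero energy
  gb <- randomDAG(4, 3, seed = 1)
  expect_equal(networkEnergy(gb, gb), 0)

  # adding an edge with tau > 0.5 lowers energy; tau < 0.5 raises it
  tau3 <- matrix(0, 3, 3)
  tau3[1, 2] <- 0.9; tau3[2, 1] <- 0.9
  tau3[1, 3] <- 0.2; tau3[3, 1] <- 0.2
  e0 <- networkEnergy(matrix(0L, 3, 3), tau3)
  gHigh <- matrix(0L, 3, 3); gHigh[1, 2] <- 1L
  gLow <- matrix(0L, 3, 3); gLow[1, 3] <- 1L
  expect_lt(networkEnergy(gHigh, tau3), e0)
  expect_gt(networkEnergy(gLow, tau3), e0)

  expect_error(networkEnergy(matrix(0L, 2, 2), matrix(0, 3, 3)),
               "dimensions")
})

test_that("the factorised partition bound is exact at N=2 and bounds the DAG sum at N=3", {
  set.seed(2)
  tau2 <- matrix(0, 2, 2)
  tau2[1, 2] <- 0.7; tau2[2, 1] <- 0.7
  all2 <- allDirectedGraphs(2)     # 4 graphs incl. the 2-cycle
  for (beta in c(0, 1, 5, 30))
    expect_equal(logPartitionBound(tau2, beta),
                 log(gibbsSumOracle(all2, tau2, beta)))

  g3 <- matrix(0L, 3, 3); g3[1, 2] <- g3[2, 3] <- 1L
  x <- simulateGaussian(g3, nSamples = 100, seed = 3)
  tau3 <- ggmTau(x)
  dags3 <- enumDAGsOracle(3)
  for (beta in c(0, 1, 5, 30))
    expect_gte(logPartitionBound(tau3, beta),
               log(gibbsSumOracle(dags3, tau3, beta)))

  # flat limit: every relaxed graph has weight 1
  expect_equal(logPartitionBound(tau3, 0), 6 * log(2))
})

test_that("proposeBeta reflects at the bounds and stays symmetric", {
  set.seed(4)
  draws <- replicate(4000, proposeBeta(15, 1, c(0, 30)))
  expect_true(all(draws >= 14 & draws <= 16))

  draws0 <- replicate(8000, proposeBeta(0.2, 1, c(0, 30)))
  expect_true(all(draws0 >= 0 & draws0 <= 1.2))
  # reflection doubles mass below 0.8: detailed balance of the proposal
  # means density on (0, 0.8) is 1 (two layers of 1/2) and 1/2 above
  pLow <- mean(draws0 < 0.8)
  expect_equal(pLow, 0.8 / 1.0, tolerance = 0.05)

  set.seed(7); a <- proposeBeta(3, 0.5)
  set.seed(7); b <- proposeBeta(3, 0.5)
  expect_identical(a, b)
})

test_that("betaMove leaves the structure's conditional law invariant", {
  # long run at fixed structure: sampled beta matches the quadrature CDF
  # of p(beta | G) on [0, 30] (coarse unit-level version; the acceptance
  # suite runs the full-length check)
  g <- matrix(0L, 3, 3); g[1, 2] <- g[2, 3] <- 1L
  x <- simulateGaussian(g, nSamples = 100, seed = 5)
  tau <- ggmTau(x)
  energy <- networkEnergy(matrix(0L, 3, 3), tau)   # fixed empty graph
  set.seed(6)
  beta <- 15
  keep <- numeric(2000)
  for (i in seq_len(2e4)) {
    beta <- betaMove(beta, energy, tau)$beta
    if (i %% 10 == 0) keep[i / 10] <- beta
  }
  grid <- seq(0, 30, length.out = 3001)
  off <- row(tau) != col(tau)
  ldens <- vapply(grid, function(b)
    -b * energy - logPartitionBound(tau, b), numeric(1))
  dens <- exp(ldens - max(ldens))
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(ecdf(keep)(grid) - cdf))
  expect_lt(ks, 0.1)
})

test_that("runChain is deterministic and respects the thinning schedule", {
  g <- randomDAG(4, 4, seed = 8)
  x <- simulateGaussian(g, nSamples = 50, seed = 9)
  tr <- runChain(x, mode = "bn", nSteps = 1000, thin = 10, seed = 10)
  expect_equal(traceLength(tr), 100)
  expect_equal(sampleSteps(tr), seq.int(10, 1000, by = 10))
  tr2 <- runChain(x, mode = "bn", nSteps = 1000, thin = 10, seed = 10)
  expect_identical(adjacencySamples(tr), adjacencySamples(tr2))
  expect_identical(scoreTrace(tr), scoreTrace(tr2))
})

test_that("every sampled structure is acyclic and caches equal recomputation", {
  g <- randomDAG(5, 6, seed = 11)
  x <- simulateGaussian(g, nSamples = 60, seed = 12)
  tau <- ggmTau(x)
  tr <- runChain(x, mode = "bnggm", tau = tau, nSteps = 1500, thin = 10,
                 seed = 13)
  hyper <- bgeHyperparams(x)
  idx <- c(1, 37, 75, 150)
  for (j in seq_len(traceLength(tr)))
    expect_true(dfsAcyclic(adjacencySamples(tr)[, , j]))
  for (j in idx) {
    adj <- adjacencySamples(tr)[, , j]
    expect_equal(scoreTrace(tr)[j], graphLogScore(adj, x, hyper),
                 tolerance = 1e-9)
    expect_equal(energyTrace(tr)[j], networkEnergy(adj, tau),
                 tolerance = 1e-9)
  }
})

test_that("bnggm with beta clamped at zero reproduces bn exactly", {
  g <- randomDAG(4, 4, seed = 14)
  x <- simulateGaussian(g, nSamples = 50, seed = 15)
  tau <- ggmTau(x)
  a <- runChain(x, mode = "bn", nSteps = 800, thin = 10, seed = 16)
  b <- runChain(x, mode = "bnggm", tau = tau, nSteps = 800, thin = 10,
                seed = 16, betaInit = 0, sampleBeta = FALSE)
  expect_identical(adjacencySamples(a), adjacencySamples(b))
})

test_that("MCMC edge posteriors approach the exact enumeration posterior", {
  g <- matrix(0L, 3, 3); g[1, 2] <- g[2, 3] <- 1L
  x <- simulateGaussian(g, nSamples = 100, seed = 17)
  tr <- runChain(x, mode = "bn", nSteps = 2e4, thin = 10, seed = 18)
  exact <- exactEdgePosterior(x)
  expect_lt(max(abs(edgePosterior(tr) - exact)), 0.05)
})

test_that("a binarised-truth prior at large fixed beta pins the posterior", {
  g <- matrix(0L, 3, 3); g[1, 2] <- g[2, 3] <- 1L
  x <- simulateGaussian(g, nSamples = 100, seed = 19)
  tr <- runChain(x, mode = "bnggm", tau = g + 0, nSteps = 5000, thin = 10,
                 betaInit = 30, sampleBeta = FALSE, seed = 20)
  post <- edgePosterior(tr)
  expect_lt(max(abs(post - g)), 0.1)
})

test_that("runChain honours a custom initial structure", {
  g <- randomDAG(4, 4, seed = 21)
  x <- simulateGaussian(g, nSamples = 50, seed = 22)
  init <- randomDAG(4, 3, seed = 23)
  tr <- runChain(x, mode = "bn", nSteps = 1, thin = 1, initDag = init,
                 seed = 24)
  # after a single step the state differs from the start by at most one
  # edge operation
  expect_lte(sum(abs(adjacencySamples(tr)[, , 1] - unname(init))), 2)
  cyc <- matrix(0L, 4, 4); cyc[1, 2] <- cyc[2, 1] <- 1L
  expect_error(runChain(x, mode = "bn", nSteps = 10, initDag = cyc),
               "cycle")
})

test_that("runChain validates its inputs", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(runChain(x, mode = "bnggm", nSteps = 100), "tau")
  expect_error(runChain(x, mode = "bnggm", tau = matrix(0, 3, 3),
                        nSteps = 100), "dimensions")
})
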