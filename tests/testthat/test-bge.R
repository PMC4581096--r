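# The BGe local score is the log ratio of set-marginal likelihoods under
# the Gaussian-inverse-Wishart prior. The quadrature oracles below
# integrate that marginal likelihood numerically from the generative
# definition (Wishart prior with rate matrix t0 on the precision, df
# adjusted to alphaW - N + l for an l-subset), sharing no code with the
# package's determinant-ratio implementation.

quad1D <- function(xcol, mu0, alphaMu, nu, t0s) {
  gmu <- pracma::gaussLegendre(200, -12, 14)
  gw <- pracma::gaussLegendre(400, 1e-10, 150)
  fv <- outer(seq_along(gmu$x), seq_along(gw$x), function(i, j) {
    m <- gmu$x[i]; w <- gw$x[j]
    lik <- vapply(seq_along(m), function(z)
      sum(dnorm(xcol, m[z], 1 / sqrt(w[z]), log = TRUE)), numeric(1))
    exp(lik) * dnorm(m, mu0, 1 / sqrt(alphaMu * w)) *
      dgamma(w, shape = nu / 2, rate = t0s / 2)
  })
  log(sum((gmu$w %o% gw$w) * fv))
}

# 2-D marginal: mean integrated analytically, precision integrated on a
# Gauss grid over its Cholesky factor
quad2D <- function(x2, mu0, alphaMu, df, t0s) {
  n <- nrow(x2)
  l <- 2
  M <- diag(n) + matrix(1 / alphaMu, n, n)
  ldM <- c(determinant(M)$modulus)
  Xc <- sweep(x2, 2, mu0)
  Q <- t(Xc) %*% solve(M) %*% Xc
  ga <- pracma::gaussLegendre(120, 1e-8, 9)
  gb <- pracma::gaussLegendre(120, -9, 9)
  gc <- pracma::gaussLegendre(120, 1e-8, 9)
  grid <- expand.grid(a = ga$x, b = gb$x, c = gc$x)
  wts <- expand.grid(wa = ga$w, wb = gb$w, wc = gc$w)
  W11 <- grid$a^2; W12 <- grid$a * grid$b; W22 <- grid$b^2 + grid$c^2
  ldW <- 2 * log(grid$a) + 2 * log(grid$c)
  lconstW <- -(df * l / 2) * log(2) - (l * (l - 1) / 4) * log(pi) -
    sum(lgamma((df + 1 - 1:l) / 2)) + (df / 2) * 2 * log(t0s)
  logf <- (-(n * l / 2) * log(2 * pi) - (l / 2) * ldM + (n / 2) * ldW -
             0.5 * (W11 * Q[1, 1] + 2 * W12 * Q[1, 2] + W22 * Q[2, 2])) +
    ((df - l - 1) / 2) * ldW - 0.5 * t0s * (W11 + W22) + lconstW +
    log(4) + 2 * log(grid$a) + log(grid$c)       # Cholesky Jacobian
  log(sum(wts$wa * wts$wb * wts$wc * exp(logf)))
}

test_that("local scores agree with direct numerical integration", {
  skip_if_not_installed("pracma")
  set.seed(1)
  n <- 3; N <- 2
  x <- matrix(rnorm(n * N, 1, 0.8), n, N)
  mu0 <- c(0.2, -0.1)
  hyper <- bgeHyperparams(x, mu0 = mu0)
  t0s <- hyper@t0[1, 1]

  l1 <- localBGe(1, integer(0), x, hyper)
  expect_equal(l1, quad1D(x[, 1], mu0[1], 1, hyper@alphaW - N + 1, t0s),
               tolerance = 1e-4)

  l12 <- l1 + localBGe(2, 1, x, hyper)
  expect_equal(l12, quad2D(x, mu0, 1, hyper@alphaW - N + 2, t0s),
               tolerance = 1e-4)
})

test_that("a single observation scores as the prior-predictive Student-t", {
  x <- matrix(c(0.7, -0.3), 1, 2)
  mu0 <- c(0, 0)
  hyper <- bgeHyperparams(x, mu0 = mu0)
  N <- 2
  nu <- hyper@alphaW - N + 1
  t0s <- hyper@t0[1, 1]
  scale <- sqrt(t0s * (hyper@alphaMu + 1) / (hyper@alphaMu * nu))
  expect_equal(localBGe(1, integer(0), x, hyper),
               dt((x[1, 1] - mu0[1]) / scale, df = nu, log = TRUE) -
                 log(scale))
})

test_that("the score is exchangeable in observations but not in data content", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  hyper <- bgeHyperparams(x, mu0 = c(0, 0, 0))
  s <- localBGe(1, c(2, 3), x, hyper)
  perm <- x[sample(nrow(x)), ]
  expect_equal(localBGe(1, c(2, 3), perm, hyper), s)
  dup <- rbind(x, x[1, ])
  expect_false(isTRUE(all.equal(localBGe(1, c(2, 3), dup, hyper), s)))
})

test_that("two-node likelihood equivalence holds exactly", {
  set.seed(3)
  x <- matrix(rexp(40), 20, 2)   # arbitrary, non-Gaussian data
  hyper <- bgeHyperparams(x)
  expect_equal(localBGe(1, 2, x, hyper) + localBGe(2, integer(0), x, hyper),
               localBGe(2, 1, x, hyper) + localBGe(1, integer(0), x, hyper),
               tolerance = 1e-10)
})

test_that("scores are equal within every 3-node Markov-equivalence class", {
  set.seed(4)
  x <- matrix(rt(300, df = 3), 100, 3)   # arbitrary data
  hyper <- bgeHyperparams(x)
  dags <- enumDAGsOracle(3)
  keys <- vapply(dags, equivClassKey, character(1))
  scores <- vapply(dags, function(g) graphLogScore(g, x, hyper), numeric(1))
  expect_length(unique(keys), 11)
  for (k in unique(keys)) {
    cl <- scores[keys == k]
    expect_lt(max(cl) - min(cl), 1e-8)
  }
})

test_that("the score decomposes over nodes", {
  set.seed(5)
  x <- matrix(rnorm(500), 100, 5)
  hyper <- bgeHyperparams(x)
  g <- randomDAG(5, 6, seed = 6)
  total <- graphLogScore(g, x, hyper)
  locals <- vapply(1:5, function(i)
    localBGe(i, which(g[, i] == 1), x, hyper), numeric(1))
  expect_equal(total, sum(locals))
  # changing one node's parent set changes only that local term
  g2 <- g
  victim <- which(colSums(g) > 0)[1]
  g2[, victim] <- 0
  locals2 <- vapply(1:5, function(i)
    localBGe(i, which(g2[, i] == 1), x, hyper), numeric(1))
  expect_equal(locals2[-victim], locals[-victim])
  expect_false(locals2[victim] == locals[victim])
})

test_that("the generating DAG outscores the empty graph on simulated data", {
  g <- randomDAG(5, 6, seed = 7)
  x <- simulateGaussian(g, nSamples = 100, sigma2 = 0.01, seed = 8)
  expect_gt(graphLogScore(g, x), graphLogScore(matrix(0L, 5, 5), x))
})

test_that("the score cache is bit-identical to recomputation", {
  set.seed(9)
  x <- matrix(rnorm(300), 100, 3)
  hyper <- bgeHyperparams(x)
  cache <- newScoreCache()
  a <- localBGe(2, c(1, 3), x, hyper, cache)
  b <- localBGe(2, c(3, 1), x, hyper, cache)   # same set, cache hit
  expect_identical(a, b)
  expect_identical(a, localBGe(2, c(1, 3), x, hyper))
  expect_error(localBGe(1, 1, x, hyper), "own parent")
})

test_that("graphLogScore rejects cyclic input", {
  x <- matrix(rnorm(30), 10, 3)
  cyc <- matrix(0L, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1L
  expect_error(graphLogScore(cyc, x), "cycle")
})
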