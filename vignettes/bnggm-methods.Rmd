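---
title: "GGM-guided structure MCMC for Gaussian Bayesian networks: models and methods"
author: "bnggm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GGM-guided structure MCMC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnggm)
```

## The inference problem

Given an expression-style data matrix — `n` observations of `N` variables
(genes, proteins) — we want the posterior distribution over directed
acyclic graphs (DAGs) `G` describing which variables regulate which.
Under a Bayesian network, the joint density factorises by the local
Markov property, `P(X_1, ..., X_N) = prod_i P(X_i | X_{pa(i)})`, and
score-based structure learning weighs each DAG by
`P(G | D) ∝ P(D | G) P(G)`.

Because the number of DAGs grows super-exponentially, the posterior is
explored by Metropolis-Hastings structure MCMC. The well-known weakness
of that random walk — single-edge moves mix slowly and get trapped near
local maxima — is the problem this package addresses: a fast, coarse
method (a graphical Gaussian model, GGM) is folded into the structure
prior through a hierarchical model, and the data decide how much that
guidance is trusted.

## Marginal likelihood: the BGe score

`P(D | G)` is the BGe score: the marginal likelihood of a Gaussian DAG
model under a Gaussian-inverse-Wishart parameter prior, integrable in
closed form and *likelihood equivalent* — every DAG in one
Markov-equivalence class scores identically. The graph score decomposes
into per-node local terms; each is a ratio of set-marginal likelihoods
evaluated with Cholesky-based log-determinants (`localBGe()`,
`graphLogScore()`). Sampling re-scores only the one or two nodes a move
touches, and a hashed cache (`newScoreCache()`) makes repeated visits
O(1).

The hyperparameters (`bgeHyperparams()`) follow the standard weak,
proper, equivalence-preserving construction:

* `mu0` — prior mean; default the column means of the data.
* `alphaMu = 1` — equivalent sample size of the mean prior.
* `alphaW = N + 2` — Wishart degrees of freedom, the smallest value
  giving a finite prior covariance.
* `t0 = alphaMu (alphaW - N - 1) / (alphaMu + 1) * I` — prior scale,
  chosen so each variable's implied prior marginal variance is 1.

All are overridable. Absolute score values are hyperparameter-sensitive;
every correctness claim in the package therefore rests on properties
(score equivalence, agreement with direct quadrature of the defining
integral, exchangeability) rather than on particular score values. The
test suite checks the 1-D and 2-D marginal likelihoods against
independent numerical integration of the generative definition, and
score equality within all eleven 3-node equivalence classes.

## The GGM guidance signal

A graphical Gaussian model summarises direct (full-order conditional)
linear dependencies by partial correlations
`rho_ik = -C^{-1}_ik / sqrt(C^{-1}_ii C^{-1}_kk)`. Because inverting an
empirical covariance is unstable (or impossible when `N > n`), the
covariance is estimated by analytic shrinkage
(`shrinkageCovariance()`): off-diagonal correlations are shrunk toward
zero with the intensity that minimises expected squared loss
(`lambda* = sum Var(r_ik) / sum r_ik^2`, clamped to [0, 1]), variances
kept empirical. For any positive intensity the estimate is positive
definite. On pure noise the optimal intensity is 1 — total shrinkage —
which is the estimator working as intended, not a failure mode; in that
regime all partial correlations vanish and the guidance matrix below is
undefined (the error suggests the uninformative fallback `tau = 0.5`).

Only the *strength* of a partial correlation carries structure
information, so `rescaleTau()` maps absolute values affinely onto
[0, 1] over the off-diagonal entries:
`tau_ik = (|rho_ik| - min|rho|) / (max|rho| - min|rho|)`. Values above
0.5 are evidence for an edge between `i` and `k`, below 0.5 against,
0.5 is uninformative. Two conventions are deliberate:

* min and max are taken over off-diagonal entries only, and the
  diagonal of `tau` is fixed at 0 and excluded from every downstream
  sum — the diagonal of the partial-correlation formula is an artefact
  and self-loops are impossible in a DAG; including it would only add a
  constant energy offset that distorts the inverse-temperature moves.
* `tau` is symmetric. A GGM cannot orient edges, so both directions of
  a pair receive identical guidance; this is an inherited limitation of
  the guidance signal, not of the sampler.

## The hierarchical prior and its samplers

The structure prior is a Gibbs distribution
`P(G | beta) = exp(-beta E(G)) / Z(beta)` with energy
`E(G) = sum_{i != k} |tau_ik - g_ik|` (`networkEnergy()`): the L1
mismatch between the candidate adjacency and the guidance. `beta` acts
as an inverse temperature — at `beta = 0` the prior is flat and the
sampler reduces exactly to plain structure MCMC; as `beta` grows the
prior concentrates on minimum-energy structures. Rather than fixing
`beta`, it is given a uniform prior on [0, 30] and sampled, so the
chain itself learns how informative the GGM is for the data at hand.

Each MCMC step performs two sub-moves:

1. **Structure move.** A proposal is drawn uniformly from the
   acyclicity-valid single-edge neighbourhood (additions, deletions,
   reversals; `neighborhoodMoves()`) and accepted with probability
   `min{1, exp(dScore - beta dE) |N(G)| / |N(G')|}`. The Hastings
   factor corrects for unequal neighbourhood sizes; without it the
   small-graph exactness checks against full enumeration fail, so it is
   not optional. Acyclicity is maintained with boolean reachability
   closures; a reversal `i->k` is valid iff the only path `i => k` is
   the edge itself, which in a DAG can be read off `A %*% R` without
   recomputing a closure per candidate.
2. **beta move.** With the structure fixed, a reflected-uniform
   symmetric proposal (`proposeBeta()`, half-width 0.5 by default) is
   accepted with probability
   `min{exp(-E(G)(beta' - beta)) Z(beta) / Z(beta'), 1}`
   (`betaMove()`); the uniform prior cancels.

The partition function `Z(beta)` sums over all DAGs and is intractable,
but admitting *every* directed graph factorises the sum over ordered
pairs into `prod (exp(-beta tau_ik) + exp(-beta |tau_ik - 1|))` — a
polynomial-time upper bound (`logPartitionBound()`), computed in log
space. The same bound is used in the numerator and denominator of the
beta acceptance ratio, so the consistent bias largely cancels. The
bound is exact at `N = 2`; the tests verify both the exactness and the
upper-bound property against brute-force enumeration, and that the
sampled `beta` at fixed structure reproduces the quadrature-computed
conditional density `p(beta | G) ∝ exp(-beta E) / Z_bound(beta)`.

One "MCMC step" is one structure proposal plus (in guided mode) one
beta proposal. The 1:1 interleaving, the 0.5 proposal half-width and
the empty-graph default start are design choices where the method
itself is silent; all are exposed in `runChain()` and recorded in the
trace configuration.

## Simulation protocol and preprocessing

`simulateGaussian()` draws linear-Gaussian data in topological order:
`X_i ~ N(sum_k w_ik x_k, sigma2)` over the parents of `i`, parentless
nodes centred at 0 (the literal empty sum). Defaults are the benchmark
regime: common edge weight `w = 1`, noise variance `sigma2 = 0.01`, 100
observations per data set, 5 replicate data sets in the experiment
grid. This generator matches the BGe model family exactly, which is
what makes it the "easy" reference condition: passing on it shows the
machinery is correct, not that real data — nonlinear, non-Gaussian,
with measurement error — will be recovered equally well. The external
data path (`quantileNormalize()`) replaces each variable's values by
standard-normal quantiles of their ranks, `Phi^{-1}((r - 0.5) / n)`
with tied ranks averaged: finite at the extreme ranks (an endpoint
convention is required, since the naive `j/n` quantile is infinite at
the top rank), symmetric, order-preserving; constant columns map to 0
with a warning.

`randomDAG()` samples a uniform topological order and then the
requested number of order-consistent edges uniformly — a construction
chosen for simplicity and edge-count control, not uniformity over all
labelled DAGs with that edge count.

## Evaluation

`edgePosterior()` averages post-burn-in sampled adjacencies into
marginal edge probabilities. `rocAUC()` sweeps every distinct score as
a threshold and integrates the ROC by trapezoid (ties grouped, i.e.
counted half — identical to the Mann-Whitney statistic, which the tests
verify by brute-force pair counting and against an independent ROC
implementation). Because Markov equivalence leaves some edges
unorientable even with infinite data, the evaluation of recovered
networks treats an undirected call as the superposition of both
directed orientations: with `undirectedTruth = TRUE` the truth is
symmetrised and each ordered pair is scored by the posterior mass of
the pair in either direction. Directed evaluation remains the default
for callers who want orientation accuracy specifically.

Convergence is assessed with two chains per data set started from
different initialisations (the first from the empty graph, the second
from a seeded random DAG at quarter edge density):
`c_rms = sqrt(mean((r_a - r_b)^2 / 2))` over ordered off-diagonal pairs
— the RMS perpendicular spread of the paired-posterior scatter around
the line `y = x`. It is 0 for identical posteriors, bounded by
`1/sqrt(2)`, and symmetric. This precise formula is this package's own
definition (the quantity is usually inspected visually; published
definitions vary by constant factors), and any monotone variant ranks
methods identically, which is the only use made of it.
`aucTrajectory()` and `cRmsTrajectory()` apply the evaluation
prefix-wise — at each thinned step, as if the run had ended there, with
the first half of the prefix discarded — so a single run yields the
full accuracy-versus-length curve.

## The experiment grid

`experimentPlan()` / `runExperiment()` reproduce the benchmark design:
per replicate data set, the guidance `tau` is computed once from that
data set alone (the method needs no side information), then both
samplers run paired chains; summaries report mean and standard
deviation of the prefix AUC across data sets and the paired c_rms
curves, plus a seed manifest from which any single trace can be
recomputed in isolation. Quantile normalisation is applied to external
data only — simulated Gaussian data are already in the model family.
The plan is an R object rather than a configuration file; a thin
command-line wrapper over the individual steps ships in
`inst/scripts/bnggm.R`.

## Numerical choices and degenerate inputs

* All acceptance ratios, scores and partition terms are computed in log
  space; `log1p`/max-factoring keep the partition bound stable at the
  top of the beta range.
* Cholesky factorisation backs every determinant and inversion; a
  non-positive-definite posterior scale raises an error rather than
  propagating NaN.
* Cached local scores and energies are updated incrementally and are
  bit-identical to recomputation (tested at sampled states).
* Degenerate inputs fail loudly with the remedy named: zero-variance
  variables (shrinkage), singular covariance (use shrinkage), all-equal
  partial correlations (uninformative `tau = 0.5` fallback), cyclic
  adjacencies, infeasible edge counts.

## Problem sizes used in the shipped checks

The test-suite and reproduction script sizes were chosen to keep full
runs on a laptop-class single core in the minutes range while retaining
discriminating power: exactness checks run 3-node chains for 1e5 steps
against full 25-DAG enumeration (agreement within 0.03); the beta
conditional check retains 1e4 thinned samples; the benchmark recovery
experiment uses the packaged synthetic 10-node DAG with 5 data sets ×
2 modes × 2 chains × 1e4 steps. At these sizes the guided sampler's
final mean AUC (superposition evaluation) is ≈ 0.96 and its final mean
c_rms is consistently below plain structure MCMC's, the qualitative
signature of the method.

## Known limitations

* The GGM guidance is undirected and cannot distinguish moral edges
  (co-parents) from true edges; with strong guidance this can promote
  co-parent false positives. The sampled `beta` mitigates but does not
  remove this.
* The partition bound over-counts cyclic graphs; its bias grows with
  `beta` and graph size. Since it appears in both sides of the beta
  acceptance ratio the practical effect is a mild distortion of the
  `beta` posterior, not of the structure posterior given `beta`.
* The pure-R sampler is comfortable to ~20 nodes and 1e5 steps;
  larger problems want a compiled inner loop.
* Gaussian simulated data share the scoring model's assumptions;
  performance there is an upper bound on what to expect from ODE-based
  or measured data.
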