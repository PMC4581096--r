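# bnggm — GGM-guided structure MCMC for Gaussian Bayesian networks

Infers gene-regulatory networks from expression-style data
(observations × variables) with Gaussian Bayesian networks. Structures
are scored by the BGe marginal likelihood P(D|G) and sampled by
Metropolis–Hastings structure MCMC (single-edge add/delete/reverse
moves, uniform proposals over the acyclicity-valid neighbourhood with a
Hastings size correction). Plain structure MCMC mixes slowly; the
package's hierarchical sampler speeds convergence by letting a
graphical Gaussian model (GGM) — cheap shrinkage-estimated partial
correlations, min–max rescaled to a guidance matrix τ ∈ [0,1] — shape
the structure prior:

    P(G | β) = exp(−β E(G)) / Z(β),      E(G) = Σ_{i≠k} |τ_ik − g_ik|

The inverse temperature β is not fixed: it carries a uniform prior on
[0, 30] and is sampled in a second Metropolis sub-move, with the
intractable partition function Z(β) replaced by an edge-factorised
polynomial upper bound (acyclicity relaxed), used consistently on both
sides of the acceptance ratio. So the data decide how much the GGM
guidance is trusted. The package also ships the benchmark machinery:
linear-Gaussian simulation from DAGs, quantile normalisation for
non-Gaussian data, exact small-graph enumeration oracles, ROC/AUC edge
evaluation and the two-chain convergence diagnostic c_rms.

## Worked example

```r
library(bnggm)

g   <- benchmarkDAG()                       # packaged 10-node synthetic DAG
x   <- simulateGaussian(g, nSamples = 100, seed = 42)   # w=1, sigma2=0.01
tau <- ggmTau(x)                            # shrinkage GGM -> guidance in [0,1]

bn    <- runChain(x, mode = "bn",                nSteps = 1e4, thin = 10, seed = 101)
bnggm <- runChain(x, mode = "bnggm", tau = tau,  nSteps = 1e4, thin = 10, seed = 101)
bnggm
#> ChainTrace: 1000 samples of 10 nodes (mode = bnggm, 10000 steps, thin 10)
#>   final log score: 596.145
#>   beta range: [ 0.0252 , 9.98 ]
#>   acceptance rates: add 0.80, delete 0.35, reverse 0.84, beta 0.70

rocAUC(edgePosterior(bn),    g, undirectedTruth = TRUE)   # 0.979
rocAUC(edgePosterior(bnggm), g, undirectedTruth = TRUE)   # 0.973
mean(betaTrace(bnggm)[500:1000])                          # 0.83
```

`edgePosterior()` averages the post-burn-in sampled adjacencies into
marginal edge probabilities; `rocAUC(..., undirectedTruth = TRUE)`
scores them against the true network treating an undirected edge as the
superposition of both orientations (the appropriate view when Markov
equivalence leaves edges unorientable — both samplers recover the
skeleton almost perfectly here). The posterior mean of β (~0.8 on this
data set) is the weight the chain itself assigned to the GGM guidance.

The convergence gain shows up across replicate data sets: with
`experimentPlan()` / `runExperiment()` (5 data sets × 2 modes × 2
independently initialised chains × 1e4 steps, the protocol the
defaults encode), the guided sampler's final mean c_rms is consistently
below plain structure MCMC's while mean AUC stays ≥ 0.95 for both —
same answers, reached in fewer steps.

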