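#' Define a simulation-study plan
#'
#' Describes the full benchmark grid: for each of `nDatasets` replicate
#' data sets, both sampling modes are run with `chainsPerDataset`
#' independently seeded chains, and the GGM guidance matrix is computed
#' once per data set from that data set alone. Defaults mirror the
#' standard protocol: 5 replicate data sets of 100 observations each,
#' edge weight 1, noise variance 0.01, 1e4 MCMC steps thinned by 10 with
#' the first half as burn-in, and two chains per mode for convergence
#' diagnostics.
#'
#' @param dag binary true adjacency matrix the data are simulated from
#'   (ignored when `datasets` are supplied).
#' @param nDatasets number of replicate data sets (default 5).
#' @param chainsPerDataset chains per (data set, mode); >= 2 (default 2).
#' @param modes sampling modes to run (default both).
#' @param nSamples observations per data set (default 100).
#' @param weight,sigma2 simulation parameters (defaults 1 and 0.01).
#' @param nSteps,thin,burnInFraction sampler schedule (defaults 1e4, 10,
#'   0.5).
#' @param dataType `"gaussian"` (simulate from `dag`) or `"external"`
#'   (use `datasets`, quantile-normalising each first).
#' @param datasets for `dataType = "external"`: list of data matrices.
#' @param seed master seed; every chain and data set derives its own seed
#'   from it (default 1).
#' @return an `ExperimentPlan` list object.
#' @export
experimentPlan <- function(dag = NULL, nDatasets = 5, chainsPerDataset = 2,
                           modes = c("bn", "bnggm"), nSamples = 100,
                           weight = 1, sigma2 = 0.01, nSteps = 10000,
                           thin = 10, burnInFraction = 0.5,
                           dataType = c("gaussian", "external"),
                           datasets = NULL, seed = 1) {
  dataType <- match.arg(dataType)
  if (chainsPerDataset < 2)
    stop("convergence reporting needs at least 2 chains per data set")
  if (dataType == "gaussian" && is.null(dag))
    stop("gaussian plans need a true 'dag' to simulate from")
  if (dataType == "external") {
    if (is.null(datasets)) stop("external plans need 'datasets'")
    nDatasets <- length(datasets)
  }
  structure(list(dag = dag, nDatasets = nDatasets,
                 chainsPerDataset = chainsPerDataset, modes = modes,
                 nSamples = nSamples, weight = weight, sigma2 = sigma2,
                 nSteps = nSteps, thin = thin,
                 burnInFraction = burnInFraction, dataType = dataType,
                 datasets = datasets, seed = seed),
            class = "ExperimentPlan")
}

# deterministic sub-seed derivation, kept well below 2^31
.subSeed <- function(master, dataset, chain = 0, mode = 0) {
  (master * 7919L + dataset * 104729L + chain * 1299709L +
     mode * 15485863L) %% 2147483647L
}

#' Run the full benchmark experiment
#'
#' Executes the plan: simulates (or normalises) each data set, computes
#' its tau guidance matrix once, runs every (mode, chain) cell, and
#' summarises accuracy (prefix AUC against the truth, when known) and
#' convergence (two-chain c_rms) per step. Following the two-chain
#' diagnostic protocol, the chains of a pair start from different
#' initialisations: the first from the empty graph, later ones from a
#' seeded random DAG at quarter edge density.
#'
#' @param plan an [experimentPlan()] object.
#' @param truth binary true adjacency for evaluation (default: the plan's
#'   `dag`; required for AUC columns).
#' @param undirectedTruth passed to [rocAUC()].
#' @param verbose print progress lines.
#' @return list with elements
#'   \describe{
#'     \item{summary}{data frame: `mode`, `step`, `meanAUC`, `sdAUC`
#'       (across data sets, chains averaged within data set), `meanCrms`,
#'       `sdCrms`.}
#'     \item{report}{per-data-set convergence report (long form, with a
#'       `dataset` column).}
#'     \item{traces}{nested list `[[dataset]][[mode]][[chain]]` of
#'       [ChainTrace-class] objects.}
#'     \item{manifest}{data frame of every cell's derived seed, enough to
#'       recompute any trace alone.}
#'   }
#' @examples
#' \donttest{
#' g <- randomDAG(6, 6, seed = 1)
#' plan <- experimentPlan(g, nDatasets = 2, nSteps = 1000, seed = 7)
#' res <- runExperiment(plan)
#' head(res$summary)
#' }
#' @export
runExperiment <- function(plan, truth = plan$dag, undirectedTruth = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  modes <- plan$modes
  manifest <- NULL
  traces <- vector("list", plan$nDatasets)
  reports <- vector("list", plan$nDatasets)
  for (d in seq_len(plan$nDatasets)) {
    if (plan$dataType == "gaussian") {
      x <- simulateGaussian(plan$dag, nSamples = plan$nSamples,
                            weight = plan$weight, sigma2 = plan$sigma2,
                            seed = .subSeed(plan$seed, d))
    } else {
      x <- quantileNormalize(plan$datasets[[d]])
    }
    tau <- if ("bnggm" %in% modes) ggmTau(x) else NULL
    traces[[d]] <- list()
    for (m in seq_along(modes)) {
      mode <- modes[m]
      traces[[d]][[mode]] <- lapply(seq_len(plan$chainsPerDataset),
        function(ch) {
          sd <- .subSeed(plan$seed, d, ch, m)
          manifest <<- rbind(manifest,
            data.frame(dataset = d, mode = mode, chain = ch, seed = sd))
          if (verbose)
            message("dataset ", d, " mode ", mode, " chain ", ch)
          nv <- ncol(x)
          init <- if (ch == 1) NULL
            else randomDAG(nv, floor(nv * (nv - 1) / 4), seed = sd,
                           labels = colnames(x))
          runChain(x, mode = mode, tau = tau, nSteps = plan$nSteps,
                   thin = plan$thin,
                   burnInFraction = plan$burnInFraction,
                   initDag = init, seed = sd)
        })
    }
    if (!is.null(truth)) {
      pairs <- lapply(traces[[d]], function(tl) tl[1:2])
      rep_d <- convergenceReport(pairs, truth, undirectedTruth)
      rep_d$dataset <- d
      reports[[d]] <- rep_d
    }
  }
  report <- do.call(rbind, reports)
  summary <- NULL
  if (!is.null(report)) {
    report$aucMean <- (report$aucA + report$aucB) / 2
    mAuc <- stats::aggregate(aucMean ~ mode + step, report, mean)
    sAuc <- stats::aggregate(aucMean ~ mode + step, report, stats::sd)
    mCr <- stats::aggregate(crms ~ mode + step, report, mean)
    sCr <- stats::aggregate(crms ~ mode + step, report, stats::sd)
    summary <- data.frame(mode = mAuc$mode, step = mAuc$step,
                          meanAUC = mAuc$aucMean, sdAUC = sAuc$aucMean,
                          meanCrms = mCr$crms, sdCrms = sCr$crms)
    summary <- summary[order(summary$mode, summary$step), ]
    rownames(summary) <- NULL
  }
  list(summary = summary, report = report, traces = traces,
       manifest = manifest)
}

#' Packaged benchmark networks
#'
#' `benchmarkDAG()` returns a fixed synthetic 10-node regulatory-style
#' benchmark DAG (11 edges: a fan-out hub, a cascade and a collider),
#' shipped as a plain-text adjacency matrix. It is a synthetic stand-in
#' constructed for this package, not a published topology.
#'
#' `rafPathwayDAG()` returns an 11-node, 20-edge directed network of the
#' Raf signalling pathway reconstructed from the consensus descriptions in
#' the signalling literature; edge-level details vary between published
#' versions, so treat it as approximate.
#'
#' @return binary adjacency matrix with node labels.
#' @export
benchmarkDAG <- function() {
  readAdjacencyMatrix(system.file("extdata", "benchmark10_synthetic.tsv",
                                  package = "bnggm", mustWork = TRUE))
}

#' @rdname benchmarkDAG
#' @export
rafPathwayDAG <- function() {
  readAdjacencyMatrix(system.file("extdata",
                                  "raf_pathway_reconstructed_edges.tsv",
                                  package = "bnggm", mustWork = TRUE))
}
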