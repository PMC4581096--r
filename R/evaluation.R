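#' Marginal posterior edge probabilities from a trace
#'
#' Element-wise mean of the post-burn-in sampled adjacency matrices: entry
#' (i, k) estimates the marginal posterior probability of the directed
#' edge i -> k.
#'
#' @param trace a [ChainTrace-class].
#' @param burnInFraction fraction of stored samples discarded from the
#'   front (default: the fraction recorded in the trace config, normally
#'   0.5).
#' @return N x N matrix with entries in [0, 1], zero diagonal.
#' @export
edgePosterior <- function(trace, burnInFraction = NULL) {
  if (is.null(burnInFraction))
    burnInFraction <- trace@config$burnInFraction
  s <- traceLength(trace)
  keep <- (floor(s * burnInFraction) + 1L):s
  if (length(keep) < 1 || keep[1] > s)
    stop("no samples remain after burn-in")
  apply(trace@adjacency[, , keep, drop = FALSE], c(1, 2), mean)
}

#' Classify predicted edges against a known network
#'
#' Thresholds the posterior matrix at `epsilon` (an edge is called present
#' when its posterior probability is >= epsilon) and cross-tabulates the
#' calls against the true adjacency over all ordered off-diagonal pairs.
#'
#' @param posterior N x N matrix of edge scores in [0, 1].
#' @param truth binary N x N true adjacency matrix.
#' @param epsilon threshold in [0, 1].
#' @return named integer vector `c(TP, FP, TN, FN)`; sums to N(N-1).
#' @export
classifyEdges <- function(posterior, truth, epsilon) {
  if (!all(dim(posterior) == dim(truth)))
    stop("'posterior' and 'truth' must have the same dimensions")
  stopifnot(epsilon >= 0, epsilon <= 1)
  off <- row(truth) != col(truth)
  a <- posterior[off] >= epsilon
  t <- truth[off] == 1
  c(TP = sum(t & a), FP = sum(!t & a), TN = sum(!t & !a),
    FN = sum(t & !a))
}

#' Area under the ROC curve for edge recovery
#'
#' Sweeps the threshold over every distinct posterior value, plots the
#' true-positive rate against the false-positive rate, and integrates by
#' the trapezoid rule; tied scores are grouped into single threshold steps
#' (equivalent to counting a tie as half a concordant pair). Directed
#' evaluation over ordered off-diagonal pairs; set `undirectedTruth =
#' TRUE` to treat each undirected edge as the superposition of both
#' directed orientations: the truth is symmetrised and each ordered pair
#' is scored by the posterior mass of the pair in either orientation.
#' The superposition view is the appropriate one when Markov equivalence
#' leaves edges unorientable.
#'
#' @param posterior N x N matrix of edge scores.
#' @param truth binary N x N true adjacency matrix, at least one positive
#'   and one negative pair.
#' @param undirectedTruth apply the superposition rule before evaluation.
#' @return AUC in [0, 1]; 1 = perfect ranking, 0.5 = random.
#' @export
rocAUC <- function(posterior, truth, undirectedTruth = FALSE) {
  if (!all(dim(posterior) == dim(truth)))
    stop("'posterior' and 'truth' must have the same dimensions")
  if (undirectedTruth) {
    sp <- .superpose(posterior, truth)
    posterior <- sp$posterior
    truth <- sp$truth
  }
  off <- row(truth) != col(truth)
  .aucVec(posterior[off], truth[off] == 1)
}

# superposition rule: an undirected edge counts as both directed
# orientations, so the truth is symmetrised and each ordered pair is
# scored by the posterior mass of the pair in either direction
# (disjoint events in a DAG, hence the sum)
.superpose <- function(posterior, truth) {
  list(posterior = posterior + t(posterior),
       truth = 1 * ((truth + t(truth)) > 0))
}

# trapezoid AUC over distinct-score thresholds for score vector s and
# logical labels pos
.aucVec <- function(s, pos) {
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("degenerate truth: need at least one positive and one negative")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  pos <- pos[ord]
  # group tied scores into one threshold step each
  grp <- cumsum(!duplicated(s))
  tpByGrp <- tapply(pos, grp, sum)
  fpByGrp <- tapply(!pos, grp, sum)
  tpr <- c(0, cumsum(tpByGrp)) / nPos
  fpr <- c(0, cumsum(fpByGrp)) / nNeg
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' AUC as a function of simulation length
#'
#' For each thinned sample s, the AUC the run would have achieved had it
#' stopped there: the posterior is recomputed from the prefix ending at s
#' with the first half of that prefix discarded as burn-in, then scored
#' against the truth. Uses cumulative sums, so the whole trajectory costs
#' O(S) posterior updates.
#'
#' @param trace a [ChainTrace-class].
#' @param truth binary true adjacency matrix.
#' @param undirectedTruth passed to [rocAUC()].
#' @return data frame with columns `step` and `auc`.
#' @export
aucTrajectory <- function(trace, truth, undirectedTruth = FALSE) {
  post <- .prefixPosteriors(trace)
  auc <- vapply(seq_len(dim(post)[3]), function(s)
    rocAUC(post[, , s], truth, undirectedTruth), numeric(1))
  data.frame(step = trace@step, auc = auc)
}

# prefix-wise posteriors under the halved-burn-in rule: slice s is the mean
# adjacency over stored samples (floor(s/2)+1) .. s
.prefixPosteriors <- function(trace) {
  adj <- trace@adjacency
  s <- dim(adj)[3]
  cs <- aperm(apply(adj, c(1, 2), cumsum), c(2, 3, 1))   # cumsum over slices
  out <- array(0, dim(adj))
  for (j in seq_len(s)) {
    lo <- floor(j / 2)          # discard samples 1..lo
    cnt <- j - lo
    out[, , j] <- if (lo == 0) cs[, , j] / cnt
    else (cs[, , j] - cs[, , lo]) / cnt
  }
  out
}

#' Two-chain convergence RMS
#'
#' Root-mean-square spread of the paired edge posteriors around the line
#' y = x, over ordered off-diagonal pairs:
#' \deqn{c_{rms} = \sqrt{ \mathrm{mean}( (r_a - r_b)^2 / 2 ) },}
#' i.e. the RMS perpendicular distance of the scatter points
#' \eqn{(r_a, r_b)} from the diagonal. Zero iff the two chains' posteriors
#' agree exactly; bounded above by \eqn{1/\sqrt{2}}; symmetric in its
#' arguments. Small values indicate the two independently initialised
#' chains have converged to the same posterior.
#'
#' @param posteriorA,posteriorB edge-posterior matrices of equal shape.
#' @return non-negative scalar.
#' @export
cRms <- function(posteriorA, posteriorB) {
  if (!all(dim(posteriorA) == dim(posteriorB)))
    stop("posterior matrices must have the same dimensions")
  off <- row(posteriorA) != col(posteriorA)
  sqrt(mean((posteriorA[off] - posteriorB[off])^2 / 2))
}

#' c_rms as a function of simulation length
#'
#' Applies the prefix rule of [aucTrajectory()] to two chains run on the
#' same data and returns the convergence RMS at every thinned step.
#'
#' @param traceA,traceB two [ChainTrace-class] objects of equal length on
#'   the same variables.
#' @return data frame with columns `step` and `crms`.
#' @export
cRmsTrajectory <- function(traceA, traceB) {
  if (traceLength(traceA) != traceLength(traceB))
    stop("traces must have equal length")
  pa <- .prefixPosteriors(traceA)
  pb <- .prefixPosteriors(traceB)
  crms <- vapply(seq_len(dim(pa)[3]), function(s)
    cRms(pa[, , s], pb[, , s]), numeric(1))
  data.frame(step = traceA@step, crms = crms)
}

#' Accuracy and convergence report for paired chains
#'
#' For each sampling mode, takes a pair of chains run on the same data
#' from different initialisations and tabulates, per thinned step, the
#' two-chain c_rms and each chain's prefix AUC against the truth.
#'
#' @param tracePairs named list (one element per mode); each element a
#'   list of exactly two [ChainTrace-class] objects.
#' @param truth binary true adjacency matrix.
#' @param undirectedTruth passed to [rocAUC()].
#' @return data frame with columns `mode`, `step`, `crms`, `aucA`, `aucB`.
#' @export
convergenceReport <- function(tracePairs, truth, undirectedTruth = FALSE) {
  out <- lapply(names(tracePairs), function(mode) {
    pair <- tracePairs[[mode]]
    if (length(pair) != 2)
      stop("need exactly two traces per mode (got ", length(pair),
           " for '", mode, "')")
    ca <- pair[[1]]@config
    cb <- pair[[2]]@config
    if (ca$nSteps != cb$nSteps || ca$thin != cb$thin ||
        ca$mode != cb$mode)
      stop("mismatched chain configurations within mode '", mode, "'")
    cr <- cRmsTrajectory(pair[[1]], pair[[2]])
    aa <- aucTrajectory(pair[[1]], truth, undirectedTruth)
    ab <- aucTrajectory(pair[[2]], truth, undirectedTruth)
    data.frame(mode = mode, step = cr$step, crms = cr$crms,
               aucA = aa$auc, aucB = ab$auc)
  })
  do.call(rbind, out)
}
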