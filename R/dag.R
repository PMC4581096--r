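#' DAG utilities
#'
#' Directed graphs are represented throughout the package as square binary
#' adjacency matrices with `adj[i, k] == 1` meaning a directed edge
#' from node `i` to node `k`. Row/column names carry the node labels.
#'
#' @name dag-utils
NULL

.checkAdjacency <- function(adj, arg = "adj") {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("'", arg, "' must be a square matrix")
  if (any(!adj %in% c(0, 1)))
    stop("'", arg, "' must be binary (0/1)")
  if (any(diag(adj) != 0))
    stop("'", arg, "' must have a zero diagonal (no self-loops)")
  invisible(adj)
}

#' Reflexive transitive closure (reachability) of a directed graph
#'
#' Boolean matrix-power closure: entry `[i, k]` is 1 iff `k` is reachable
#' from `i` by a directed path (of length >= 0, so the diagonal is 1).
#'
#' @param adj square binary adjacency matrix.
#' @return binary reachability matrix of the same dimension.
#' @keywords internal
.reachability <- function(adj) {
  n <- nrow(adj)
  r <- adj + diag(n)
  steps <- ceiling(log2(max(n, 2)))
  for (s in seq_len(steps)) {
    r <- r %*% r
    r[r > 0] <- 1
  }
  r
}

#' Test whether a directed graph is acyclic
#'
#' @param adj square binary adjacency matrix.
#' @return `TRUE` if the graph has no directed cycle.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 3] <- 1
#' isAcyclic(a)
#' a[3, 1] <- 1
#' isAcyclic(a)
#' @export
isAcyclic <- function(adj) {
  .checkAdjacency(adj)
  r <- .reachability(adj)
  # a cycle exists iff some edge i->j closes against a path j => i
  !any(diag(adj %*% r) > 0)
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; errors if the graph contains a cycle.
#'
#' @param adj square binary adjacency matrix.
#' @return integer vector of node indices such that every edge points from
#'   an earlier to a later position.
#' @export
topologicalOrder <- function(adj) {
  .checkAdjacency(adj)
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order <- c(order, v)
    children <- which(adj[v, ] == 1)
    for (c in children) {
      indeg[c] <- indeg[c] - 1
      if (!is.na(indeg[c]) && indeg[c] == 0) {
        avail <- c(avail, c)
        indeg[c] <- NA
      }
    }
  }
  if (length(order) < n)
    stop("graph is cyclic: no topological order exists")
  order
}

#' Sample a random labelled DAG with a fixed number of edges
#'
#' Draws a uniformly random topological order of the nodes, then picks
#' `nEdges` of the `choose(nNodes, 2)` order-consistent node pairs uniformly
#' at random and orients each from the earlier to the later node.
#'
#' @param nNodes number of nodes.
#' @param nEdges number of edges; must not exceed `nNodes*(nNodes-1)/2`.
#' @param seed optional integer seed for reproducibility.
#' @param labels optional character vector of node labels
#'   (default `X1..XnNodes`).
#' @return binary adjacency matrix with `nEdges` edges, guaranteed acyclic.
#' @examples
#' g <- randomDAG(5, 6, seed = 1)
#' sum(g)
#' isAcyclic(g)
#' @export
randomDAG <- function(nNodes, nEdges, seed = NULL, labels = NULL) {
  stopifnot(nNodes >= 1, nEdges >= 0)
  maxE <- nNodes * (nNodes - 1) / 2
  if (nEdges > maxE)
    stop("nEdges = ", nEdges, " exceeds the maximum ", maxE,
         " for an acyclic graph on ", nNodes, " nodes")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("X", seq_len(nNodes))
  ord <- sample.int(nNodes)
  adj <- matrix(0L, nNodes, nNodes, dimnames = list(labels, labels))
  if (nEdges > 0) {
    pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), nEdges), , drop = FALSE]
    # positions in the sampled order -> node indices
    adj[cbind(ord[pick[, 1]], ord[pick[, 2]])] <- 1L
  }
  adj
}

#' Read an adjacency matrix from delimited text or an edge list
#'
#' Accepts either a labelled square matrix (whitespace- or comma-delimited,
#' header row of node labels) or a two-column `source<TAB>target` edge list.
#' The format is detected from the first line.
#'
#' @param file path to the file.
#' @param labels for edge-list input, optional full node-label set (so that
#'   isolated nodes are representable); ignored for matrix input.
#' @return binary adjacency matrix with dimnames.
#' @export
readAdjacencyMatrix <- function(file, labels = NULL) {
  first <- readLines(file, n = 1L)
  nfields <- length(strsplit(trimws(first), "[,\t ]+")[[1]])
  if (nfields == 2 && !grepl(",", first)) {
    el <- utils::read.table(file, sep = "\t", header = FALSE,
                            col.names = c("source", "target"),
                            colClasses = "character")
    if (is.null(labels)) labels <- sort(unique(c(el$source, el$target)))
    adj <- matrix(0L, length(labels), length(labels),
                  dimnames = list(labels, labels))
    adj[cbind(match(el$source, labels), match(el$target, labels))] <- 1L
  } else {
    sep <- if (grepl(",", first)) "," else ""
    m <- utils::read.table(file, sep = sep, header = TRUE,
                           check.names = FALSE)
    adj <- as.matrix(m)
    storage.mode(adj) <- "integer"
    rownames(adj) <- colnames(adj)
  }
  .checkAdjacency(adj, "file contents")
  adj
}

#' Write an adjacency matrix as labelled delimited text
#'
#' @param adj binary adjacency matrix.
#' @param file output path.
#' @param sep field separator (default tab).
#' @export
writeAdjacencyMatrix <- function(adj, file, sep = "\t") {
  .checkAdjacency(adj)
  utils::write.table(adj, file, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}
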