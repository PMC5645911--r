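# canonical rooted-binary representation of an unrooted topology:
# unroot, then root on the edge leading to the alphabetically first tip
.rootAtTip <- function(tree) {
  tree <- ape::unroot(tree)
  tip <- sort(tree$tip.label)[1]
  tr <- ape::root(tree, outgroup = tip, resolve.root = TRUE)
  ape::reorder.phylo(tr, "cladewise")
}

# internal edges of the underlying unrooted topology: edges (p, v) with v
# internal and p not the root
.internalEdges <- function(tree) {
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  which(tree$edge[, 2] > nTip & tree$edge[, 1] != root)
}

.swapClades <- function(tree, n1, n2) {
  e <- tree$edge
  i1 <- which(e[, 2] == n1); i2 <- which(e[, 2] == n2)
  p1 <- e[i1, 1]; p2 <- e[i2, 1]
  e[i1, 1] <- p2; e[i2, 1] <- p1
  tree$edge <- e
  ape::reorder.phylo(tree, "cladewise")
}

#' Nearest-neighbor-interchange neighborhood
#'
#' All NNI rearrangements of the unrooted topology, grouped by the
#' internal edge they act on.  Each internal edge yields two alternative
#' topologies (subtree swaps across the edge); branch lengths travel with
#' their subtrees.
#'
#' @param tree [ape::phylo] (rooted representations are canonicalized).
#' @return list with `tree` (the canonical rooted form) and `byEdge`, a
#'   list per internal edge holding `edge` (the row in `tree$edge`) and
#'   `trees` (the two neighbors).
#' @export
nniNeighbors <- function(tree) {
  tr <- .rootAtTip(tree)
  nTip <- length(tr$tip.label)
  out <- lapply(.internalEdges(tr), function(ei) {
    v <- tr$edge[ei, 2]; p <- tr$edge[ei, 1]
    kids <- .childrenOf(tr, v)
    sib <- setdiff(.childrenOf(tr, p), v)
    list(edge = ei,
         trees = list(.swapClades(tr, kids[1], sib[1]),
                      .swapClades(tr, kids[2], sib[1])))
  })
  list(tree = tr, byEdge = out)
}

#' Maximum-likelihood tree search by repeated local rearrangements
#'
#' Hill climbing over nearest-neighbor interchanges: starting from a
#' (randomly resolved) start tree with optimized branch lengths, all NNI
#' neighbors are scored with re-optimized branch lengths and the best is
#' accepted while it improves the total log-likelihood; the search stops
#' at a local optimum.  Deterministic given `seed`.
#'
#' @inheritParams siteLogLikelihoods
#' @param startTree starting topology; polytomies are resolved randomly.
#' @param seed optional integer seed controlling polytomy resolution.
#' @param tol minimal log-likelihood improvement to accept a move.
#' @param ... passed to [optimizeBranchLengths()].
#' @return the ML tree (canonical rooted form) with optimized branch
#'   lengths; total log-likelihood in attribute `"logLik"`.
#' @export
mlLocalRearrangementSearch <- function(startTree, aln, model, seed = NULL,
                                       tol = 1e-6, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- startTree
  if (!ape::is.binary(ape::unroot(tr))) tr <- ape::multi2di(tr, random = TRUE)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr <- .rootAtTip(tr)
  tr <- optimizeBranchLengths(tr, aln, model, ...)
  best <- attr(tr, "logLik")
  repeat {
    nb <- nniNeighbors(tr)
    cand <- unlist(lapply(nb$byEdge, `[[`, "trees"), recursive = FALSE)
    if (!length(cand)) break
    scored <- lapply(cand, optimizeBranchLengths, aln = aln, model = model,
                     ...)
    ll <- vapply(scored, attr, numeric(1), "logLik")
    if (max(ll) > best + tol) {
      i <- which.max(ll)
      tr <- scored[[i]]
      best <- ll[i]
    } else break
  }
  attr(tr, "logLik") <- best
  tr
}
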