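#' RELL support from per-site log-likelihood vectors
#'
#' Resampling-estimated log-likelihood: bootstrap site weights are drawn
#' `nReplicates` times and the support of the focal tree is the percentage
#' of replicates in which its resampled total log-likelihood is strictly
#' highest among the supplied trees.  No re-optimization is performed.
#'
#' @param siteLnL numeric matrix, sites x trees; column 1 (or `focal`) is
#'   the focal tree.
#' @param nReplicates bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param focal column index of the focal tree.
#' @return support percentage in \[0, 100\].
#' @export
rellFromSiteLogLik <- function(siteLnL, nReplicates = 1000L, seed = NULL,
                               focal = 1L) {
  if (!is.null(seed)) set.seed(seed)
  siteLnL <- as.matrix(siteLnL)
  n <- nrow(siteLnL)
  W <- stats::rmultinom(nReplicates, n, rep(1 / n, n))
  tot <- t(siteLnL) %*% W                      # trees x replicates
  wins <- vapply(seq_len(nReplicates), function(b)
    all(tot[focal, b] > tot[-focal, b]), logical(1))
  100 * mean(wins)
}

#' RELL branch support over local (NNI) alternatives
#'
#' For each internal branch of the ML tree, the tree is compared against
#' its two NNI alternatives for that branch: alternative branch lengths
#' are re-optimized once, per-site log-likelihoods are computed for all
#' three trees, and bootstrap resampling of sites ([rellFromSiteLogLik()])
#' gives the percentage of replicates in which the ML tree is strictly
#' best.  Stochastic but reproducible given `seed`.
#'
#' @inheritParams siteLogLikelihoods
#' @param tree the ML tree with branch lengths (see
#'   [mlLocalRearrangementSearch()]).
#' @param nReplicates bootstrap replicates per branch (default 1000).
#' @param seed optional integer seed.
#' @param ... passed to [optimizeBranchLengths()] for the alternatives.
#' @return the canonical rooted tree with `node.label` set to the branch
#'   support (percent, `NA` for the root); a data.frame of per-branch
#'   details is attached as attribute `"supportTable"`.  With fewer than
#'   4 taxa there are no internal branches and all labels are `NA`.
#' @export
rellSupport <- function(tree, aln, model, nReplicates = 1000L, seed = NULL,
                        ...) {
  if (!is.null(seed)) set.seed(seed)
  nb <- nniNeighbors(tree)
  tr <- nb$tree
  nTip <- length(tr$tip.label)
  tr$node.label <- rep(NA_character_, tr$Nnode)
  details <- list()
  base <- siteLogLikelihoods(tr, aln, model)
  for (b in nb$byEdge) {
    alts <- lapply(b$trees, optimizeBranchLengths, aln = aln, model = model,
                   ...)
    S <- cbind(base,
               siteLogLikelihoods(alts[[1]], aln, model),
               siteLogLikelihoods(alts[[2]], aln, model))
    sup <- rellFromSiteLogLik(S, nReplicates = nReplicates)
    v <- tr$edge[b$edge, 2]
    tr$node.label[v - nTip] <- sprintf("%.1f", sup)
    details[[length(details) + 1L]] <- data.frame(
      node = v, tips = paste(sort(.cladeTips(tr, v)), collapse = ","),
      support = sup, stringsAsFactors = FALSE)
  }
  attr(tr, "supportTable") <- if (length(details)) do.call(rbind, details)
  else data.frame(node = integer(), tips = character(), support = numeric())
  tr
}

#' Branch support of a taxon set
#'
#' Looks up the RELL support of the branch subtending `taxa` in a
#' supported tree.  The full tip set returns 100 by convention (the
#' trivial bipartition).  If neither `taxa` nor its complement forms a
#' clade, the bipartition is not present in the tree and `NA` is returned
#' with a message.
#'
#' @param tree output of [rellSupport()].
#' @param taxa character vector of tip labels.
#' @return numeric support percentage, or `NA` if the bipartition is
#'   absent.
#' @export
cladeSupport <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  if (setequal(taxa, tree$tip.label)) return(100)
  nTip <- length(tree$tip.label)
  lookup <- function(set) {
    for (v in (nTip + 1L):(nTip + tree$Nnode)) {
      if (setequal(.cladeTips(tree, v), set)) return(v)
    }
    NA_integer_
  }
  v <- lookup(taxa)
  if (is.na(v)) v <- lookup(setdiff(tree$tip.label, taxa))
  if (is.na(v)) {
    message("bipartition not present in tree")
    return(NA_real_)
  }
  as.numeric(tree$node.label[v - nTip])
}
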