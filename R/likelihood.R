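# IUPAC partial-likelihood encodings; unknown symbols fall back to all-ones
.DNA_AMBIG <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"))

.tipPartial <- function(chars, states) {
  S <- length(states); L <- length(chars)
  out <- matrix(0, S, L)
  for (j in seq_len(L)) {
    ch <- chars[j]
    obs <- if (ch %in% states) ch
    else if (length(states) == 4L && !is.null(.DNA_AMBIG[[ch]]))
      .DNA_AMBIG[[ch]]
    else if (length(states) == 2L && ch %in% c("A", "G")) "R"
    else if (length(states) == 2L && ch %in% c("C", "T")) "Y"
    else states  # gap / ambiguity: missing data
    out[match(obs, states), j] <- 1
  }
  out
}

# Precomputed likelihood context: postorder tree, site-pattern compression
# and tip partial likelihoods, reused across many branch-length evaluations.
.likContext <- function(tree, aln, model) {
  m <- aln@mat
  if (!setequal(tree$tip.label, rownames(m)))
    stop("tree tips and alignment OTUs differ")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  bad <- setdiff(unique(as.vector(m)),
                 c(model@states, names(.DNA_AMBIG), "N", "X", "-", ".", "?",
                   "*"))
  if (length(bad) && !all(bad %in% LETTERS))
    stop("invalid state symbol(s): ", paste(bad, collapse = ", "))
  post <- ape::reorder.phylo(tree, "postorder")
  m <- m[post$tip.label, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "\r")
  ukey <- unique(key)
  idx <- match(key, ukey)
  w <- tabulate(idx, length(ukey))
  mu <- m[, match(ukey, key), drop = FALSE]
  tipP <- lapply(seq_len(nrow(mu)), function(i)
    .tipPartial(mu[i, ], model@states))
  rates <- if (length(model@gammaShape))
    discreteGammaRates(model@gammaShape, model@nCat) else 1
  list(post = post, tipP = tipP, idx = idx, w = w, rates = rates,
       model = model, nPat = length(ukey),
       root = post$edge[nrow(post$edge), 1])
}

# per-pattern log-likelihoods for given edge lengths (postorder order)
.ctxPatternLnL <- function(ctx, edgeLengths) {
  post <- ctx$post; model <- ctx$model
  nTip <- length(post$tip.label)
  L <- ctx$nPat
  # rescaling is only needed on deep trees; small products cannot underflow
  doScale <- nrow(post$edge) > 30L
  perCat <- matrix(0, length(ctx$rates), L)
  for (ci in seq_along(ctx$rates)) {
    part <- vector("list", nTip + post$Nnode)
    part[seq_len(nTip)] <- ctx$tipP
    logScale <- numeric(L)
    for (ei in seq_len(nrow(post$edge))) {
      p <- post$edge[ei, 1]; ch <- post$edge[ei, 2]
      P <- transitionProb(model, edgeLengths[ei] * ctx$rates[ci])
      contrib <- P %*% part[[ch]]
      part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
      if (doScale && p != ch) {
        m <- part[[p]]
        mx <- m[cbind(max.col(t(m)), seq_len(ncol(m)))]
        if (any(mx < 1e-100 & mx > 0)) {
          sc <- ifelse(mx > 0, mx, 1)
          part[[p]] <- sweep(m, 2, sc, "/")
          logScale <- logScale + log(sc)
        }
      }
    }
    lik <- as.vector(model@freqs %*% part[[ctx$root]])
    perCat[ci, ] <- log(lik) + logScale
  }
  mx <- apply(perCat, 2, max)
  mx + log(colMeans(exp(sweep(perCat, 2, mx, "-"))))
}

.ctxTotal <- function(ctx, edgeLengths)
  sum(.ctxPatternLnL(ctx, edgeLengths) * ctx$w)

#' Per-site log-likelihoods by the pruning algorithm
#'
#' Computes the log-likelihood of every alignment column on a tree under a
#' time-reversible substitution model, by post-order conditional-likelihood
#' recursion over compressed site patterns (with rescaling for numerical
#' stability).  With a gamma-shaped rate model the per-site likelihood is
#' the equal-weight average over the discrete rate categories.  Gaps and
#' ambiguity codes are treated as missing data; IUPAC codes (e.g.
#' RY-coded third positions) contribute the corresponding partial
#' information.  The result is invariant to the root placement and to OTU
#' row order.
#'
#' @param tree [ape::phylo] with branch lengths; tip labels must match the
#'   alignment OTUs.  Zero-length branches contribute an identity
#'   transition.
#' @param aln a [GeneAlignment-class].
#' @param model a [SubstitutionModel-class] whose alphabet matches the
#'   alignment.
#' @return numeric vector of per-site log-likelihoods, with the total
#'   (their sum) as attribute `"total"`.
#' @export
siteLogLikelihoods <- function(tree, aln, model) {
  ctx <- .likContext(tree, aln, model)
  pat <- .ctxPatternLnL(ctx, ctx$post$edge.length)
  site <- pat[ctx$idx]
  structure(site, total = sum(site))
}

#' Total log-likelihood
#' @inheritParams siteLogLikelihoods
#' @return numeric(1).
#' @export
treeLogLik <- function(tree, aln, model)
  .ctxTotal(.likContext(tree, aln, model),
            ape::reorder.phylo(tree, "postorder")$edge.length)

#' Optimize branch lengths by coordinate-wise search
#'
#' Repeated sweeps of univariate (golden-section) optimization over each
#' branch, until the total log-likelihood improves by less than `tol` in a
#' sweep or `maxSweeps` is reached.  The total log-likelihood is
#' non-decreasing across sweeps.
#'
#' @inheritParams siteLogLikelihoods
#' @param tol convergence tolerance in log-likelihood units (default 1e-6).
#' @param maxSweeps maximum sweeps (default 50); a warning is issued on
#'   non-convergence and the best tree so far returned.
#' @param maxBranch upper bound for any branch length.
#' @return the tree (in postorder edge order) with optimized
#'   `edge.length` and the final log-likelihood in attribute `"logLik"`.
#' @export
optimizeBranchLengths <- function(tree, aln, model, tol = 1e-6,
                                  maxSweeps = 50L, maxBranch = 10) {
  ctx <- .likContext(tree, aln, model)
  el <- ctx$post$edge.length
  cur <- .ctxTotal(ctx, el)
  converged <- FALSE
  for (sweep in seq_len(maxSweeps)) {
    prev <- cur
    for (ei in seq_along(el)) {
      f <- function(x) {
        el2 <- el; el2[ei] <- x
        -.ctxTotal(ctx, el2)
      }
      opt <- stats::optimize(f, c(0, maxBranch), tol = 1e-7)
      if (-opt$objective > cur) {
        el[ei] <- opt$minimum
        cur <- -opt$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("branch-length optimization did not converge in ", maxSweeps,
            " sweeps; returning best so far")
  out <- ctx$post
  out$edge.length <- el
  attr(out, "logLik") <- cur
  out
}
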