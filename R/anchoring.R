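#' Local protein alignment identity
#'
#' Smith-Waterman local alignment under a BLOSUM62-style scoring scheme;
#' identity is the percentage of matching residues over aligned columns
#' (including internal gap columns).
#'
#' @param a,b protein sequences (character or `AAString`).
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gapOpening,gapExtension gap penalties.
#' @return named numeric vector `c(identity = , score = )`.
#' @examples
#' pairwiseIdentity("MKV", "MRV")["identity"]  # 66.7 over 3 columns
#' @export
pairwiseIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  ncols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  c(identity = 100 * Biostrings::nmatch(pa) / ncols,
    score = Biostrings::score(pa))
}

#' Reciprocal-best-hit ortholog anchors
#'
#' Anchors a gene pair when each member is the other's highest-scoring hit
#' across the two sequence stores and the alignment identity exceeds
#' `minIdentity`.  Ties on score are broken by identity, then by
#' lexicographic id, so the result is deterministic.  The anchor set is a
#' partial matching and is symmetric in its two arguments.
#'
#' @param setA,setB `AAStringSet` protein stores.
#' @param minIdentity percent identity threshold (strict `>`; default 40).
#' @param ... passed to [pairwiseIdentity()].
#' @return data.frame `gene_a`, `gene_b`, `identity`, `score`.
#' @export
reciprocalBestHits <- function(setA, setB, minIdentity = 40, ...) {
  if (!length(setA) || !length(setB)) stop("both stores must be non-empty")
  idsA <- names(setA); idsB <- names(setB)
  idm <- scm <- matrix(0, length(setA), length(setB),
                       dimnames = list(idsA, idsB))
  chA <- as.character(setA); chB <- as.character(setB)
  for (i in seq_along(idsA)) for (j in seq_along(idsB)) {
    r <- pairwiseIdentity(chA[i], chB[j], ...)
    idm[i, j] <- r[["identity"]]; scm[i, j] <- r[["score"]]
  }
  bestOf <- function(score, ident, ids) {
    ids[order(-score, -ident, ids)][1L]
  }
  bestB <- vapply(seq_along(idsA), function(i)
    bestOf(scm[i, ], idm[i, ], idsB), character(1))
  bestA <- vapply(seq_along(idsB), function(j)
    bestOf(scm[, j], idm[, j], idsA), character(1))
  names(bestB) <- idsA; names(bestA) <- idsB
  keep <- vapply(idsA, function(a) bestA[[bestB[[a]]]] == a, logical(1))
  out <- data.frame(gene_a = idsA[keep], gene_b = unname(bestB[idsA[keep]]),
                    stringsAsFactors = FALSE)
  out$identity <- idm[cbind(out$gene_a, out$gene_b)]
  out$score <- scm[cbind(out$gene_a, out$gene_b)]
  out <- out[out$identity > minIdentity, , drop = FALSE]
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Macrosynteny dot-plot records
#'
#' One record per anchor: the gene midpoints (floor of the mean of start
#' and end) in the reference and query regions, the anchor identity, and
#' whether the two genes are transcribed in the same direction.
#'
#' @param regionRef,regionQuery [Region-class] objects.
#' @param anchors data.frame with `gene_a` (reference gene ids) and
#'   `gene_b` (query gene ids); an `identity` column is carried through.
#' @return data.frame `gene_a`, `gene_b`, `x_mid`, `y_mid`, `identity`,
#'   `orientation` (`"same"`/`"opposite"`).
#' @export
buildDotplot <- function(regionRef, regionQuery, anchors) {
  gr <- geneTable(regionRef); gq <- geneTable(regionQuery)
  ia <- match(anchors$gene_a, gr$gene_id)
  ib <- match(anchors$gene_b, gq$gene_id)
  if (anyNA(ia)) stop("anchor names unknown reference gene(s): ",
                      paste(anchors$gene_a[is.na(ia)], collapse = ", "))
  if (anyNA(ib)) stop("anchor names unknown query gene(s): ",
                      paste(anchors$gene_b[is.na(ib)], collapse = ", "))
  data.frame(
    gene_a = anchors$gene_a, gene_b = anchors$gene_b,
    x_mid = floor((gr$start[ia] + gr$end[ia]) / 2),
    y_mid = floor((gq$start[ib] + gq$end[ib]) / 2),
    identity = if ("identity" %in% names(anchors)) anchors$identity
               else NA_real_,
    orientation = ifelse(gr$strand[ia] == gq$strand[ib], "same", "opposite"),
    stringsAsFactors = FALSE)
}

#' Orientation counts for a dot plot
#'
#' @param dotplot output of [buildDotplot()].
#' @return named integer vector `n_anchored`, `n_same_orientation`,
#'   `n_opposite`; the orientation counts partition the anchor count.
#' @export
macrosyntenyStats <- function(dotplot) {
  n <- nrow(dotplot)
  s <- if (n) sum(dotplot$orientation == "same") else 0L
  c(n_anchored = as.integer(n), n_same_orientation = as.integer(s),
    n_opposite = as.integer(n - s))
}

#' Write anchors or dot-plot records as TSV
#' @param x data.frame from [reciprocalBestHits()] or [buildDotplot()].
#' @param path output file.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
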