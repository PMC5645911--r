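#' Construct a GeneAlignment
#'
#' @param x named character vector of equal-length sequences, character
#'   matrix (rows = OTUs), or `XStringSet`.
#' @param alphabet `"dna"`, `"protein"` or `"ry"`.
#' @param codonPositions per-column codon positions (1/2/3); for an
#'   in-frame CDS alignment use `codonPositions = "cds"` to annotate
#'   columns 1,2,3,1,2,3,...
#' @param partition per-column source-gene labels, or a single label
#'   recycled to all columns.
#' @return a [GeneAlignment-class].
#' @export
geneAlignment <- function(x, alphabet = c("dna", "protein", "ry"),
                          codonPositions = NULL, partition = NULL) {
  alphabet <- match.arg(alphabet)
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    w <- unique(nchar(x))
    if (length(w) != 1L) stop("sequences must have equal length")
    m <- matrix(unlist(strsplit(toupper(x), "")), nrow = length(x),
                byrow = TRUE, dimnames = list(names(x), NULL))
  } else m <- x
  nc <- ncol(m)
  cp <- if (is.null(codonPositions)) integer(0)
        else if (identical(codonPositions, "cds")) {
          if (nc %% 3L != 0L) stop("CDS alignment length must be a multiple of 3")
          rep(1:3, nc / 3L)
        } else as.integer(codonPositions)
  pm <- if (is.null(partition)) character(0)
        else if (length(partition) == 1L) rep(partition, nc)
        else as.character(partition)
  new("GeneAlignment", mat = m, alphabet = alphabet, codonPositions = cp,
      partitionMap = pm)
}

#' @describeIn GeneAlignment-class OTU labels
#' @param x,object a `GeneAlignment`
#' @export
setGeneric("otus", function(x) standardGeneric("otus"))
#' @export
setMethod("otus", "GeneAlignment", function(x) rownames(x@mat))

#' @describeIn GeneAlignment-class alignment as a character matrix
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @export
setMethod("alignmentMatrix", "GeneAlignment", function(x) x@mat)

#' @describeIn GeneAlignment-class per-column codon positions
#' @export
setGeneric("codonPositions", function(x) standardGeneric("codonPositions"))
#' @export
setMethod("codonPositions", "GeneAlignment", function(x) x@codonPositions)

#' @describeIn GeneAlignment-class per-column partition labels
#' @export
setGeneric("partitionMap", function(x) standardGeneric("partitionMap"))
#' @export
setMethod("partitionMap", "GeneAlignment", function(x) x@partitionMap)

#' @describeIn GeneAlignment-class number of columns
#' @export
setMethod("ncol", "GeneAlignment", function(x) ncol(x@mat))

setMethod("show", "GeneAlignment", function(object) {
  cat(sprintf("GeneAlignment: %d OTUs x %d columns (%s)%s%s\n",
              nrow(object@mat), ncol(object@mat), object@alphabet,
              if (length(object@codonPositions)) ", codon-annotated" else "",
              if (length(object@partitionMap))
                sprintf(", %d partition(s)",
                        length(unique(object@partitionMap))) else ""))
})

.sliceAlignment <- function(aln, keep) {
  new("GeneAlignment", mat = aln@mat[, keep, drop = FALSE],
      alphabet = aln@alphabet,
      codonPositions = if (length(aln@codonPositions))
        aln@codonPositions[keep] else integer(0),
      partitionMap = if (length(aln@partitionMap))
        aln@partitionMap[keep] else character(0))
}

.GAP_CHARS <- c("-", ".")

#' Prune majority-gap alignment sites
#'
#' Removes columns with gaps in more than half of the OTUs; a column with
#' gaps in exactly half of the OTUs is kept.  Codon-position and
#' partition annotations are sliced consistently.
#'
#' @param aln a [GeneAlignment-class].
#' @return the pruned alignment.
#' @export
pruneGapSites <- function(aln) {
  gaps <- colSums(matrix(aln@mat %in% .GAP_CHARS, nrow(aln@mat)))
  .sliceAlignment(aln, gaps <= nrow(aln@mat) / 2)
}

#' Third-codon-position treatment
#'
#' Fast-evolving third codon positions can be `"include"`d unchanged,
#' `"ry"`-coded (purines A,G to R; pyrimidines C,T to Y, keeping only
#' transversion information), or `"exclude"`d.  RY-coded columns remain in
#' a DNA alignment as IUPAC ambiguity codes, so downstream likelihoods
#' treat them as two-state partial information.
#'
#' @param aln a codon-annotated DNA [GeneAlignment-class].
#' @param mode `"include"`, `"ry"` or `"exclude"`.
#' @return a [GeneAlignment-class].
#' @export
thirdPositionTreatment <- function(aln, mode = c("include", "ry", "exclude")) {
  mode <- match.arg(mode)
  if (!length(aln@codonPositions))
    stop("alignment lacks codon-position annotation")
  if (mode == "include") return(aln)
  third <- aln@codonPositions == 3L
  if (mode == "exclude") return(.sliceAlignment(aln, !third))
  m <- aln@mat
  m[, third] <- chartr("AGCT", "RRYY", m[, third])
  new("GeneAlignment", mat = m, alphabet = aln@alphabet,
      codonPositions = aln@codonPositions, partitionMap = aln@partitionMap)
}

#' Recode a whole DNA alignment to the binary RY alphabet
#'
#' @param aln DNA [GeneAlignment-class].
#' @return `"ry"` alignment (A,G -> R; C,T -> Y; other symbols -> `-`).
#' @export
ryCode <- function(aln) {
  m <- aln@mat
  m[] <- ifelse(m %in% c("A", "G", "R"), "R",
                ifelse(m %in% c("C", "T", "Y"), "Y", "-"))
  new("GeneAlignment", mat = m, alphabet = "ry",
      codonPositions = aln@codonPositions, partitionMap = aln@partitionMap)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Columns are appended in input order; OTUs are matched by label and
#' must form identical sets (row order may differ).  The partition map
#' records the source gene of every column (from `names(alns)`, else
#' `gene1`, `gene2`, ...).  Codon positions are carried through when all
#' inputs have them.
#'
#' @param alns list of [GeneAlignment-class] with a common alphabet.
#' @return concatenated [GeneAlignment-class].
#' @export
concatenateAlignments <- function(alns) {
  stopifnot(length(alns) >= 1L)
  ref <- rownames(alns[[1]]@mat)
  labs <- names(alns)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- paste0("gene", seq_along(alns))
  for (i in seq_along(alns)) {
    miss <- setdiff(ref, rownames(alns[[i]]@mat))
    extra <- setdiff(rownames(alns[[i]]@mat), ref)
    if (length(miss) || length(extra))
      stop("OTU set mismatch in partition ", labs[i],
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  alpha <- unique(vapply(alns, function(a) a@alphabet, character(1)))
  if (length(alpha) != 1L) stop("alphabet mismatch across partitions")
  mats <- lapply(alns, function(a) a@mat[ref, , drop = FALSE])
  allCp <- all(vapply(alns, function(a) length(a@codonPositions) > 0,
                      logical(1)))
  cp <- if (allCp) unlist(lapply(alns, function(a) a@codonPositions))
        else integer(0)
  pm <- unlist(lapply(seq_along(alns), function(i)
    if (length(alns[[i]]@partitionMap)) alns[[i]]@partitionMap
    else rep(labs[i], ncol(alns[[i]]@mat))))
  new("GeneAlignment", mat = do.call(cbind, mats), alphabet = alpha,
      codonPositions = as.integer(cp), partitionMap = unname(pm))
}

#' Read / write alignments
#'
#' FASTA alignments are read through [readFastaStore()]; relaxed PHYLIP is
#' read with \pkg{seqinr} and written directly.
#'
#' @param path file path.
#' @param alphabet `"dna"` or `"protein"`.
#' @param aln a [GeneAlignment-class].
#' @param ... passed to [geneAlignment()].
#' @export
readAlignmentFasta <- function(path, alphabet = c("dna", "protein"), ...) {
  alphabet <- match.arg(alphabet)
  store <- readFastaStore(path, alphabet = ifelse(alphabet == "dna",
                                                  "dna", "protein"))
  geneAlignment(as.character(store), alphabet = alphabet, ...)
}

#' @rdname readAlignmentFasta
#' @export
readAlignmentPhylip <- function(path, alphabet = c("dna", "protein"), ...) {
  alphabet <- match.arg(alphabet)
  a <- seqinr::read.alignment(path, format = "phylip")
  seqs <- toupper(gsub("[ \r\n]", "", unlist(a$seq)))
  names(seqs) <- trimws(a$nam)
  geneAlignment(seqs, alphabet = alphabet, ...)
}

#' @rdname readAlignmentFasta
#' @export
writeAlignmentPhylip <- function(aln, path) {
  seqs <- apply(aln@mat, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(aln@mat), ncol(aln@mat)), con)
  writeLines(sprintf("%-12s%s", rownames(aln@mat), seqs), con)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' @param aln a [GeneAlignment-class] with a partition map.
#' @param path output file.
#' @param type data-type prefix (default `"DNA"`).
#' @export
writePartitions <- function(aln, path, type = "DNA") {
  if (!length(aln@partitionMap)) stop("alignment has no partition map")
  pm <- aln@partitionMap
  parts <- unique(pm)
  lines <- vapply(parts, function(p) {
    i <- range(which(pm == p))
    sprintf("%s, %s = %d-%d", type, p, i[1], i[2])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
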