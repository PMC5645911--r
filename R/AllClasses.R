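#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Annotated genomic region
#'
#' A `Region` is a scaffold or chromosome arm carrying ordered, stranded
#' gene models.  Gene coordinates are 1-based inclusive (GFF3 convention)
#' and genes are kept sorted by start position.
#'
#' @slot regionId single region identifier (e.g. a scaffold name).
#' @slot speciesId species the region belongs to.
#' @slot length region length in bp.
#' @slot genes a [GenomicRanges::GRanges] with metadata columns `gene_id`
#'   and `protein_id`; strand must be `+` or `-`.
#' @slot linkageGroup linkage-group label or `NA` if unassigned.
#'
#' @seealso [Region()], [readAnnotations()]
#' @export
setClass("Region",
  slots = c(
    regionId     = "character",
    speciesId    = "character",
    length       = "numeric",
    genes        = "GRanges",
    linkageGroup = "character"
  )
)

setValidity("Region", function(object) {
  msg <- character()
  g <- object@genes
  if (length(object@regionId) != 1L) msg <- c(msg, "regionId must be length 1")
  if (length(g) > 0L) {
    if (is.null(mcols(g)$gene_id))
      msg <- c(msg, "genes must carry a gene_id metadata column")
    else if (anyDuplicated(mcols(g)$gene_id))
      msg <- c(msg, "gene_id values must be unique within a region")
    st <- as.character(GenomicRanges::strand(g))
    if (!all(st %in% c("+", "-")))
      msg <- c(msg, "all genes must be stranded (+ or -)")
    if (is.unsorted(GenomicRanges::start(g)))
      msg <- c(msg, "genes must be sorted by start position")
    if (any(GenomicRanges::end(g) > object@length))
      msg <- c(msg, "gene end coordinates exceed region length")
    if (any(GenomicRanges::start(g) < 1L))
      msg <- c(msg, "gene start coordinates must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Microsynteny presence/order matrix
#'
#' Per-region presence, rank order and relative orientation of a reference
#' gene panel.  States are `"P"` (present), `"A"` (absent) and `"U"`
#' (unknown; allowed at declared region edges where a gene may fall beyond
#' the assembled sequence).  Each row corresponds to one region, labelled
#' with its species and a synteny-copy label (`"#1"`, `"#2"`).
#'
#' @slot panel ordered reference gene names (columns).
#' @slot states character matrix of `"P"`/`"A"`/`"U"`, rows = regions.
#' @slot ranks integer matrix; for present genes, the rank of the gene in
#'   genomic order within its row; `NA` otherwise.
#' @slot orientations character matrix; `"+"` if a present gene is on the
#'   same strand as the reference copy, `"-"` otherwise; `NA` if absent.
#' @slot species species label per row.
#' @slot copy synteny-copy label per row (`"#1"`, `"#2"`).
#' @slot regionIds region identifier per row.
#'
#' @seealso [presenceOrderMatrix()], [extractMicrosynteny()],
#'   [emitFixtureMatrix()]
#' @export
setClass("PresenceOrderMatrix",
  slots = c(
    panel        = "character",
    states       = "matrix",
    ranks        = "matrix",
    orientations = "matrix",
    species      = "character",
    copy         = "character",
    regionIds    = "character"
  )
)

setValidity("PresenceOrderMatrix", function(object) {
  msg <- character()
  p <- length(object@panel); n <- nrow(object@states)
  if (anyDuplicated(object@panel)) msg <- c(msg, "panel gene names must be unique")
  for (nm in c("states", "ranks", "orientations")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(n, p)))
      msg <- c(msg, sprintf("%s has wrong dimensions", nm))
  }
  if (!all(object@states %in% c("P", "A", "U")))
    msg <- c(msg, "states must be P, A or U")
  if (length(object@species) != n || length(object@copy) != n ||
      length(object@regionIds) != n)
    msg <- c(msg, "row annotations must match number of rows")
  if (n > 0 && p > 0) {
    for (i in seq_len(n)) {
      r <- object@ranks[i, object@states[i, ] == "P"]
      if (anyNA(r) || anyDuplicated(r))
        msg <- c(msg, sprintf("row %d: present genes must have unique ranks", i))
    }
    if (any(!is.na(object@ranks[object@states != "P"])))
      msg <- c(msg, "absent/unknown genes must have NA rank")
  }
  if (length(msg)) msg else TRUE
})

#' Candidate duplication scenario
#'
#' A placement of one or more large-scale duplication events on branches of
#' a species tree, together with the duplicated template (a contiguous
#' interval of the gene panel).  A branch is named by the tip set of the
#' clade below it; a single tip names a terminal branch.
#'
#' @slot name scenario label.
#' @slot placements list of character vectors; each vector is the tip set
#'   of the clade subtended by a duplication branch.
#' @slot template panel genes duplicated at each placement; empty means
#'   "infer the minimal duplicated segment from the matrix".
#'
#' @seealso [duplicationScenario()], [scenarioTotalEvents()],
#'   [rankScenarios()]
#' @export
setClass("DuplicationScenario",
  slots = c(name = "character", placements = "list", template = "character")
)

setValidity("DuplicationScenario", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(object@placements) < 1L)
    msg <- c(msg, "at least one duplication placement is required")
  if (!all(vapply(object@placements, is.character, logical(1))))
    msg <- c(msg, "placements must be character vectors of tip labels")
  if (length(msg)) msg else TRUE
})

#' Event count for a duplication scenario
#'
#' @slot nDuplications number of duplication events.
#' @slot nLosses Dollo-minimal number of gene-loss events.
#' @slot total sum of the two.
#' @seealso [scenarioTotalEvents()]
#' @export
setClass("EventCount",
  slots = c(nDuplications = "integer", nLosses = "integer", total = "integer")
)

setValidity("EventCount", function(object) {
  if (object@total != object@nDuplications + object@nLosses)
    "total must equal nDuplications + nLosses"
  else if (object@nDuplications < 0L || object@nLosses < 0L)
    "event counts must be non-negative"
  else TRUE
})

#' Molecular alignment with codon and partition annotation
#'
#' A plain character-matrix alignment (rows = OTUs) carrying optional
#' per-column codon positions (1/2/3, for alignments derived from CDS) and
#' an optional per-column source-gene partition map for concatenated
#' supermatrices.
#'
#' @slot mat character matrix, `rownames` are OTU labels.
#' @slot alphabet `"dna"`, `"protein"` or `"ry"` (binary purine/pyrimidine).
#' @slot codonPositions integer vector of length `ncol(mat)` or length 0.
#' @slot partitionMap character vector of length `ncol(mat)` or length 0.
#'
#' @seealso [geneAlignment()], [concatenateAlignments()]
#' @export
setClass("GeneAlignment",
  slots = c(
    mat            = "matrix",
    alphabet       = "character",
    codonPositions = "integer",
    partitionMap   = "character"
  )
)

setValidity("GeneAlignment", function(object) {
  msg <- character()
  if (!is.character(object@mat)) msg <- c(msg, "mat must be a character matrix")
  if (is.null(rownames(object@mat))) msg <- c(msg, "mat must have OTU rownames")
  if (!object@alphabet %in% c("dna", "protein", "ry"))
    msg <- c(msg, "alphabet must be dna, protein or ry")
  nc <- ncol(object@mat)
  if (!length(object@codonPositions) %in% c(0L, nc))
    msg <- c(msg, "codonPositions must be empty or one per column")
  if (length(object@codonPositions) && !all(object@codonPositions %in% 1:3))
    msg <- c(msg, "codonPositions must be 1, 2 or 3")
  if (!length(object@partitionMap) %in% c(0L, nc))
    msg <- c(msg, "partitionMap must be empty or one per column")
  if (length(msg)) msg else TRUE
})

#' Substitution model for likelihood computation
#'
#' Time-reversible substitution model defined by an exchangeability matrix
#' and stationary frequencies, scaled to one expected substitution per unit
#' branch length, with optional discrete-gamma rate variation.
#'
#' @slot name model name (JC69, K2P, HKY, TN93, GTR, RY, PoissonAA,
#'   empiricalAA, codonGY).
#' @slot states state alphabet.
#' @slot Q scaled instantaneous rate matrix.
#' @slot freqs stationary frequencies.
#' @slot gammaShape numeric(1) shape of gamma rate variation, or numeric(0)
#'   for rate homogeneity.
#' @slot nCat number of discrete gamma categories.
#' @slot eig cached eigendecomposition of `Q` used by [transitionProb()].
#' @seealso [substitutionModel()], [siteLogLikelihoods()]
#' @export
setClass("SubstitutionModel",
  slots = c(
    name       = "character",
    states     = "character",
    Q          = "matrix",
    freqs      = "numeric",
    gammaShape = "numeric",
    nCat       = "integer",
    eig        = "list"
  )
)

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  s <- length(object@states)
  if (!identical(dim(object@Q), c(s, s))) msg <- c(msg, "Q dimension mismatch")
  if (length(object@freqs) != s) msg <- c(msg, "freqs dimension mismatch")
  if (abs(sum(object@freqs) - 1) > 1e-8) msg <- c(msg, "freqs must sum to 1")
  if (any(abs(rowSums(object@Q)) > 1e-6)) msg <- c(msg, "Q rows must sum to 0")
  if (length(object@gammaShape) == 1L && object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be > 0")
  if (length(msg)) msg else TRUE
})
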