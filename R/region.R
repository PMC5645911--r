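#' Construct a Region
#'
#' @param regionId region (scaffold) identifier.
#' @param speciesId species identifier.
#' @param length region length in bp; defaults to the maximum gene end.
#' @param genes a `data.frame` with columns `gene_id`, `start`, `end`,
#'   `strand` and optionally `protein_id` (1-based inclusive coordinates),
#'   or a ready-made [GenomicRanges::GRanges].
#' @param linkageGroup linkage-group label or `NA`.
#' @return a [Region-class] object with genes sorted by start.
#' @examples
#' g <- data.frame(gene_id = c("b", "a"), start = c(500, 100),
#'                 end = c(700, 250), strand = c("-", "+"))
#' r <- Region("scf1", "eel", genes = g)
#' geneTable(r)$gene_id  # sorted by start: "a", "b"
#' @export
Region <- function(regionId, speciesId, genes, length = NULL,
                   linkageGroup = NA_character_) {
  if (is.data.frame(genes)) {
    if (nrow(genes) > 0 && any(genes$end < genes$start))
      stop("validation error: end < start for gene(s) ",
           paste(genes$gene_id[genes$end < genes$start], collapse = ", "))
    pid <- if ("protein_id" %in% names(genes)) as.character(genes$protein_id)
           else rep(NA_character_, nrow(genes))
    gr <- GRanges(
      seqnames = rep(regionId, nrow(genes)),
      ranges = IRanges(start = genes$start, end = genes$end),
      strand = genes$strand
    )
    mcols(gr)$gene_id <- as.character(genes$gene_id)
    mcols(gr)$protein_id <- pid
  } else {
    gr <- genes
    if (is.null(mcols(gr)$protein_id))
      mcols(gr)$protein_id <- rep(NA_character_, base::length(gr))
  }
  gr <- gr[order(GenomicRanges::start(gr))]
  if (is.null(length))
    length <- if (base::length(gr)) max(GenomicRanges::end(gr)) else 0
  new("Region", regionId = as.character(regionId),
      speciesId = as.character(speciesId), length = as.numeric(length),
      genes = gr, linkageGroup = as.character(linkageGroup))
}

#' @describeIn Region-class region identifier
#' @param object,x a `Region`
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))

#' @export
setMethod("regionId", "Region", function(x) x@regionId)

#' @describeIn Region-class species identifier
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @export
setMethod("speciesId", "Region", function(x) x@speciesId)

#' @describeIn Region-class region length in bp
#' @export
setGeneric("regionLength", function(x) standardGeneric("regionLength"))

#' @export
setMethod("regionLength", "Region", function(x) x@length)

#' @describeIn Region-class linkage-group label (`NA` if unassigned)
#' @export
setGeneric("linkageGroup", function(x) standardGeneric("linkageGroup"))

#' @export
setMethod("linkageGroup", "Region", function(x) x@linkageGroup)

#' @describeIn Region-class gene models as a data.frame sorted by start
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @export
setMethod("geneTable", "Region", function(x) {
  g <- x@genes
  data.frame(
    gene_id = mcols(g)$gene_id,
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    protein_id = mcols(g)$protein_id,
    stringsAsFactors = FALSE
  )
})

#' @describeIn Region-class number of genes
#' @export
setMethod("length", "Region", function(x) base::length(x@genes))

setMethod("show", "Region", function(object) {
  cat(sprintf("Region %s (%s): %d genes, %s bp, LG %s\n",
              object@regionId, object@speciesId, base::length(object@genes),
              format(object@length, big.mark = ","),
              ifelse(is.na(object@linkageGroup), "unassigned",
                     object@linkageGroup)))
})
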