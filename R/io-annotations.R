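#' Read gene annotations into Region objects
#'
#' Parses a GFF3 or BED file and returns one [Region-class] per sequence
#' (scaffold/chromosome).  GFF3 coordinates are kept 1-based inclusive;
#' BED intervals are converted from 0-based half-open to 1-based
#' inclusive.  Genes are sorted by start within each region.
#'
#' For GFF3, features of type `gene` are used when present, otherwise all
#' features; the gene identifier is taken from the `ID` (or `Name`)
#' attribute, and a `protein_id` attribute is carried through when
#' present.  Region lengths come from `##sequence-region` pragmas when
#' available, else from the maximum gene end.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param speciesId species label attached to every returned region, or a
#'   named vector mapping region ids to species.
#' @param regionLengths optional named vector of region lengths in bp.
#' @return list of [Region-class], named by region id.
#' @export
readAnnotations <- function(path, dialect = c("gff3", "bed"),
                            speciesId = "unknown", regionLengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (dialect == "gff3") {
    .checkGffLines(lines, body)
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(mcols(gr)) &&
        any(as.character(mcols(gr)$type) == "gene"))
      gr <- gr[as.character(mcols(gr)$type) == "gene"]
    ids <- mcols(gr)$ID
    if (is.null(ids)) ids <- mcols(gr)$Name
    if (is.null(ids)) ids <- paste0("feature", seq_along(gr))
    ids[is.na(ids)] <- paste0("feature", which(is.na(ids)))
    pid <- mcols(gr)$protein_id
    if (is.null(pid)) pid <- rep(NA_character_, length(gr))
    tab <- data.frame(
      region = as.character(GenomicRanges::seqnames(gr)),
      gene_id = as.character(ids),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      protein_id = as.character(pid), stringsAsFactors = FALSE)
    pragma <- .gffSequenceRegions(lines)
  } else {
    .checkBedLines(lines, body)
    gr <- rtracklayer::import(path, format = "bed")
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
    tab <- data.frame(
      region = as.character(GenomicRanges::seqnames(gr)),
      gene_id = as.character(nm),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      protein_id = NA_character_, stringsAsFactors = FALSE)
    pragma <- numeric(0)
  }
  if (any(tab$strand == "*"))
    stop("validation error: unstranded feature(s): ",
         paste(tab$gene_id[tab$strand == "*"], collapse = ", "))
  if (any(tab$end < tab$start))
    stop("validation error: end < start for ",
         paste(tab$gene_id[tab$end < tab$start], collapse = ", "))
  out <- lapply(split(tab, tab$region), function(d) {
    rid <- d$region[1]
    sp <- if (length(speciesId) > 1L || !is.null(names(speciesId)))
      unname(speciesId[rid]) else speciesId
    len <- if (!is.null(regionLengths) && rid %in% names(regionLengths))
      regionLengths[[rid]]
    else if (rid %in% names(pragma)) pragma[[rid]]
    else max(d$end)
    Region(rid, sp, d[, -1], length = len)
  })
  out[order(names(out))]
}

.checkGffLines <- function(lines, body) {
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("parse error at line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e))
      stop(sprintf("parse error at line %d: non-numeric coordinates", i))
    if (e < s)
      stop(sprintf("validation error at line %d: end < start", i))
  }
  invisible(TRUE)
}

.checkBedLines <- function(lines, body) {
  for (i in which(body)) {
    if (grepl("^(track|browser)", lines[i])) next
    f <- strsplit(lines[i], "[\t ]+")[[1]]
    if (length(f) < 6L)
      stop(sprintf("parse error at line %d: BED needs >= 6 fields for stranded genes",
                   i))
    if (is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))))
      stop(sprintf("parse error at line %d: non-numeric coordinates", i))
  }
  invisible(TRUE)
}

.gffSequenceRegions <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) return(numeric(0))
  parts <- strsplit(trimws(sr), "[ \t]+")
  len <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
  names(len) <- vapply(parts, function(p) p[2], character(1))
  len
}

#' Write regions as GFF3
#'
#' Inverse of [readAnnotations()] for the GFF3 dialect; coordinates
#' round-trip exactly.
#'
#' @param regions list of [Region-class].
#' @param path output file.
#' @export
writeAnnotationsGff3 <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (r in regions)
    writeLines(sprintf("##sequence-region %s 1 %d", regionId(r),
                       as.integer(regionLength(r))), con)
  for (r in regions) {
    g <- geneTable(r)
    if (!nrow(g)) next
    attr9 <- sprintf("ID=%s", g$gene_id)
    has_pid <- !is.na(g$protein_id)
    attr9[has_pid] <- paste0(attr9[has_pid], ";protein_id=",
                             g$protein_id[has_pid])
    writeLines(sprintf("%s\tparalogon\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       regionId(r), g$start, g$end, g$strand, attr9), con)
  }
  invisible(path)
}
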