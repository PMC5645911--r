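#' Construct a presence/order matrix
#'
#' @param panel ordered reference gene names.
#' @param rows list of row descriptions; each element is a list with
#'   `species`, `copy`, `regionId` and `genes`, where `genes` is a
#'   data.frame with columns `gene` (panel gene), `state` (`P`/`A`/`U`),
#'   `rank` and `orientation` (`rank`/`orientation` needed for `P` only).
#'   Panel genes not mentioned are absent.
#' @return a [PresenceOrderMatrix-class].
#' @export
presenceOrderMatrix <- function(panel, rows) {
  n <- length(rows); p <- length(panel)
  states <- matrix("A", n, p, dimnames = list(NULL, panel))
  ranks <- matrix(NA_integer_, n, p, dimnames = list(NULL, panel))
  ori <- matrix(NA_character_, n, p, dimnames = list(NULL, panel))
  for (i in seq_len(n)) {
    g <- rows[[i]]$genes
    if (!is.null(g) && nrow(g)) {
      j <- match(g$gene, panel)
      if (anyNA(j)) stop("unknown panel gene(s): ",
                         paste(g$gene[is.na(j)], collapse = ", "))
      states[i, j] <- g$state
      isP <- g$state == "P"
      ranks[i, j[isP]] <- as.integer(g$rank[isP])
      if (!is.null(g$orientation)) ori[i, j[isP]] <- g$orientation[isP]
      else ori[i, j[isP]] <- "+"
    }
  }
  sp <- vapply(rows, function(r) r$species, character(1))
  cp <- vapply(rows, function(r) r$copy, character(1))
  rid <- vapply(rows, function(r)
    if (is.null(r$regionId)) paste0(r$species, r$copy) else r$regionId,
    character(1))
  rownames(states) <- rownames(ranks) <- rownames(ori) <- paste(sp, cp)
  new("PresenceOrderMatrix", panel = panel, states = states, ranks = ranks,
      orientations = ori, species = sp, copy = cp, regionIds = rid)
}

#' @describeIn PresenceOrderMatrix-class the ordered reference gene panel
#' @param x,object a `PresenceOrderMatrix`
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @export
setMethod("panelGenes", "PresenceOrderMatrix", function(x) x@panel)

#' @describeIn PresenceOrderMatrix-class state matrix (P/A/U)
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))
#' @export
setMethod("stateMatrix", "PresenceOrderMatrix", function(x) x@states)

#' @describeIn PresenceOrderMatrix-class rank matrix
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))
#' @export
setMethod("rankMatrix", "PresenceOrderMatrix", function(x) x@ranks)

#' @describeIn PresenceOrderMatrix-class orientation matrix
#' @export
setGeneric("orientationMatrix", function(x) standardGeneric("orientationMatrix"))
#' @export
setMethod("orientationMatrix", "PresenceOrderMatrix",
          function(x) x@orientations)

#' @describeIn PresenceOrderMatrix-class species per row
#' @export
setGeneric("rowSpecies", function(x) standardGeneric("rowSpecies"))
#' @export
setMethod("rowSpecies", "PresenceOrderMatrix", function(x) x@species)

#' @describeIn PresenceOrderMatrix-class synteny-copy label per row
#' @export
setGeneric("copyLabels", function(x) standardGeneric("copyLabels"))
#' @export
setMethod("copyLabels", "PresenceOrderMatrix", function(x) x@copy)

setMethod("show", "PresenceOrderMatrix", function(object) {
  cat(sprintf("PresenceOrderMatrix: %d regions x %d panel genes\n",
              nrow(object@states), length(object@panel)))
  print(object@states)
})

.matrixRowIndex <- function(m, row) {
  if (is.numeric(row)) return(as.integer(row))
  i <- match(row, rownames(m@states))
  if (is.na(i)) i <- match(row, m@regionIds)
  if (is.na(i)) stop("unknown matrix row: ", row)
  i
}

#' Present genes of a matrix row in genomic order
#' @keywords internal
.presentInOrder <- function(m, i) {
  isP <- m@states[i, ] == "P"
  genes <- m@panel[isP]
  genes[order(m@ranks[i, isP])]
}

#' Gene-order conservation against the panel order
#'
#' Number of order-conserved genes in a matrix row, defined as the length
#' of the longest common subsequence (LCS) between the row's present genes
#' in genomic order and the reference panel order.  Orientation is
#' ignored; the value equals the number of present genes exactly when the
#' observed order is a subsequence of the panel order ("perfectly
#' conserved").
#'
#' @param m a [PresenceOrderMatrix-class].
#' @param row row name (e.g. `"eel #1"`), region id, or index.
#' @return integer LCS length.
#' @export
orderConservation <- function(m, row) {
  i <- .matrixRowIndex(m, row)
  .lcsLength(.presentInOrder(m, i), m@panel)
}

.lcsLength <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  d <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d[i + 1L, j + 1L] <- if (a[i] == b[j]) d[i, j] + 1L
    else max(d[i, j + 1L], d[i + 1L, j])
  }
  d[na + 1L, nb + 1L]
}

#' Shared single-copy loss pattern between two species
#'
#' Panel genes whose presence pattern across the two synteny copies is
#' identical in both species and records exactly one loss (present on one
#' copy, absent on the other).  Genes with an unknown state in any of the
#' four rows are excluded, as are genes outside the duplicated template:
#' a gene outside the minimal duplicated segment is absent from copy #2
#' because it was never duplicated, not because a copy was lost.
#'
#' @param m a [PresenceOrderMatrix-class] with `#1` and `#2` rows for both
#'   species.
#' @param speciesPair character vector of two species labels.
#' @param copies the two copy labels (default `c("#1", "#2")`).
#' @param template panel genes considered duplicated; default: the
#'   interval returned by [minimalDuplicatedSegment()].
#' @return character vector of shared-loss genes, in panel order.
#' @export
sharedLossPattern <- function(m, speciesPair, copies = c("#1", "#2"),
                              template = NULL) {
  stopifnot(length(speciesPair) == 2L, length(copies) == 2L)
  if (is.null(template)) template <- minimalDuplicatedSegment(m)
  rows <- lapply(speciesPair, function(sp) {
    lapply(copies, function(cp) {
      i <- which(m@species == sp & m@copy == cp)
      if (length(i) != 1L)
        stop("missing row for species ", sp, " copy ", cp)
      m@states[i, ]
    })
  })
  ok <- vapply(seq_along(m@panel), function(j) {
    p1 <- c(rows[[1]][[1]][j], rows[[1]][[2]][j])
    p2 <- c(rows[[2]][[1]][j], rows[[2]][[2]][j])
    if (any(c(p1, p2) == "U")) return(FALSE)
    identical(p1, p2) && sum(p1 == "A") == 1L
  }, logical(1))
  genes <- m@panel[ok]
  genes[genes %in% template]
}

#' Extract a microsynteny presence/order matrix
#'
#' Projects each region onto a reference gene panel through ortholog
#' anchors.  A panel gene is present in a region when an anchor links it
#' to a gene of that region; present genes get a rank (genomic order among
#' present panel genes) and a relative orientation (`"+"` when the target
#' gene is on the same strand as the reference copy).  A panel gene with
#' two or more anchors into one region is an error (candidate tandem
#' duplication, outside the model).
#'
#' When `boundaryUnknown` is `TRUE`, an absent panel gene whose expected
#' position lies beyond the last present panel gene on a row, with that
#' flanking gene within `edgeMargin` bp of the region boundary, is marked
#' `"U"` (unknown) instead of `"A"`: the region may simply be truncated
#' before the gene.
#'
#' @param panel ordered reference gene names (must exist in
#'   `referenceRegion`).
#' @param regions list of [Region-class] to project (the reference region
#'   may be included; it is matched by region id and scored all-present).
#' @param anchors data.frame with `gene_a` (reference gene ids, i.e. panel
#'   names) and `gene_b` (gene ids in target regions).
#' @param referenceRegion the [Region-class] carrying the panel.
#' @param copyLabels optional named character vector (names = region ids)
#'   of copy labels; by default regions of each species are labelled
#'   `"#1"`, `"#2"`, ... by decreasing number of present panel genes.
#' @param boundaryUnknown enable edge-unknown calling (default `TRUE`).
#' @param edgeMargin bp distance from the region boundary within which the
#'   flanking gene triggers an unknown call (default 5000).
#' @return a [PresenceOrderMatrix-class].
#' @export
extractMicrosynteny <- function(panel, regions, anchors, referenceRegion,
                                copyLabels = NULL, boundaryUnknown = TRUE,
                                edgeMargin = 5000) {
  refTab <- geneTable(referenceRegion)
  if (!all(panel %in% refTab$gene_id))
    stop("panel gene(s) missing from reference region: ",
         paste(setdiff(panel, refTab$gene_id), collapse = ", "))
  refStrand <- refTab$strand[match(panel, refTab$gene_id)]
  rowList <- lapply(regions, function(r) {
    tab <- geneTable(r)
    if (identical(regionId(r), regionId(referenceRegion))) {
      g <- data.frame(gene = panel, state = "P",
                      rank = rank(tab$start[match(panel, tab$gene_id)]),
                      orientation = "+", stringsAsFactors = FALSE)
      return(list(species = speciesId(r), regionId = regionId(r), genes = g))
    }
    a <- anchors[anchors$gene_a %in% panel & anchors$gene_b %in% tab$gene_id,
                 , drop = FALSE]
    if (anyDuplicated(a$gene_a))
      stop("panel gene(s) anchored more than once in region ", regionId(r),
           ": ", paste(unique(a$gene_a[duplicated(a$gene_a)]), collapse = ", "))
    present <- panel %in% a$gene_a
    tgt <- a$gene_b[match(panel, a$gene_a)]
    tgtIdx <- match(tgt, tab$gene_id)
    state <- ifelse(present, "P", "A")
    if (boundaryUnknown && any(present) && !all(present)) {
      state <- .flagEdgeUnknown(state, present, panel, tab, tgtIdx,
                                regionLength(r), edgeMargin)
    }
    rnk <- rep(NA_integer_, length(panel))
    rnk[present] <- rank(tab$start[tgtIdx[present]])
    ori <- rep(NA_character_, length(panel))
    ori[present] <- ifelse(tab$strand[tgtIdx[present]] ==
                             refStrand[present], "+", "-")
    g <- data.frame(gene = panel, state = state, rank = rnk,
                    orientation = ori, stringsAsFactors = FALSE)
    list(species = speciesId(r), regionId = regionId(r), genes = g)
  })
  # default copy labels: per species, by decreasing present-gene count
  sp <- vapply(rowList, `[[`, character(1), "species")
  np <- vapply(rowList, function(r) sum(r$genes$state == "P"), integer(1))
  rid <- vapply(rowList, `[[`, character(1), "regionId")
  cp <- character(length(rowList))
  if (!is.null(copyLabels)) {
    cp <- unname(copyLabels[rid])
    if (anyNA(cp)) stop("copyLabels missing for region(s): ",
                        paste(rid[is.na(cp)], collapse = ", "))
  } else {
    for (s in unique(sp)) {
      i <- which(sp == s)
      cp[i[order(-np[i], rid[i])]] <- paste0("#", seq_along(i))
    }
  }
  for (i in seq_along(rowList)) rowList[[i]]$copy <- cp[i]
  presenceOrderMatrix(panel, rowList)
}

# mark trailing/leading absences as unknown when the flanking present gene
# sits within edgeMargin of the region boundary
.flagEdgeUnknown <- function(state, present, panel, tab, tgtIdx, regLen,
                             edgeMargin) {
  pIdx <- which(present)
  starts <- tab$start[tgtIdx]
  # direction of the mapping: do panel ranks increase with coordinates?
  incr <- if (length(pIdx) >= 2L)
    stats::cor(pIdx, starts[pIdx], method = "spearman") >= 0 else TRUE
  flagSide <- function(absIdx, flankIdx, towardHighCoord) {
    gi <- tgtIdx[flankIdx]
    nearEdge <- if (towardHighCoord) regLen - tab$end[gi] <= edgeMargin
    else tab$start[gi] - 1 <= edgeMargin
    if (nearEdge) state[absIdx] <<- "U"
  }
  lastP <- max(pIdx); firstP <- min(pIdx)
  after <- which(!present & seq_along(panel) > lastP)
  before <- which(!present & seq_along(panel) < firstP)
  if (length(after)) flagSide(after, lastP, towardHighCoord = incr)
  if (length(before)) flagSide(before, firstP, towardHighCoord = !incr)
  state
}

#' Write / read a presence/order matrix as TSV
#'
#' One row per region with columns `species`, `copy`, `region_id`, then
#' one column per panel gene containing `P:<rank>:<orientation>`, `A` or
#' `U`.  `readPresenceMatrix(writePresenceMatrix(m))` round-trips.
#'
#' @param m a [PresenceOrderMatrix-class].
#' @param path file path.
#' @export
writePresenceMatrix <- function(m, path) {
  cells <- matrix("A", nrow(m@states), ncol(m@states))
  cells[m@states == "U"] <- "U"
  isP <- m@states == "P"
  cells[isP] <- sprintf("P:%d:%s", m@ranks[isP], m@orientations[isP])
  df <- data.frame(species = m@species, copy = m@copy,
                   region_id = m@regionIds, cells, stringsAsFactors = FALSE)
  names(df) <- c("species", "copy", "region_id", m@panel)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePresenceMatrix
#' @export
readPresenceMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  panel <- setdiff(names(df), c("species", "copy", "region_id"))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    cells <- as.character(df[i, panel])
    parts <- strsplit(cells, ":", fixed = TRUE)
    st <- vapply(parts, `[`, character(1), 1L)
    rk <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
    or <- vapply(parts, `[`, character(1), 3L)
    g <- data.frame(gene = panel, state = st, rank = rk, orientation = or,
                    stringsAsFactors = FALSE)
    list(species = df$species[i], copy = df$copy[i],
         regionId = df$region_id[i], genes = g)
  })
  presenceOrderMatrix(panel, rows)
}
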