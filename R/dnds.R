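.geneticCode <- function() {
  Biostrings::GENETIC_CODE
}

.splitCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3L != 0L) stop("sequence length must be a multiple of 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# synonymous site count of one codon: per position, the fraction of the
# three single-nucleotide changes that preserve the amino acid.  Changes
# to stop codons count as nonsynonymous.
.codonSynSites <- function(codon, code = .geneticCode()) {
  aa <- code[[codon]]
  nts <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (alt in setdiff(.DNA_STATES, nts[pos])) {
    mut <- nts; mut[pos] <- alt
    mc <- paste(mut, collapse = "")
    if (code[[mc]] == aa) s <- s + 1 / 3
  }
  s
}

# synonymous / nonsynonymous differences between two codons, averaged over
# all shortest mutational pathways; pathways passing through a stop codon
# are excluded (unless all are blocked, in which case all are used)
.codonPairDiffs <- function(a, b, code = .geneticCode()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  d <- which(ca != cb)
  if (!length(d)) return(c(sd = 0, nd = 0))
  perms <- switch(length(d), list(d),
                  list(d, d[2:1]),
                  list(d[c(1, 2, 3)], d[c(1, 3, 2)], d[c(2, 1, 3)],
                       d[c(2, 3, 1)], d[c(3, 1, 2)], d[c(3, 2, 1)]))
  paths <- lapply(perms, function(ord) {
    cur <- ca; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- cb[pos]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (code[[c2]] == "*") blocked <- TRUE
      if (code[[c1]] == code[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  })
  pm <- do.call(rbind, paths)
  ok <- pm[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[ok, "sd"]), nd = mean(pm[ok, "nd"]))
}

#' Nei-Gojobori (1986) pairwise dN/dS counts
#'
#' Counts synonymous (S) and nonsynonymous (N) sites by per-codon mutation
#' enumeration averaged over both sequences, and synonymous (Sd) and
#' nonsynonymous (Nd) differences averaged over all shortest mutational
#' pathways between differing codons (pathways through stop codons
#' excluded).  Proportions are corrected for multiple hits with the
#' Jukes-Cantor formula `d = -3/4 log(1 - 4p/3)`; when `p >= 3/4` the
#' corresponding distance is `NA` (flagged as undefined).  Codons
#' containing gaps or ambiguity in either sequence are skipped.  The
#' function is symmetric in its arguments and `N + S` equals three times
#' the number of compared codons.
#'
#' @param cdsA,cdsB in-frame coding sequences of equal length (character
#'   or `DNAString`), without internal stop codons.
#' @return named list `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`,
#'   `nCodons` (codons compared).
#' @examples
#' ng86PairCounts("GGGAAA", "GGAAAA")  # one synonymous difference
#' @export
ng86PairCounts <- function(cdsA, cdsB) {
  code <- .geneticCode()
  a <- .splitCodons(cdsA); b <- .splitCodons(cdsB)
  if (length(a) != length(b)) stop("sequences must have equal length")
  clean <- function(x) all(strsplit(x, "")[[1]] %in% .DNA_STATES)
  use <- vapply(a, clean, logical(1)) & vapply(b, clean, logical(1))
  if (any(code[a[use]] == "*") || any(code[b[use]] == "*"))
    stop("stop codon in coding sequence")
  N <- S <- Nd <- Sd <- 0
  for (i in which(use)) {
    sa <- .codonSynSites(a[i], code); sb <- .codonSynSites(b[i], code)
    S <- S + (sa + sb) / 2
    N <- N + 3 - (sa + sb) / 2
    dd <- .codonPairDiffs(a[i], b[i], code)
    Sd <- Sd + dd[["sd"]]; Nd <- Nd + dd[["nd"]]
  }
  jc <- function(p) if (is.nan(p) || p >= 3 / 4) NA_real_
                    else -3 / 4 * log(1 - 4 * p / 3)
  pN <- if (N > 0) Nd / N else NaN
  pS <- if (S > 0) Sd / S else NaN
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = jc(pN), dS = jc(pS), nCodons = sum(use))
}

#' Sliding-window dN/dS scan
#'
#' Computes Nei-Gojobori dN and dS in windows of `windowAa` codons
#' advanced by `stepAa` codons along an in-frame codon alignment, for a
#' named focal sequence pair.  A final partial window is kept when it
#' spans at least half a window (configurable).  The dN/dS ratio is `NA`
#' (undefined) when dS is 0 or undefined.
#'
#' @param aln codon alignment: a [GeneAlignment-class] (DNA,
#'   codon-annotated), a named character vector, or a `DNAStringSet` of
#'   equal-length in-frame CDS.
#' @param pair names of the two sequences to compare (default: first two).
#' @param windowAa window size in codons (default 25).
#' @param stepAa step in codons (default 5).
#' @param keepPartial keep a final partial window of at least
#'   `windowAa / 2` codons (default `TRUE`).
#' @return data.frame with one row per window: `start_codon`, `end_codon`,
#'   `N`, `S`, `Nd`, `Sd`, `dN`, `dS`, `ratio`; window parameters are kept
#'   in attributes `window`, `step` and `pair`.  An alignment shorter than
#'   one window yields a single truncated window flagged by attribute
#'   `truncated`.
#' @export
slidingDnds <- function(aln, pair = NULL, windowAa = 25L, stepAa = 5L,
                        keepPartial = TRUE) {
  seqs <- if (is(aln, "GeneAlignment")) apply(aln@mat, 1, paste, collapse = "")
          else stats::setNames(as.character(aln), names(aln))
  if (is.null(pair)) pair <- names(seqs)[1:2]
  if (!all(pair %in% names(seqs)))
    stop("pair not found in alignment: ", paste(pair, collapse = ", "))
  sa <- seqs[[pair[1]]]; sb <- seqs[[pair[2]]]
  nCod <- nchar(sa) %/% 3L
  truncated <- FALSE
  if (nCod < windowAa) {
    starts <- 1L; ends <- nCod; truncated <- TRUE
  } else {
    starts <- seq(1L, nCod - windowAa + 1L, by = stepAa)
    ends <- starts + windowAa - 1L
    lastEnd <- ends[length(ends)]
    if (keepPartial && lastEnd < nCod) {
      s2 <- starts[length(starts)] + stepAa
      if (nCod - s2 + 1L >= windowAa / 2) {
        starts <- c(starts, s2); ends <- c(ends, nCod)
      }
    }
  }
  rows <- lapply(seq_along(starts), function(i) {
    i1 <- (starts[i] - 1L) * 3L + 1L; i2 <- ends[i] * 3L
    r <- ng86PairCounts(substr(sa, i1, i2), substr(sb, i1, i2))
    data.frame(start_codon = as.integer(starts[i]),
               end_codon = as.integer(ends[i]),
               N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
               dN = r$dN, dS = r$dS,
               ratio = if (!is.na(r$dS) && r$dS > 0 && !is.na(r$dN))
                 r$dN / r$dS else NA_real_)
  })
  out <- do.call(rbind, rows)
  structure(out, window = windowAa, step = stepAa, pair = pair,
            truncated = truncated)
}

#' Mask codon windows with elevated nonsynonymous substitution
#'
#' Removes every codon column covered by a flagged window: a window is
#' flagged when its dN/dS ratio exceeds `ratioThreshold`, or, when the
#' ratio is undefined (dS = 0), when its dN is positive and reaches the
#' `dnQuantile` quantile of the window dN values.  The returned alignment
#' keeps its codon annotation.
#'
#' @param aln the codon [GeneAlignment-class] the scan was derived from.
#' @param scan output of [slidingDnds()].
#' @param ratioThreshold dN/dS threshold (> 0).
#' @param dnQuantile quantile of window dN used for undefined-ratio
#'   windows (default 0.95).
#' @return masked [GeneAlignment-class]; a warning is issued if every
#'   column is removed.
#' @export
maskWindows <- function(aln, scan, ratioThreshold, dnQuantile = 0.95) {
  if (ratioThreshold <= 0) stop("ratioThreshold must be > 0")
  dnCut <- stats::quantile(scan$dN, dnQuantile, na.rm = TRUE, names = FALSE)
  flagged <- (!is.na(scan$ratio) & scan$ratio > ratioThreshold) |
    (is.na(scan$ratio) & !is.na(scan$dN) & scan$dN > 0 & scan$dN >= dnCut)
  if (!any(flagged)) return(aln)
  nCod <- ncol(aln@mat) %/% 3L
  drop <- rep(FALSE, nCod)
  for (i in which(flagged))
    drop[scan$start_codon[i]:min(scan$end_codon[i], nCod)] <- TRUE
  keepCols <- rep(!drop, each = 3L)
  if (!any(keepCols)) warning("all windows flagged; masked alignment is empty")
  .sliceAlignment(aln, keepCols)
}
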