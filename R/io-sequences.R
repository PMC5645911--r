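#' Read a FASTA sequence store
#'
#' Reads FASTA into a Biostrings string set ([Biostrings::AAStringSet] or
#' [Biostrings::DNAStringSet]).  Residues are upper-cased on read; record
#' ids are the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return an `XStringSet` named by record id.
#' @export
readFastaStore <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("[ \t].*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(raw) <- ids
  seqs <- toupper(as.character(raw))
  if (alphabet == "protein") Biostrings::AAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
}

#' Write a sequence store as FASTA
#'
#' Round-trip `readFastaStore(writeFastaStore(x))` is the identity on ids
#' and residues.
#'
#' @param store an `XStringSet`.
#' @param path output file.
#' @export
writeFastaStore <- function(store, path) {
  Biostrings::writeXStringSet(store, path)
  invisible(path)
}

#' Read a rooted species tree from newick
#'
#' @param path newick file (or a newick string).
#' @return an [ape::phylo] tree.
#' @examples
#' tr <- readSpeciesTree(textConnection("((eel,arowana),gar);"))
#' @export
readSpeciesTree <- function(path) {
  tr <- if (inherits(path, "connection")) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    ape::read.tree(text = txt)
  } else if (is.character(path) && !file.exists(path) && grepl("\\(", path)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("parse error: invalid newick")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}
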