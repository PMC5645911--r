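#' Default five-lineage species tree
#'
#' A rooted tree of the lineages framing the duplication-timing inference:
#' a holostean outgroup (gar), then eel (Elopomorpha) and arowana
#' (Osteoglossomorpha) branching basally to a clupeocephalan pair
#' (zebrafish, medaka).  Branch lengths are in substitutions/site.
#'
#' @return an [ape::phylo].
#' @export
figTeleostTree <- function() {
  ape::read.tree(text = paste0(
    "(gar:0.35,(eel:0.30,(arowana:0.28,",
    "(zebrafish:0.22,medaka:0.22):0.08):0.05):0.06);"))
}

#' Simulation configuration
#'
#' Describes the generating history for [simulateWgdDataset()]: a species
#' tree, an ancestral segment of `panelSize` genes, one whole-genome
#' duplication (or independent segmental duplications), per-branch Dollo
#' gene losses, occasional segment inversions, and sequence evolution.
#'
#' @param tree rooted [ape::phylo] with branch lengths
#'   (substitutions/site); default [figTeleostTree()].
#' @param panelSize number of genes in the ancestral segment (default 11).
#' @param wgdClade tip set of the clade below the WGD branch (default: all
#'   non-outgroup tips, i.e. every tip except the first-branching one).
#' @param independentDupClades list of tip sets for lineage-specific
#'   duplications (scenario-2 truth); exactly one of `wgdClade` /
#'   `independentDupClades` may be set.
#' @param lossProb per-gene per-branch copy-loss probability (default 0.2).
#' @param inversionProb per-branch probability of one segment inversion
#'   (default 0.1).
#' @param kappa,baseFreqs HKY mutation parameters.
#' @param geneRates per-gene rate multipliers (default all 1).
#' @param omega per-gene dN/dS for the codon sequence mode (default 0.2).
#' @param geneLengthMeanLog,geneLengthSdLog lognormal parameters for gene
#'   length in codons.
#' @param intergenicRange uniform range (bp) for intergenic spacing.
#' @param seed integer random seed; one global seed governs all draws.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(tree = figTeleostTree(), panelSize = 11L,
                             wgdClade = NULL, independentDupClades = NULL,
                             lossProb = 0.2, inversionProb = 0.1,
                             kappa = 2, baseFreqs = rep(0.25, 4),
                             geneRates = NULL, omega = 0.2,
                             geneLengthMeanLog = log(250),
                             geneLengthSdLog = 0.25,
                             intergenicRange = c(2000, 20000), seed = 1L) {
  if (!is.null(wgdClade) && !is.null(independentDupClades))
    stop("set exactly one of wgdClade / independentDupClades")
  if (is.null(wgdClade) && is.null(independentDupClades)) {
    # default: duplicate everything but the outgroup (a tip child of the root)
    nTip <- length(tree$tip.label)
    rootKids <- tree$edge[tree$edge[, 1] == nTip + 1L, 2]
    og <- if (any(rootKids <= nTip)) tree$tip.label[rootKids[rootKids <= nTip][1]]
          else tree$tip.label[1]
    wgdClade <- setdiff(tree$tip.label, og)
  }
  stopifnot(lossProb >= 0, lossProb <= 1,
            inversionProb >= 0, inversionProb <= 1)
  if (lossProb == 1) warning("lossProb = 1 is degenerate: everything is lost")
  structure(list(
    tree = tree, panelSize = as.integer(panelSize), wgdClade = wgdClade,
    independentDupClades = independentDupClades, lossProb = lossProb,
    inversionProb = inversionProb, kappa = kappa, baseFreqs = baseFreqs,
    geneRates = geneRates, omega = omega,
    geneLengthMeanLog = geneLengthMeanLog,
    geneLengthSdLog = geneLengthSdLog,
    intergenicRange = intergenicRange, seed = as.integer(seed)),
    class = "SimulationConfig")
}

.evolveStates <- function(idx, model, t) {
  if (t <= 0) return(idx)
  P <- transitionProb(model, t)
  S <- ncol(P)
  out <- idx
  for (s in unique(idx)) {
    w <- idx == s
    out[w] <- sample.int(S, sum(w), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a duplicated-segment dataset with truth labels
#'
#' Generates an ancestral segment of panel genes, duplicates it at the
#' configured branch(es), applies Dollo losses (a copy once lost stays
#' absent in all descendants) and occasional contiguous inversions along
#' every branch below a duplication, evolves gene sequences down the tree,
#' and lays out the surviving genes of each tip as [Region-class] objects
#' with random intergenic spacing.  All draws come from one generator
#' stream seeded by `config$seed`, so equal seeds give identical outputs.
#'
#' @param config a [simulationConfig()].
#' @param sequences `"nucleotide"` (HKY site-wise evolution; translations
#'   may contain X where a stop arose), `"codon"` (GY94-style codon model
#'   with per-gene omega, no stops) or `"none"` (presence/order only).
#' @return list of class `WgdSimulation`:
#'   \describe{
#'     \item{regions}{list of [Region-class], one per surviving
#'       (species, copy) segment.}
#'     \item{cds,proteins}{`DNAStringSet` / `AAStringSet` keyed by gene id
#'       (empty when `sequences = "none"`).}
#'     \item{truth}{generating scenario, duplication placement(s),
#'       realized losses and inversions (with branch labels), the true
#'       template, loss-trial counts, and the panel.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulateWgdDataset <- function(config,
                               sequences = c("nucleotide", "codon", "none")) {
  sequences <- match.arg(sequences)
  set.seed(config$seed)
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  nTip <- length(tree$tip.label)
  panel <- sprintf("g%02d", seq_len(config$panelSize))
  rates <- if (is.null(config$geneRates))
    stats::setNames(rep(1, config$panelSize), panel)
  else stats::setNames(config$geneRates, panel)
  lens <- pmax(30L, round(stats::rlnorm(config$panelSize,
                                        config$geneLengthMeanLog,
                                        config$geneLengthSdLog)))
  names(lens) <- panel
  placements <- if (!is.null(config$wgdClade)) list(config$wgdClade)
                else config$independentDupClades
  dupNodes <- vapply(placements, function(p) .nodeForTips(tree, p),
                     integer(1))
  ntModel <- substitutionModel("HKY", kappa = config$kappa,
                               baseFreqs = config$baseFreqs)
  codModel <- if (sequences == "codon")
    lapply(stats::setNames(panel, panel), function(g)
      codonSubstitutionModel(config$kappa,
                             if (length(config$omega) > 1)
                               config$omega[[g]] else config$omega,
                             config$baseFreqs))
  else NULL
  senseCodons <- .codonStates()
  ancSeq <- lapply(panel, function(g) {
    if (sequences == "none") return(NULL)
    if (sequences == "codon") {
      m <- codModel[[g]]
      sample.int(length(m@states), lens[[g]], replace = TRUE,
                 prob = m@freqs)
    } else {
      cods <- sample(senseCodons, lens[[g]], replace = TRUE)
      match(unlist(strsplit(cods, "")), .DNA_STATES)
    }
  })
  names(ancSeq) <- panel
  ancGenes <- data.frame(gene = panel,
                         strand = sample(c("+", "-"), config$panelSize,
                                         replace = TRUE),
                         stringsAsFactors = FALSE)
  rootSeg <- list(list(copy = "#1", duplicated = FALSE, genes = ancGenes,
                       seqs = ancSeq))
  losses <- list(); inversions <- list(); lossTrials <- 0L
  tips <- list()
  branchLabel <- function(node) {
    paste(sort(.cladeTips(tree, node)), collapse = "+")
  }
  evolveGene <- function(g, idx, t) {
    if (sequences == "none" || is.null(idx)) return(idx)
    model <- if (sequences == "codon") codModel[[g]] else ntModel
    .evolveStates(idx, model, t * rates[[g]])
  }
  recurse <- function(node, segs) {
    for (ei in which(tree$edge[, 1] == node)) {
      child <- tree$edge[ei, 2]
      t <- tree$edge.length[ei]
      cur <- segs
      if (any(dupNodes == child)) {
        stopifnot(length(cur) == 1L)
        cur <- list(
          modifyList(cur[[1]], list(copy = "#1", duplicated = TRUE)),
          modifyList(cur[[1]], list(copy = "#2", duplicated = TRUE)))
      }
      lbl <- branchLabel(child)
      for (si in seq_along(cur)) {
        seg <- cur[[si]]
        if (seg$duplicated && nrow(seg$genes) > 0) {
          lost <- stats::runif(nrow(seg$genes)) < config$lossProb
          lossTrials <<- lossTrials + nrow(seg$genes)
          if (any(lost)) {
            losses[[length(losses) + 1L]] <<- data.frame(
              branch = lbl, copy = seg$copy, gene = seg$genes$gene[lost],
              stringsAsFactors = FALSE)
            seg$seqs[seg$genes$gene[lost]] <- NULL
            seg$genes <- seg$genes[!lost, , drop = FALSE]
          }
        }
        if (nrow(seg$genes) >= 2 &&
            stats::runif(1) < config$inversionProb) {
          n <- nrow(seg$genes)
          i <- sample.int(n, 1); j <- sample.int(n, 1)
          lo <- min(i, j); hi <- max(i, j)
          seg$genes[lo:hi, ] <- seg$genes[hi:lo, , drop = FALSE]
          seg$genes$strand[lo:hi] <- chartr("+-", "-+",
                                            seg$genes$strand[lo:hi])
          inversions[[length(inversions) + 1L]] <<- data.frame(
            branch = lbl, copy = seg$copy, from = lo, to = hi,
            stringsAsFactors = FALSE)
        }
        if (sequences != "none")
          seg$seqs <- lapply(stats::setNames(seg$genes$gene,
                                             seg$genes$gene),
                             function(g) evolveGene(g, seg$seqs[[g]], t))
        cur[[si]] <- seg
      }
      if (child <= nTip) tips[[tree$tip.label[child]]] <<- cur
      else recurse(child, cur)
    }
  }
  recurse(nTip + 1L, rootSeg)
  regions <- list(); cds <- character(); prots <- character()
  for (sp in names(tips)) for (seg in tips[[sp]]) {
    if (!nrow(seg$genes)) next
    cpShort <- sub("#", "c", seg$copy)
    rid <- paste0(sp, "_", cpShort)
    n <- nrow(seg$genes)
    gaps <- round(stats::runif(n, config$intergenicRange[1],
                               config$intergenicRange[2]))
    glen <- lens[seg$genes$gene] * 3L
    starts <- cumsum(gaps) + cumsum(c(0, glen[-n]))
    ends <- starts + glen - 1L
    gid <- paste(sp, cpShort, seg$genes$gene, sep = "_")
    regions[[rid]] <- Region(rid, sp,
      data.frame(gene_id = gid, start = starts, end = ends,
                 strand = seg$genes$strand, protein_id = gid,
                 stringsAsFactors = FALSE),
      length = ends[n] + round(stats::runif(1, config$intergenicRange[1],
                                            config$intergenicRange[2])))
    if (sequences != "none") {
      for (k in seq_len(n)) {
        g <- seg$genes$gene[k]
        dna <- if (sequences == "codon")
          paste(codModel[[g]]@states[seg$seqs[[g]]], collapse = "")
        else paste(.DNA_STATES[seg$seqs[[g]]], collapse = "")
        cds[[gid[k]]] <- dna
      }
    }
  }
  if (length(cds)) {
    cdsSet <- Biostrings::DNAStringSet(cds)
    aa <- chartr("*", "X", as.character(Biostrings::translate(cdsSet)))
    protSet <- Biostrings::AAStringSet(aa)
  } else {
    cdsSet <- Biostrings::DNAStringSet()
    protSet <- Biostrings::AAStringSet()
  }
  truth <- list(
    scenario = if (!is.null(config$wgdClade)) "single-WGD" else "independent",
    placements = placements,
    losses = if (length(losses)) do.call(rbind, losses)
      else data.frame(branch = character(), copy = character(),
                      gene = character(), stringsAsFactors = FALSE),
    inversions = if (length(inversions)) do.call(rbind, inversions)
      else data.frame(branch = character(), copy = character(),
                      from = integer(), to = integer(),
                      stringsAsFactors = FALSE),
    template = panel, panel = panel, lossTrials = lossTrials)
  structure(list(regions = regions, cds = cdsSet, proteins = protSet,
                 truth = truth, config = config),
            class = "WgdSimulation")
}

#' Truth-based ortholog anchors for a simulation
#'
#' Builds the anchor table linking a reference region's genes to every
#' other simulated region by the generating gene identity (each simulated
#' gene id embeds its panel gene).  This bypasses sequence comparison and
#' is intended for pipeline tests; use [reciprocalBestHits()] on
#' `sim$proteins` for the full sequence-based route.
#'
#' @param sim a `WgdSimulation`.
#' @param referenceRegionId region id serving as reference (default: the
#'   first region of the first-branching species).
#' @return data.frame `gene_a`, `gene_b`, `identity`, `score`.
#' @export
truthAnchors <- function(sim, referenceRegionId = NULL) {
  if (is.null(referenceRegionId)) {
    placed <- unlist(if (!is.null(sim$config$wgdClade))
      list(sim$config$wgdClade) else sim$config$independentDupClades)
    og <- setdiff(sim$config$tree$tip.label, placed)[1]
    if (is.na(og)) og <- sim$config$tree$tip.label[1]
    referenceRegionId <- grep(paste0("^", og, "_"), names(sim$regions),
                              value = TRUE)[1]
  }
  ref <- sim$regions[[referenceRegionId]]
  refTab <- geneTable(ref)
  panelOf <- function(ids) vapply(strsplit(ids, "_"), function(p)
    p[length(p)], character(1))
  refPanel <- panelOf(refTab$gene_id)
  out <- list()
  for (rid in setdiff(names(sim$regions), referenceRegionId)) {
    tab <- geneTable(sim$regions[[rid]])
    pg <- panelOf(tab$gene_id)
    hit <- match(pg, refPanel)
    ok <- !is.na(hit)
    if (any(ok))
      out[[rid]] <- data.frame(gene_a = refTab$gene_id[hit[ok]],
                               gene_b = tab$gene_id[ok],
                               identity = 100, score = NA_real_,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
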