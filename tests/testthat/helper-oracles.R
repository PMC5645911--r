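# Independent oracle implementations used to validate the package's
# algorithms.  These deliberately use brute force / exhaustive enumeration
# and share no code with the implementations they check.

# affine-gap Smith-Waterman best local score (gap of length L costs
# open + L * extend, matching Biostrings conventions)
oracleLocalScore <- function(a, b, mat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[a[i], b[j]]
    M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                           X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                           Y[i + 1, j] - extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# LCS length by exhaustive subsequence enumeration (|a| small)
oracleLcs <- function(a, b) {
  isSubseq <- function(x, y) {
    j <- 1L
    for (e in y) if (j <= length(x) && identical(x[j], e)) j <- j + 1L
    j > length(x)
  }
  for (k in rev(seq_len(min(length(a), length(b))))) {
    for (idx in utils::combn(length(a), k, simplify = FALSE)) {
      if (isSubseq(a[idx], b)) return(k)
    }
  }
  0L
}

# minimal Dollo loss count by exhaustive enumeration of loss-branch subsets
oracleDollo <- function(tree, originNode, states) {
  nTip <- length(tree$tip.label)
  desc <- function(v) {
    out <- v
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (k in kids) out <- c(out, desc(k))
    out
  }
  nodes <- desc(originNode)                 # candidate loss branches
  tipsBelow <- intersect(nodes, seq_len(nTip))
  labs <- tree$tip.label[tipsBelow]
  st <- setNames(rep("unknown", length(labs)), labs)
  known <- intersect(names(states), labs)
  st[known] <- states[known]
  best <- Inf
  for (k in 0:length(nodes)) {
    if (k >= best) break
    for (sub in utils::combn(length(nodes), k, simplify = FALSE)) {
      lost <- unique(unlist(lapply(nodes[sub], desc)))
      ok <- TRUE
      for (i in seq_along(tipsBelow)) {
        tipAbsent <- tipsBelow[i] %in% lost
        if (st[i] == "absent" && !tipAbsent) { ok <- FALSE; break }
        if (st[i] == "present" && tipAbsent) { ok <- FALSE; break }
      }
      if (ok) { best <- min(best, k); break }
    }
  }
  best
}

# brute-force scenario scorer: enumerates loss-branch subsets per
# (copy, template gene) column instead of using the tree DP
oracleScenarioTotal <- function(scenario, m, tree) {
  template <- minimalDuplicatedSegment(m)
  total <- length(scenario@placements)
  st <- stateMatrix(m)
  for (pl in scenario@placements) {
    node <- paralogon:::.nodeForTips(tree, pl)
    below <- paralogon:::.cladeTips(tree, node)
    for (cp in c("#1", "#2")) for (g in template) {
      states <- vapply(below, function(sp) {
        i <- which(rowSpecies(m) == sp & copyLabels(m) == cp)
        if (!length(i)) "absent"
        else c(P = "present", A = "absent", U = "unknown")[[st[i[1], g]]]
      }, character(1))
      total <- total + oracleDollo(tree, node, states)
    }
  }
  total
}

# total log-likelihood by brute-force summation over all interior-node
# state assignments (tiny trees only)
oracleLnL <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  S <- length(model@states)
  m <- aln@mat[tree$tip.label, , drop = FALSE]
  Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
    transitionProb(model, tree$edge.length[i]))
  root <- nTip + 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nInt)))
  total <- 0
  for (site in seq_len(ncol(m))) {
    obs <- match(m[, site], model@states)
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- c(obs, grid[g, ])          # tips then interior nodes
      p <- unname(model@freqs[assign[root]])
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * Ps[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# NG86 counts by an independent enumeration (recursive pathway expansion)
oracleNg86 <- function(sa, sb) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  codsA <- substring(sa, seq(1, nchar(sa), 3), seq(3, nchar(sa), 3))
  codsB <- substring(sb, seq(1, nchar(sb), 3), seq(3, nchar(sb), 3))
  synSites <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      for (n in nts[nts != ch[p]]) {
        alt <- ch; alt[p] <- n
        if (code[[paste(alt, collapse = "")]] == code[[cod]])
          tot <- tot + 1 / 3
      }
    }
    tot
  }
  pathDiffs <- function(a, b) {
    da <- strsplit(a, "")[[1]]; db <- strsplit(b, "")[[1]]
    dif <- which(da != db)
    if (!length(dif)) return(c(0, 0))
    acc <- list()
    rec <- function(cur, remaining, sd, nd, blocked) {
      if (!length(remaining)) {
        acc[[length(acc) + 1]] <<- c(sd, nd, blocked)
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur; nxt[p] <- db[p]
        cFrom <- paste(cur, collapse = ""); cTo <- paste(nxt, collapse = "")
        syn <- code[[cFrom]] == code[[cTo]]
        rec(nxt, setdiff(remaining, p), sd + syn, nd + !syn,
            blocked || code[[cTo]] == "*")
      }
    }
    rec(da, dif, 0, 0, FALSE)
    m <- do.call(rbind, acc)
    keep <- m[, 3] == 0
    if (!any(keep)) keep <- rep(TRUE, nrow(m))
    c(mean(m[keep, 1]), mean(m[keep, 2]))
  }
  N <- S <- Nd <- Sd <- 0
  for (i in seq_along(codsA)) {
    ok <- all(strsplit(paste0(codsA[i], codsB[i]), "")[[1]] %in% nts)
    if (!ok) next
    s <- (synSites(codsA[i]) + synSites(codsB[i])) / 2
    S <- S + s; N <- N + 3 - s
    d <- pathDiffs(codsA[i], codsB[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd)
}

# random sense-codon CDS without stop codons
randomCds <- function(nCodons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# simulate an alignment by direct state evolution down a tree (input data
# for likelihood / search tests; not an oracle)
simAlignment <- function(tree, L, model, seed) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  nTip <- length(tree$tip.label)
  S <- length(model@states)
  seqs <- list()
  seqs[[nTip + 1L]] <- sample.int(S, L, TRUE, prob = model@freqs)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    P <- transitionProb(model, tree$edge.length[i])
    x <- seqs[[p]]; y <- x
    for (s in seq_len(S)) {
      w <- x == s
      if (any(w)) y[w] <- sample.int(S, sum(w), TRUE, prob = P[s, ])
    }
    seqs[[ch]] <- y
  }
  m <- do.call(rbind, lapply(seq_len(nTip), function(i)
    model@states[seqs[[i]]]))
  rownames(m) <- tree$tip.label
  geneAlignment(m, if (S == 20) "protein" else if (S == 2) "ry" else "dna")
}

# random presence/order matrix over a panel for property tests
randomMatrix <- function(panel, species, pPresent = 0.7, pUnknown = 0.05) {
  rows <- list()
  for (sp in species) for (cp in c("#1", "#2")) {
    st <- sample(c("P", "A", "U"), length(panel), TRUE,
                 prob = c(pPresent, 1 - pPresent - pUnknown, pUnknown))
    pres <- which(st == "P")
    g <- data.frame(gene = panel, state = st, rank = NA_integer_,
                    orientation = NA_character_, stringsAsFactors = FALSE)
    if (length(pres)) {
      g$rank[pres] <- sample(length(pres))
      g$orientation[pres] <- sample(c("+", "-"), length(pres), TRUE)
    }
    rows[[length(rows) + 1]] <- list(species = sp, copy = cp,
                                     genes = g[st != "A", , drop = FALSE])
  }
  presenceOrderMatrix(panel, rows)
}
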