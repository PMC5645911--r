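test_that("equal seeds give identical simulations", {
  cfg <- simulationConfig(seed = 7)
  s1 <- simulateWgdDataset(cfg)
  s2 <- simulateWgdDataset(cfg)
  expect_identical(lapply(s1$regions, geneTable), lapply(s2$regions, geneTable))
  expect_identical(as.character(s1$cds), as.character(s2$cds))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateWgdDataset(simulationConfig(seed = 8))
  expect_false(identical(as.character(s1$cds), as.character(s3$cds)))
})

test_that("without losses and inversions every duplicated species is complete", {
  cfg <- simulationConfig(lossProb = 0, inversionProb = 0, seed = 3)
  sim <- simulateWgdDataset(cfg, sequences = "none")
  tipSpecies <- cfg$tree$tip.label
  dup <- cfg$wgdClade
  for (sp in tipSpecies) {
    rids <- grep(paste0("^", sp, "_"), names(sim$regions), value = TRUE)
    expect_length(rids, if (sp %in% dup) 2L else 1L)
    for (rid in rids) {
      tab <- geneTable(sim$regions[[rid]])
      expect_equal(nrow(tab), cfg$panelSize)
      # ancestral order preserved
      panelOf <- vapply(strsplit(tab$gene_id, "_"), function(p)
        p[length(p)], character(1))
      expect_identical(panelOf, sprintf("g%02d", 1:11))
    }
  }
  expect_identical(nrow(sim$truth$losses), 0L)
  expect_identical(nrow(sim$truth$inversions), 0L)
})

test_that("realized loss fraction sits inside binomial 99% bounds", {
  p <- 0.2
  trials <- 0; events <- 0; seed <- 0
  while (trials < 1000) {
    seed <- seed + 1
    sim <- simulateWgdDataset(simulationConfig(lossProb = p, seed = seed),
                              sequences = "none")
    trials <- trials + sim$truth$lossTrials
    events <- events + nrow(sim$truth$losses)
  }
  bounds <- qbinom(c(0.005, 0.995), trials, p) / trials
  expect_gte(events / trials, bounds[1])
  expect_lte(events / trials, bounds[2])
})

test_that("simulated presence is Dollo-consistent with the recorded losses", {
  tr <- figTeleostTree()
  for (seed in 1:10) {
    sim <- simulateWgdDataset(simulationConfig(lossProb = 0.3, seed = seed),
                              sequences = "none")
    losses <- sim$truth$losses
    for (i in seq_len(nrow(losses))) {
      branchTips <- strsplit(losses$branch[i], "+", fixed = TRUE)[[1]]
      cp <- sub("#", "c", losses$copy[i])
      for (sp in branchTips) {
        rid <- paste0(sp, "_", cp)
        if (!rid %in% names(sim$regions)) next
        ids <- geneTable(sim$regions[[rid]])$gene_id
        expect_false(paste(sp, cp, losses$gene[i], sep = "_") %in% ids,
                     info = paste(seed, rid, losses$gene[i]))
      }
    }
  }
})

test_that("microsynteny extraction recovers the simulated truth", {
  tr <- figTeleostTree()
  for (seed in 1:25) {
    cfg <- simulationConfig(lossProb = 0.25, inversionProb = 0.15,
                            seed = 1000 + seed)
    sim <- simulateWgdDataset(cfg, sequences = "none")
    ref <- sim$regions$gar_c1
    anc <- truthAnchors(sim)
    panel <- geneTable(ref)$gene_id
    m <- extractMicrosynteny(panel, sim$regions, anc, ref,
                             boundaryUnknown = FALSE)
    st <- stateMatrix(m)
    panelOf <- vapply(strsplit(panel, "_"), function(p) p[length(p)],
                      character(1))
    for (i in seq_len(nrow(st))) {
      rid <- m@regionIds[i]
      truthGenes <- vapply(strsplit(geneTable(sim$regions[[rid]])$gene_id,
                                    "_"),
                           function(p) p[length(p)], character(1))
      expect_identical(unname(st[i, ]) == "P",
                       panelOf %in% truthGenes, info = paste(seed, rid))
    }
  }
})

test_that("copy labelling may swap copies but states match some pairing", {
  # with heavy loss the per-species #1/#2 labels are assigned by
  # completeness; event counting is label-agnostic, which the scenario
  # recovery test exercises end to end
  sim <- simulateWgdDataset(simulationConfig(lossProb = 0.4, seed = 77),
                            sequences = "none")
  expect_true(all(grepl("_c[12]$", names(sim$regions))))
})

test_that("codon-mode sequences contain no stops and translate cleanly", {
  cfg <- simulationConfig(panelSize = 4, lossProb = 0.1, seed = 13,
                          omega = 0.5)
  sim <- simulateWgdDataset(cfg, sequences = "codon")
  expect_gt(length(sim$cds), 0)
  aa <- as.character(sim$proteins)
  expect_false(any(grepl("[*X]", aa)))
  # nucleotide mode translates with X in place of incidental stops
  simN <- simulateWgdDataset(cfg, sequences = "nucleotide")
  expect_false(any(grepl("\\*", as.character(simN$proteins))))
})

test_that("sequence-based anchoring recovers the truth anchors", {
  cfg <- simulationConfig(panelSize = 5, lossProb = 0.2, seed = 19,
                          tree = scenarioTree())
  sim <- simulateWgdDataset(cfg, sequences = "codon")
  ref <- sim$regions$gar_c1
  qid <- setdiff(names(sim$regions), "gar_c1")[1]
  qry <- sim$regions[[qid]]
  refProt <- sim$proteins[geneTable(ref)$gene_id]
  qryProt <- sim$proteins[geneTable(qry)$gene_id]
  rbh <- reciprocalBestHits(refProt, qryProt, minIdentity = 40)
  want <- truthAnchors(sim)
  want <- want[want$gene_b %in% names(qryProt), ]
  expect_identical(rbh$gene_a[order(rbh$gene_a)],
                   want$gene_a[order(want$gene_a)])
  expect_identical(rbh$gene_b[order(rbh$gene_a)],
                   want$gene_b[order(want$gene_a)])
})

test_that("neutral codon evolution yields window dN/dS near one", {
  set.seed(149)
  md <- codonSubstitutionModel(kappa = 2, omega = 1)
  P <- transitionProb(md, 1.0)
  ratios <- unlist(lapply(1:5, function(k) {
    anc <- sample.int(length(md@states), 1000, TRUE, prob = md@freqs)
    der <- vapply(anc, function(s) sample.int(length(md@states), 1,
                                              prob = P[s, ]), integer(1))
    scan <- slidingDnds(c(a = paste(md@states[anc], collapse = ""),
                          b = paste(md@states[der], collapse = "")))
    scan$ratio
  }))
  expect_gt(mean(ratios, na.rm = TRUE), 0.8)
  expect_lt(mean(ratios, na.rm = TRUE), 1.2)
})
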