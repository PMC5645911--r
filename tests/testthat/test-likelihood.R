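test_that("star tree with zero branch lengths and identical sequences gives L*log(1/4)", {
  jc <- substitutionModel("JC69")
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln <- geneAlignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                       "dna")
  expect_equal(treeLogLik(tr, aln, jc), 8 * log(0.25), tolerance = 1e-10)
})

test_that("two-taxon JC likelihood matches the closed form", {
  jc <- substitutionModel("JC69")
  set.seed(83)
  for (rep in 1:10) {
    t <- runif(1, 0.01, 1.5)
    tr <- ape::read.tree(text = "(a:1,b:1);")
    tr$edge.length <- c(t / 2, t / 2)
    L <- 40
    a <- sample(c("A", "C", "G", "T"), L, TRUE)
    b <- sample(c("A", "C", "G", "T"), L, TRUE)
    aln <- geneAlignment(rbind(a = a, b = b) |>
                           (\(m) {rownames(m) <- c("a", "b"); m})(), "dna")
    nSame <- sum(a == b)
    pSame <- 0.25 * (0.25 + 0.75 * exp(-4 * t / 3))
    pDiff <- 0.25 * (0.25 - 0.25 * exp(-4 * t / 3))
    closed <- nSame * log(pSame) + (L - nSame) * log(pDiff)
    expect_equal(treeLogLik(tr, aln, jc), closed, tolerance = 1e-8)
  }
})

test_that("pruning likelihood equals exhaustive state summation (DNA and RY)", {
  set.seed(89)
  for (rep in 1:10) {
    tr <- ape::rtree(4)
    md <- substitutionModel("GTR", rates = runif(6, 0.5, 3),
                            baseFreqs = c(.3, .2, .2, .3))
    aln <- simAlignment(tr, 15, md, seed = rep)
    expect_equal(treeLogLik(tr, aln, md), oracleLnL(tr, aln, md),
                 tolerance = 1e-8)
  }
  # binary RY alphabet
  ry <- substitutionModel("RY", baseFreqs = c(.6, .4))
  for (rep in 1:5) {
    tr <- ape::rtree(4)
    aln <- simAlignment(tr, 15, ry, seed = 100 + rep)
    expect_equal(treeLogLik(tr, aln, ry), oracleLnL(tr, aln, ry),
                 tolerance = 1e-8)
  }
})

test_that("gamma rate mixtures average the exhaustive per-category likelihoods", {
  set.seed(97)
  tr <- ape::rtree(4)
  md <- substitutionModel("HKY", kappa = 3, baseFreqs = c(.28, .22, .22, .28),
                          gammaShape = 0.7, nCat = 4)
  md0 <- substitutionModel("HKY", kappa = 3, baseFreqs = c(.28, .22, .22, .28))
  aln <- simAlignment(tr, 12, md0, seed = 5)
  rates <- discreteGammaRates(0.7, 4)
  expect_equal(mean(rates), 1, tolerance = 1e-12)
  perCat <- vapply(rates, function(r) {
    tr2 <- tr; tr2$edge.length <- tr$edge.length * r
    vapply(seq_len(12), function(site)
      oracleLnL(tr2, paralogon:::.sliceAlignment(aln, site), md0),
      numeric(1))
  }, numeric(12))
  manual <- sum(log(rowMeans(exp(perCat))))
  expect_equal(treeLogLik(tr, aln, md), manual, tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting and OTU row order", {
  set.seed(101)
  tr <- ape::rtree(6)
  md <- substitutionModel("K2P", kappa = 2.5)
  aln <- simAlignment(tr, 50, md, seed = 9)
  base <- treeLogLik(tr, aln, md)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                        resolve.root = TRUE)
  expect_equal(treeLogLik(rerooted, aln, md), base, tolerance = 1e-6)
  perm <- sample(nrow(alignmentMatrix(aln)))
  aln2 <- geneAlignment(alignmentMatrix(aln)[perm, , drop = FALSE], "dna")
  expect_equal(treeLogLik(tr, aln2, md), base, tolerance = 1e-10)
})

test_that("gaps and ambiguity codes act as missing data", {
  jc <- substitutionModel("JC69")
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  full <- geneAlignment(c(a = "A", b = "-"), "dna")
  # one informative taxon: likelihood is the stationary frequency
  expect_equal(treeLogLik(tr, full, jc), log(0.25), tolerance = 1e-10)
  amb <- geneAlignment(c(a = "R", b = "A"), "dna")
  hardA <- treeLogLik(tr, geneAlignment(c(a = "A", b = "A"), "dna"), jc)
  hardG <- treeLogLik(tr, geneAlignment(c(a = "G", b = "A"), "dna"), jc)
  expect_equal(exp(treeLogLik(tr, amb, jc)), exp(hardA) + exp(hardG),
               tolerance = 1e-12)
})

test_that("likelihood agrees with an independent implementation (phangorn)", {
  skip_if_not_installed("phangorn")
  set.seed(103)
  tr <- ape::rtree(7)
  m <- matrix(sample(c("A", "C", "G", "T"), 7 * 80, TRUE), 7,
              dimnames = list(tr$tip.label, NULL))
  aln <- geneAlignment(m, "dna")
  fr <- c(.31, .19, .22, .28); rt <- c(1.2, 3.1, 0.8, 1.1, 2.7, 1)
  md <- substitutionModel("GTR", rates = rt, baseFreqs = fr,
                          gammaShape = 0.6, nCat = 4)
  ref <- phangorn::pml(tr, phangorn::phyDat(m), model = "GTR", bf = fr,
                       Q = rt, shape = 0.6, k = 4)$logLik
  expect_equal(treeLogLik(tr, aln, md), ref, tolerance = 1e-8)
})

test_that("branch-length optimization is monotone and finds truth at long L", {
  jc <- substitutionModel("JC69")
  # identical sequences: optimal branch length 0
  tr <- ape::read.tree(text = "(a:0.3,b:0.2);")
  same <- geneAlignment(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"), "dna")
  o <- optimizeBranchLengths(tr, same, jc)
  expect_lt(sum(o$edge.length), 1e-4)
  # lnL never decreases relative to the start
  set.seed(107)
  tr4 <- ape::rtree(4)
  aln <- simAlignment(tr4, 60, jc, seed = 2)
  before <- treeLogLik(tr4, aln, jc)
  o2 <- optimizeBranchLengths(tr4, aln, jc)
  expect_gte(attr(o2, "logLik"), before)
  # long simulated alignment recovers the generating lengths
  truth <- ape::read.tree(text = "((a:0.12,b:0.18):0.07,(c:0.15,d:0.1):0.07);")
  big <- simAlignment(truth, 12000, jc, seed = 3)
  o3 <- optimizeBranchLengths(truth, big, jc)
  matched <- o3$edge.length[match(
    paste(truth$edge[, 1], truth$edge[, 2]),
    paste(o3$edge[, 1], o3$edge[, 2]))]
  expect_equal(matched, truth$edge.length, tolerance = 0.25)
})
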