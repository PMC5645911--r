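mkPanelRegion <- function(id, sp, genes, spacing = 10000, glen = 1000,
                          strands = NULL, length = NULL) {
  n <- length(genes)
  starts <- seq(spacing, by = spacing + glen, length.out = n)
  Region(id, sp, data.frame(
    gene_id = genes, start = starts, end = starts + glen - 1,
    strand = if (is.null(strands)) rep("+", n) else strands),
    length = length)
}

test_that("microsynteny extraction records presence, rank and orientation", {
  panel <- paste0("g", 1:6)
  ref <- mkPanelRegion("ref", "gar", panel)
  # target keeps g2, g4, g5; g4 inverted; order preserved
  tgt <- mkPanelRegion("t1", "eel", c("t_g2", "t_g4", "t_g5"),
                       strands = c("+", "-", "+"))
  anc <- data.frame(gene_a = c("g2", "g4", "g5"),
                    gene_b = c("t_g2", "t_g4", "t_g5"))
  m <- extractMicrosynteny(panel, list(ref, tgt), anc, ref,
                           boundaryUnknown = FALSE)
  expect_identical(unname(stateMatrix(m)[2, ]),
                   c("A", "P", "A", "P", "P", "A"))
  expect_identical(unname(rankMatrix(m)[2, c("g2", "g4", "g5")]), 1:3)
  expect_identical(unname(orientationMatrix(m)[2, c("g2", "g4", "g5")]),
                   c("+", "-", "+"))
  # reference row is all-present in panel order
  expect_true(all(stateMatrix(m)[1, ] == "P"))
  expect_identical(unname(rankMatrix(m)[1, ]), 1:6)
})

test_that("a region with no anchors yields an all-absent row", {
  panel <- paste0("g", 1:4)
  ref <- mkPanelRegion("ref", "gar", panel)
  lone <- mkPanelRegion("t0", "eel", c("x1", "x2"))
  m <- extractMicrosynteny(panel, list(ref, lone),
                           data.frame(gene_a = character(),
                                      gene_b = character()), ref)
  expect_true(all(stateMatrix(m)[2, ] == "A"))
})

test_that("duplicate anchors of one panel gene in one region are an error", {
  panel <- paste0("g", 1:3)
  ref <- mkPanelRegion("ref", "gar", panel)
  tgt <- mkPanelRegion("t1", "eel", c("a", "b"))
  anc <- data.frame(gene_a = c("g1", "g1"), gene_b = c("a", "b"))
  expect_error(extractMicrosynteny(panel, list(ref, tgt), anc, ref),
               "more than once")
})

test_that("absences beyond a terminal gene near the region edge become unknown", {
  panel <- paste0("g", 1:5)
  ref <- mkPanelRegion("ref", "gar", panel)
  # region ends right after g4's ortholog: g5 may lie beyond the boundary
  tgt <- mkPanelRegion("t1", "eel", c("t_g2", "t_g3", "t_g4"),
                       length = 34000)
  anc <- data.frame(gene_a = c("g2", "g3", "g4"),
                    gene_b = c("t_g2", "t_g3", "t_g4"))
  m <- extractMicrosynteny(panel, list(ref, tgt), anc, ref,
                           boundaryUnknown = TRUE, edgeMargin = 5000)
  st <- stateMatrix(m)[2, ]
  expect_identical(unname(st), c("A", "P", "P", "P", "U"))
  # same data with the flag off: plain absent
  m2 <- extractMicrosynteny(panel, list(ref, tgt), anc, ref,
                            boundaryUnknown = FALSE)
  expect_identical(unname(stateMatrix(m2)[2, "g5"]), "A")
})

test_that("copy labels default to #1 for the more complete region per species", {
  panel <- paste0("g", 1:4)
  ref <- mkPanelRegion("ref", "gar", panel)
  big <- mkPanelRegion("eelB", "eel", c("b1", "b2", "b3"))
  small <- mkPanelRegion("eelS", "eel", "s1")
  anc <- data.frame(gene_a = c("g1", "g2", "g3", "g2"),
                    gene_b = c("b1", "b2", "b3", "s1"))
  m <- extractMicrosynteny(panel, list(ref, small, big), anc, ref,
                           boundaryUnknown = FALSE)
  expect_identical(copyLabels(m)[match(c("eelB", "eelS"), m@regionIds)],
                   c("#1", "#2"))
})

test_that("order conservation equals the exhaustive LCS oracle", {
  panel <- paste0("g", 1:8)
  set.seed(13)
  for (i in 1:20) {
    nPres <- sample(0:8, 1)
    pres <- sort(sample(8, nPres))
    genes <- if (nPres > 0)
      data.frame(gene = panel[pres], state = "P", rank = sample(nPres),
                 orientation = "+")
    else NULL
    rows <- list(list(species = "sp", copy = "#1", genes = genes))
    m <- presenceOrderMatrix(panel, rows)
    obs <- paralogon:::.presentInOrder(m, 1)
    expect_identical(orderConservation(m, 1), oracleLcs(obs, panel))
  }
})

test_that("order conservation attains the present count iff order is conserved", {
  panel <- paste0("g", 1:6)
  inOrder <- presenceOrderMatrix(panel, list(list(
    species = "s", copy = "#1",
    genes = data.frame(gene = panel, state = "P", rank = 1:6,
                       orientation = "+"))))
  expect_identical(orderConservation(inOrder, 1), 6L)
  swapped <- presenceOrderMatrix(panel, list(list(
    species = "s", copy = "#1",
    genes = data.frame(gene = panel, state = "P",
                       rank = c(1, 2, 4, 3, 5, 6), orientation = "+"))))
  expect_identical(orderConservation(swapped, 1), 5L)
})

test_that("shared loss patterns match brute force on random matrices", {
  set.seed(29)
  panel <- paste0("g", 1:6)
  for (rep in 1:15) {
    m <- randomMatrix(panel, c("sp1", "sp2"), pPresent = 0.55,
                      pUnknown = 0.1)
    tpl <- tryCatch(minimalDuplicatedSegment(m), error = function(e) NULL)
    if (is.null(tpl)) next
    got <- sharedLossPattern(m, c("sp1", "sp2"))
    st <- stateMatrix(m)
    ix <- function(sp, cp) which(rowSpecies(m) == sp & copyLabels(m) == cp)
    want <- panel[vapply(seq_along(panel), function(j) {
      a <- c(st[ix("sp1", "#1"), j], st[ix("sp1", "#2"), j])
      b <- c(st[ix("sp2", "#1"), j], st[ix("sp2", "#2"), j])
      !any(c(a, b) == "U") && identical(a, b) && sum(a == "A") == 1 &&
        panel[j] %in% tpl
    }, logical(1))]
    expect_identical(got, want)
  }
})

test_that("identical full retention gives an empty shared-loss set", {
  panel <- paste0("g", 1:4)
  rows <- lapply(c("sp1", "sp1", "sp2", "sp2"), function(sp)
    list(species = sp, copy = NULL,
         genes = data.frame(gene = panel, state = "P", rank = 1:4,
                            orientation = "+")))
  for (i in seq_along(rows)) rows[[i]]$copy <- c("#1", "#2")[(i - 1) %% 2 + 1]
  m <- presenceOrderMatrix(panel, rows)
  expect_identical(sharedLossPattern(m, c("sp1", "sp2")), character(0))
})

test_that("presence matrix TSV round-trips", {
  m <- emitFixtureMatrix()
  f <- tempfile(fileext = ".tsv")
  writePresenceMatrix(m, f)
  back <- readPresenceMatrix(f)
  expect_identical(stateMatrix(back), stateMatrix(m))
  expect_identical(rankMatrix(back), rankMatrix(m))
  expect_identical(orientationMatrix(back), orientationMatrix(m))
  expect_identical(copyLabels(back), copyLabels(m))
})
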