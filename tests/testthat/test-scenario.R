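test_that("minimal duplicated segment equals a brute-force window scan", {
  set.seed(37)
  panel <- paste0("g", 1:9)
  for (rep in 1:20) {
    m <- randomMatrix(panel, c("sp1", "sp2"), pPresent = 0.5)
    st <- stateMatrix(m)[copyLabels(m) == "#2", , drop = FALSE]
    presAny <- apply(st == "P", 2, any)
    if (!any(presAny)) {
      expect_error(minimalDuplicatedSegment(m), "no duplication evidence")
      next
    }
    got <- minimalDuplicatedSegment(m)
    # oracle: smallest window covering all #2-present genes
    best <- NULL
    for (i in seq_along(panel)) for (j in i:length(panel)) {
      if (all(which(presAny) >= i & which(presAny) <= j)) {
        if (is.null(best) || (j - i) < (best[2] - best[1])) best <- c(i, j)
      }
    }
    expect_identical(got, panel[best[1]:best[2]])
  }
  one <- presenceOrderMatrix(panel, list(list(
    species = "s", copy = "#2",
    genes = data.frame(gene = "g5", state = "P", rank = 1,
                       orientation = "+"))))
  expect_identical(minimalDuplicatedSegment(one), "g5")
})

test_that("Dollo loss counting handles the simple cases", {
  tr <- readSpeciesTree("(((a,b),(c,d)),e);")
  org <- length(tr$tip.label) + 1L  # root
  allP <- setNames(rep("present", 5), letters[1:5])
  expect_identical(dolloLossCount(tr, org, allP), 0L)
  one <- allP; one[["c"]] <- "absent"
  expect_identical(dolloLossCount(tr, org, one), 1L)
  # absences covering a clade cost one event
  clade <- allP; clade[c("a", "b")] <- "absent"
  expect_identical(dolloLossCount(tr, org, clade), 1L)
  # unknown tips are free
  unk <- allP; unk[["a"]] <- "absent"; unk[["b"]] <- "unknown"
  expect_identical(dolloLossCount(tr, org, unk), 1L)
  expect_error(
    dolloLossCount(tr, ape::getMRCA(tr, c("a", "b")),
                   c(a = "present", e = "present")),
    "model violation")
})

test_that("Dollo DP equals exhaustive enumeration on random instances", {
  set.seed(53)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    origin <- n + 1L
    states <- setNames(sample(c("present", "absent", "unknown"), n, TRUE,
                              prob = c(.45, .45, .1)), tr$tip.label)
    expect_identical(dolloLossCount(tr, origin, states),
                     as.integer(oracleDollo(tr, origin, states)),
                     info = paste("rep", rep))
  }
})

test_that("resolving an unknown tip as absent never decreases the loss count", {
  set.seed(59)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(c("present", "absent", "unknown"), n, TRUE),
                       tr$tip.label)
    free <- names(states)[states == "unknown"]
    if (!length(free)) next
    before <- dolloLossCount(tr, n + 1L, states)
    states[[sample(free, 1)]] <- "absent"
    expect_gte(dolloLossCount(tr, n + 1L, states), before)
  }
})

fixtureSetup <- function() {
  list(m = emitFixtureMatrix(), tree = scenarioTree(),
       s1 = duplicationScenario("single-WGD", list(c("eel", "arowana"))),
       s2 = duplicationScenario("independent", list("eel", "arowana")))
}

test_that("scenario totals on the observed matrix are 6 versus 11 events", {
  fx <- fixtureSetup()
  e1 <- scenarioTotalEvents(fx$s1, fx$m, fx$tree)
  expect_identical(nDuplications(e1), 1L)
  expect_identical(nLosses(e1), 5L)
  expect_identical(totalEvents(e1), 6L)
  d <- attr(e1, "lossDetail")
  # shared ancestral losses counted once; rho lost only in arowana #2
  expect_setequal(d$gene, c("pphln1", "rho", "adamts9", "slc2a9l1", "psmd6"))
  e2 <- scenarioTotalEvents(fx$s2, fx$m, fx$tree)
  expect_identical(nDuplications(e2), 2L)
  expect_identical(nLosses(e2), 9L)
  expect_identical(totalEvents(e2), 11L)
  # full retention: only the duplication event itself
  panel <- rhoPanel()
  rows <- list(
    list(species = "eel", copy = "#1",
         genes = data.frame(gene = panel, state = "P", rank = 1:11,
                            orientation = "+")),
    list(species = "eel", copy = "#2",
         genes = data.frame(gene = panel, state = "P", rank = 1:11,
                            orientation = "+")),
    list(species = "arowana", copy = "#1",
         genes = data.frame(gene = panel, state = "P", rank = 1:11,
                            orientation = "+")),
    list(species = "arowana", copy = "#2",
         genes = data.frame(gene = panel, state = "P", rank = 1:11,
                            orientation = "+")))
  full <- presenceOrderMatrix(panel, rows)
  eFull <- scenarioTotalEvents(fx$s1, full, fx$tree)
  expect_identical(totalEvents(eFull), 1L)
})

test_that("scenario totals equal the brute-force loss-placement oracle", {
  fx <- fixtureSetup()
  expect_identical(totalEvents(scenarioTotalEvents(fx$s1, fx$m, fx$tree)),
                   as.integer(oracleScenarioTotal(fx$s1, fx$m, fx$tree)))
  expect_identical(totalEvents(scenarioTotalEvents(fx$s2, fx$m, fx$tree)),
                   as.integer(oracleScenarioTotal(fx$s2, fx$m, fx$tree)))
  set.seed(61)
  for (rep in 1:10) {
    m <- randomMatrix(rhoPanel(), c("eel", "arowana"), pPresent = 0.6)
    ok <- tryCatch({minimalDuplicatedSegment(m); TRUE},
                   error = function(e) FALSE)
    if (!ok) next
    for (s in list(fx$s1, fx$s2))
      expect_identical(totalEvents(scenarioTotalEvents(s, m, fx$tree)),
                       as.integer(oracleScenarioTotal(s, m, fx$tree)))
  }
})

test_that("scenario totals are invariant to matrix row order", {
  fx <- fixtureSetup()
  m <- fx$m
  perm <- c(3, 5, 1, 2, 4)
  m2 <- presenceOrderMatrix(panelGenes(m), lapply(perm, function(i) {
    st <- stateMatrix(m)[i, ]
    keep <- st != "A"
    list(species = rowSpecies(m)[i], copy = copyLabels(m)[i],
         genes = data.frame(gene = panelGenes(m)[keep], state = st[keep],
                            rank = rankMatrix(m)[i, keep],
                            orientation = orientationMatrix(m)[i, keep]))
  }))
  expect_identical(totalEvents(scenarioTotalEvents(fx$s1, m2, fx$tree)),
                   totalEvents(scenarioTotalEvents(fx$s1, fx$m, fx$tree)))
})

test_that("scenario ranking prefers the single WGD and reports strictness", {
  fx <- fixtureSetup()
  r <- rankScenarios(list(fx$s1, fx$s2), fx$m, fx$tree)
  expect_identical(r$best, "single-WGD")
  expect_true(r$strictlyBest)
  expect_identical(r$ranking$total, c(6L, 11L))
  # single candidate is trivially best
  r1 <- rankScenarios(list(fx$s2), fx$m, fx$tree)
  expect_identical(r1$best, "independent")
  # ranking equals recomputation order on random matrices
  set.seed(67)
  for (rep in 1:5) {
    m <- randomMatrix(rhoPanel(), c("eel", "arowana"), pPresent = 0.6)
    ok <- tryCatch({minimalDuplicatedSegment(m); TRUE},
                   error = function(e) FALSE)
    if (!ok) next
    r <- rankScenarios(list(fx$s1, fx$s2), m, fx$tree)
    t1 <- oracleScenarioTotal(fx$s1, m, fx$tree)
    t2 <- oracleScenarioTotal(fx$s2, m, fx$tree)
    expect_identical(r$best,
                     if (t2 < t1) "independent" else "single-WGD")
  }
})

test_that("Dollo violations flag regains and are empty on the fixture", {
  fx <- fixtureSetup()
  expect_identical(nrow(dolloViolations(fx$s1, fx$m, fx$tree)), 0L)
  # a gene present on copy #2 outside the template requires a regain
  panel <- rhoPanel()
  rows <- list(
    list(species = "eel", copy = "#1",
         genes = data.frame(gene = panel, state = "P", rank = 1:11,
                            orientation = "+")),
    list(species = "eel", copy = "#2",
         genes = data.frame(gene = c("magi1", "thoc7"), state = "P",
                            rank = 1:2, orientation = "+")),
    list(species = "arowana", copy = "#1",
         genes = data.frame(gene = panel, state = "P", rank = 1:11,
                            orientation = "+")),
    list(species = "arowana", copy = "#2",
         genes = data.frame(gene = "magi1", state = "P", rank = 1,
                            orientation = "+")))
  m <- presenceOrderMatrix(panel, rows)
  s <- duplicationScenario("wgd", list(c("eel", "arowana")),
                           template = c("magi1", "rho"))
  v <- dolloViolations(s, m, fx$tree)
  expect_identical(v$gene, "thoc7")
  # all-present matrix with a full template: consistent
  full <- presenceOrderMatrix(panel, rows[c(1, 3)])
  sFull <- duplicationScenario("wgd", list(c("eel", "arowana")),
                               template = panel)
  expect_identical(nrow(dolloViolations(sFull, full, fx$tree)), 0L)
})

test_that("scenario YAML and report JSON round-trip the key fields", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scenarios:",
    "  - name: single-WGD",
    "    placements:",
    "      - [eel, arowana]",
    "  - name: independent",
    "    placements:",
    "      - [eel]",
    "      - [arowana]",
    "    template: [magi1, rho, adamts9]"), f)
  sc <- readScenarios(f)
  expect_length(sc, 2L)
  expect_identical(sc[[1]]@name, "single-WGD")
  expect_identical(sc[[2]]@placements, list("eel", "arowana"))
  expect_identical(sc[[2]]@template, c("magi1", "rho", "adamts9"))
  fx <- fixtureSetup()
  r <- rankScenarios(list(fx$s1, fx$s2), fx$m, fx$tree)
  fj <- tempfile(fileext = ".json")
  writeScenarioReport(r, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_identical(back$best, "single-WGD")
  expect_identical(back$ranking$total, c(6L, 11L))
})
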