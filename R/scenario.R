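#' Construct a duplication scenario
#'
#' @param name scenario label.
#' @param placements list of character vectors; each names the tip set of
#'   the clade below a duplication branch (a single tip names a terminal
#'   branch).
#' @param template optional explicit template (panel genes duplicated at
#'   each placement); empty means infer with
#'   [minimalDuplicatedSegment()].
#' @return a [DuplicationScenario-class].
#' @examples
#' wgd <- duplicationScenario("single-WGD", list(c("eel", "arowana")))
#' indep <- duplicationScenario("independent", list("eel", "arowana"))
#' @export
duplicationScenario <- function(name, placements, template = character()) {
  if (is.character(placements)) placements <- list(placements)
  new("DuplicationScenario", name = name, placements = placements,
      template = template)
}

setMethod("show", "DuplicationScenario", function(object) {
  pl <- vapply(object@placements, function(p)
    paste0("{", paste(p, collapse = ","), "}"), character(1))
  cat(sprintf("DuplicationScenario '%s': %d duplication(s) on %s\n",
              object@name, length(object@placements),
              paste(pl, collapse = " and ")))
  if (length(object@template))
    cat("  template:", paste(object@template, collapse = " "), "\n")
})

#' Construct an event count
#'
#' @param nDuplications,nLosses non-negative integers.
#' @return an [EventCount-class] with `total` filled in.
#' @export
eventCount <- function(nDuplications, nLosses) {
  new("EventCount", nDuplications = as.integer(nDuplications),
      nLosses = as.integer(nLosses),
      total = as.integer(nDuplications + nLosses))
}

setMethod("show", "EventCount", function(object) {
  cat(sprintf("EventCount: %d duplication(s) + %d loss(es) = %d events\n",
              object@nDuplications, object@nLosses, object@total))
})

#' @describeIn EventCount-class total number of events
#' @param x an `EventCount`
#' @export
setGeneric("totalEvents", function(x) standardGeneric("totalEvents"))
#' @export
setMethod("totalEvents", "EventCount", function(x) x@total)
#' @describeIn EventCount-class number of duplications
#' @export
setGeneric("nDuplications", function(x) standardGeneric("nDuplications"))
#' @export
setMethod("nDuplications", "EventCount", function(x) x@nDuplications)
#' @describeIn EventCount-class number of losses
#' @export
setGeneric("nLosses", function(x) standardGeneric("nLosses"))
#' @export
setMethod("nLosses", "EventCount", function(x) x@nLosses)

#' Minimal duplicated segment ("template")
#'
#' The smallest contiguous interval of the panel order containing every
#' gene observed as present on any copy-#2 row of any species.  Genes
#' inside the interval but absent from all #2 rows are implied losses;
#' genes outside the interval were never duplicated and incur no events.
#'
#' @param m a [PresenceOrderMatrix-class] with at least one `#2` row.
#' @param copy copy label of the duplicated rows (default `"#2"`).
#' @return character vector: the contiguous panel interval.
#' @export
minimalDuplicatedSegment <- function(m, copy = "#2") {
  rows <- which(m@copy == copy)
  if (!length(rows)) stop("no duplication evidence: no ", copy, " rows")
  present <- apply(m@states[rows, , drop = FALSE] == "P", 2, any)
  if (!any(present)) stop("no duplication evidence: no gene present on any ",
                          copy, " row")
  idx <- range(which(present))
  m@panel[idx[1]:idx[2]]
}

## ---- Dollo loss counting -------------------------------------------------

.childrenOf <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

.cladeTips <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    for (c in .childrenOf(tree, v)) {
      if (c <= nTip) out <- c(out, tree$tip.label[c]) else stack <- c(stack, c)
    }
  }
  out
}

#' Find the node subtending a clade named by its tip set
#' @keywords internal
.nodeForTips <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("unknown tip(s): ", paste(miss, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  node <- ape::getMRCA(tree, tips)
  if (!setequal(.cladeTips(tree, node), tips))
    stop("tips {", paste(tips, collapse = ","),
         "} do not form a clade in the tree")
  node
}

#' Dollo-minimal loss count for one gene copy
#'
#' Given a rooted species tree, the branch on which a gene copy
#' originated, and present/absent/unknown states at the tips below that
#' branch, returns the minimal number of loss events explaining the
#' absences.  A loss event is clade-wide (Dollo irreversibility): one
#' event removes the copy from an entire descendant subtree, and a copy
#' once lost is never regained.  Unknown tips are unconstrained and are
#' resolved in whichever direction minimizes events.
#'
#' The minimum equals the number of maximal present-free subtrees (below
#' the origin) that contain at least one absent tip; it is computed by a
#' post-order dynamic program and verified against exhaustive enumeration
#' in the test suite.
#'
#' @param tree rooted [ape::phylo] species tree.
#' @param origin the origin branch, named by the tip set of its clade
#'   (character) or by a node number.
#' @param states named character vector (`"present"`/`"absent"`/
#'   `"unknown"`), names = tips below the origin.  Tips of the clade not
#'   named are treated as `"unknown"`.
#' @return integer: minimal number of loss events.
#' @export
dolloLossCount <- function(tree, origin, states) {
  node <- if (is.character(origin)) .nodeForTips(tree, origin)
          else as.integer(origin)
  clade <- .cladeTips(tree, node)
  outside <- setdiff(names(states)[states == "present"], clade)
  if (length(outside))
    stop("model violation: tip(s) present outside the origin clade: ",
         paste(outside, collapse = ", "))
  full <- stats::setNames(rep("unknown", length(clade)), clade)
  known <- intersect(names(states), clade)
  full[known] <- states[known]
  nTip <- length(tree$tip.label)
  # postorder walk returning (presentFree, hasAbsent, losses-below)
  walk <- function(v) {
    if (v <= nTip) {
      st <- full[[tree$tip.label[v]]]
      return(list(pf = st != "present", ab = st == "absent", n = 0L))
    }
    kids <- lapply(.childrenOf(tree, v), walk)
    pf <- all(vapply(kids, `[[`, logical(1), "pf"))
    ab <- any(vapply(kids, `[[`, logical(1), "ab"))
    if (pf) return(list(pf = TRUE, ab = ab, n = 0L))
    n <- 0L
    for (k in kids)
      n <- n + if (k$pf) as.integer(k$ab) else k$n
    list(pf = FALSE, ab = ab, n = n)
  }
  res <- walk(node)
  if (res$pf) as.integer(res$ab) else res$n
}

## ---- scenario scoring ----------------------------------------------------

.copyLineageStates <- function(m, species, copy, gene) {
  st <- vapply(species, function(sp) {
    i <- which(m@species == sp & m@copy == copy)
    if (!length(i)) return("absent")              # whole region unobserved
    c(P = "present", A = "absent", U = "unknown")[[m@states[i[1], gene]]]
  }, character(1))
  stats::setNames(st, species)
}

#' Total event count for a duplication scenario
#'
#' Events = number of duplication placements + Dollo-minimal losses summed
#' over every (copy lineage x template gene) column.  Each placement
#' creates two copy lineages (`#1`, `#2`) over its clade; tip states for a
#' column come from the matrix rows of the species below the placement.
#' Species below a placement with no row for a copy contribute `absent`
#' states.  Unknown states contribute no losses when resolving them as
#' present is cheaper.  Genes outside the template incur no events.
#'
#' @param scenario a [DuplicationScenario-class].
#' @param m a [PresenceOrderMatrix-class].
#' @param tree rooted [ape::phylo]; tips must cover the matrix species.
#' @param copies copy labels created by each placement (default
#'   `c("#1", "#2")`).
#' @return an [EventCount-class]; the per-column loss counts are attached
#'   as attribute `"lossDetail"`.
#' @export
scenarioTotalEvents <- function(scenario, m, tree, copies = c("#1", "#2")) {
  template <- if (length(scenario@template)) scenario@template
              else minimalDuplicatedSegment(m)
  losses <- 0L
  detail <- list()
  for (pl in scenario@placements) {
    node <- .nodeForTips(tree, pl)
    below <- .cladeTips(tree, node)
    for (cp in copies) for (g in template) {
      st <- .copyLineageStates(m, below, cp, g)
      nl <- dolloLossCount(tree, node, st)
      losses <- losses + nl
      if (nl > 0)
        detail[[length(detail) + 1L]] <- data.frame(
          placement = paste(pl, collapse = ","), copy = cp, gene = g,
          losses = nl, stringsAsFactors = FALSE)
    }
  }
  out <- eventCount(length(scenario@placements), losses)
  attr(out, "lossDetail") <- if (length(detail)) do.call(rbind, detail)
    else data.frame(placement = character(), copy = character(),
                    gene = character(), losses = integer())
  out
}

#' Rank candidate duplication scenarios by parsimony
#'
#' Scenarios are ordered by ascending total events; ties are broken by
#' fewer duplications (a genome-wide duplication is a rarer event than a
#' gene loss), then by input order.
#'
#' @param candidates list of [DuplicationScenario-class].
#' @param m a [PresenceOrderMatrix-class].
#' @param tree rooted [ape::phylo].
#' @param ... passed to [scenarioTotalEvents()].
#' @return list with `ranking` (data.frame `name`, `n_duplications`,
#'   `n_losses`, `total` in rank order), `best` (name of the top
#'   scenario), `strictlyBest` (logical: top total strictly lower than the
#'   runner-up), and `events` (named list of [EventCount-class]).
#' @export
rankScenarios <- function(candidates, m, tree, ...) {
  stopifnot(length(candidates) >= 1L)
  ev <- lapply(candidates, scenarioTotalEvents, m = m, tree = tree, ...)
  names(ev) <- vapply(candidates, function(s) s@name, character(1))
  tot <- vapply(ev, totalEvents, integer(1))
  dup <- vapply(ev, nDuplications, integer(1))
  ord <- order(tot, dup, seq_along(ev))
  ranking <- data.frame(
    name = names(ev)[ord], n_duplications = dup[ord],
    n_losses = vapply(ev, nLosses, integer(1))[ord], total = tot[ord],
    stringsAsFactors = FALSE, row.names = NULL)
  strictly <- length(ev) == 1L || ranking$total[1] < ranking$total[2]
  list(ranking = ranking, best = ranking$name[1], strictlyBest = strictly,
       events = ev[ord])
}

#' Dollo-consistency check of a matrix under a scenario
#'
#' Lists genes whose tip states would require a regained copy under the
#' scenario: a gene present on a duplicated `#2` row but outside the
#' scenario's template (the duplication never copied it), or any copy row
#' with a present gene in a species that does not descend from a
#' duplication placement.  Copy `#1` is by convention the
#' ancestral-collinear region and may carry single-copy genes outside the
#' template.  An empty result means the matrix is consistent with the
#' scenario.
#'
#' @inheritParams scenarioTotalEvents
#' @return data.frame `gene`, `row`, `description` (zero rows when
#'   consistent).
#' @export
dolloViolations <- function(scenario, m, tree, copies = c("#1", "#2")) {
  template <- if (length(scenario@template)) scenario@template
              else minimalDuplicatedSegment(m)
  below <- unique(unlist(lapply(scenario@placements, function(pl)
    .cladeTips(tree, .nodeForTips(tree, pl)))))
  out <- list()
  for (i in seq_len(nrow(m@states))) {
    pres <- m@panel[m@states[i, ] == "P"]
    rowLab <- rownames(m@states)[i]
    if (m@copy[i] == copies[2]) {
      if (!m@species[i] %in% below) {
        for (g in pres)
          out[[length(out) + 1L]] <- data.frame(
            gene = g, row = rowLab,
            description = "duplicated copy present in a species outside every duplication placement",
            stringsAsFactors = FALSE)
      }
      for (g in setdiff(pres, template))
        out[[length(out) + 1L]] <- data.frame(
          gene = g, row = rowLab,
          description = "present on copy #2 outside the duplicated template (would require a regain)",
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene = character(), row = character(),
                  description = character(), stringsAsFactors = FALSE)
}

#' Read duplication scenarios from YAML
#'
#' Expected structure: a top-level `scenarios` list (or a bare list), each
#' element with fields `name`, `placements` (list of tip-label lists) and
#' optional `template`.
#'
#' @param path YAML file.
#' @return list of [DuplicationScenario-class].
#' @export
readScenarios <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenarios)) y <- y$scenarios
  lapply(y, function(s) {
    duplicationScenario(
      name = s$name,
      placements = lapply(s$placements, unlist),
      template = if (is.null(s$template)) character() else unlist(s$template))
  })
}

#' Write a scenario-ranking report as JSON
#'
#' @param ranked output of [rankScenarios()].
#' @param path output file.
#' @export
writeScenarioReport <- function(ranked, path) {
  rep <- list(
    ranking = ranked$ranking, best = ranked$best,
    strictly_best = ranked$strictlyBest,
    loss_detail = lapply(ranked$events, function(e) attr(e, "lossDetail")))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
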