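#' The 11-gene rhodopsin-region reference panel
#'
#' The genes surrounding *rho* on spotted-gar linkage group 5, in genomic
#' order, used as the microsynteny reference panel.
#'
#' @return character vector of 11 gene names.
#' @export
rhoPanel <- function() {
  c("lrig1", "slc25a26", "magi1", "rho", "adamts9", "prickle2", "pphln1",
    "slc2a9l1", "psmd6", "atxn7", "thoc7")
}

#' The observed rhodopsin-region microsynteny matrix
#'
#' The presence/order matrix of the 11-gene panel across the spotted-gar
#' reference region and the two synteny copies (#1, #2) of Japanese eel
#' and Asian arowana:
#' \itemize{
#'   \item gar: all 11 genes, panel order;
#'   \item eel #1 (the ds-rho region): all genes except *pphln1*;
#'   \item eel #2 (the fw-rho region): *magi1*, *rho*, *prickle2*,
#'     *pphln1*, *atxn7*; *atxn7* lies at the scaffold end, so the
#'     absence of *thoc7* is unknown (`U`);
#'   \item arowana #1: same pattern as eel #1;
#'   \item arowana #2: *magi1*, *prickle2*, *pphln1*, *atxn7* (no *rho*).
#' }
#'
#' @return a [PresenceOrderMatrix-class] with 5 rows and 11 panel genes.
#' @export
emitFixtureMatrix <- function() {
  panel <- rhoPanel()
  inPanelOrder <- function(genes) {
    g <- genes[order(match(genes, panel))]
    data.frame(gene = g, state = "P", rank = seq_along(g),
               orientation = "+", stringsAsFactors = FALSE)
  }
  eel2 <- inPanelOrder(c("magi1", "rho", "prickle2", "pphln1", "atxn7"))
  eel2 <- rbind(eel2, data.frame(gene = "thoc7", state = "U",
                                 rank = NA_integer_,
                                 orientation = NA_character_))
  presenceOrderMatrix(panel, list(
    list(species = "gar", copy = "#1", regionId = "gar_LG5",
         genes = inPanelOrder(panel)),
    list(species = "eel", copy = "#1", regionId = "eel_scaffold3",
         genes = inPanelOrder(setdiff(panel, "pphln1"))),
    list(species = "eel", copy = "#2", regionId = "eel_scaffold435",
         genes = eel2),
    list(species = "arowana", copy = "#1", regionId = "arowana_scaffold133",
         genes = inPanelOrder(setdiff(panel, "pphln1"))),
    list(species = "arowana", copy = "#2", regionId = "arowana_scaffold11",
         genes = inPanelOrder(c("magi1", "prickle2", "pphln1", "atxn7")))))
}

#' The three-lineage species tree used for scenario comparison
#'
#' Eel and arowana diverged at the base of the teleosts, with gar
#' (Holostei) as the pre-duplication outgroup.
#'
#' @return an [ape::phylo].
#' @export
scenarioTree <- function() {
  ape::read.tree(text = "((eel:0.30,arowana:0.28):0.10,gar:0.35);")
}
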