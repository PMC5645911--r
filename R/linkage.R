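#' Assign scaffolds to linkage groups from marker hits
#'
#' Reproduces the marker-based linkage-group assignment rule used for
#' anchoring scaffolds to a genetic map: hits below the identity threshold
#' are dropped first, then markers matching two or more scaffolds are
#' excluded, and each scaffold is assigned the linkage group named by its
#' surviving markers.  Scaffolds whose surviving markers name two or more
#' linkage groups are flagged `"split-required"` (the scaffold should be
#' split between groups), with the supporting markers reported.
#'
#' The result is independent of the input hit order and the operation is
#' idempotent.
#'
#' @param hits data.frame with columns `marker_id`, `scaffold_id`,
#'   `identity` (percent in \[0,100\]) and `linkage_group`.
#' @param minIdentity identity threshold; hits with `identity < minIdentity`
#'   are dropped (default 90, i.e. keep identity >= 90%).
#' @return list with elements
#'   \describe{
#'     \item{assignments}{data.frame `scaffold_id`, `linkage_group`
#'       (`NA` when split is required), `status`
#'       (`"assigned"`/`"split-required"`), `n_markers`.}
#'     \item{excludedMarkers}{markers dropped for hitting >= 2 scaffolds.}
#'     \item{markerDetail}{per-scaffold data.frame of surviving markers and
#'       their linkage groups.}
#'   }
#' @export
assignLinkageGroups <- function(hits, minIdentity = 90) {
  empty <- list(
    assignments = data.frame(scaffold_id = character(),
                             linkage_group = character(),
                             status = character(), n_markers = integer(),
                             stringsAsFactors = FALSE),
    excludedMarkers = character(),
    markerDetail = list())
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  stopifnot(all(c("marker_id", "scaffold_id", "identity", "linkage_group")
                %in% names(hits)))
  if (any(hits$identity < 0 | hits$identity > 100))
    stop("identity must be within [0, 100]")
  # identity threshold applied before the uniqueness test
  hits <- hits[hits$identity >= minIdentity, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  nScaf <- tapply(hits$scaffold_id, hits$marker_id,
                  function(s) length(unique(s)))
  multi <- sort(names(nScaf)[nScaf >= 2L])
  hits <- hits[!hits$marker_id %in% multi, , drop = FALSE]
  scafs <- sort(unique(hits$scaffold_id))
  detail <- lapply(scafs, function(s) {
    d <- hits[hits$scaffold_id == s, c("marker_id", "linkage_group"),
              drop = FALSE]
    d[order(d$marker_id), , drop = FALSE]
  })
  names(detail) <- scafs
  lg <- vapply(detail, function(d) {
    u <- unique(d$linkage_group)
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  status <- ifelse(is.na(lg), "split-required", "assigned")
  list(
    assignments = data.frame(
      scaffold_id = scafs, linkage_group = unname(lg),
      status = unname(status),
      n_markers = vapply(detail, nrow, integer(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE),
    excludedMarkers = multi,
    markerDetail = detail)
}

#' Validate predicted gene models by length agreement
#'
#' A predicted sequence is kept when its length differs from the reference
#' by strictly less than `maxRelDiff` of the reference length:
#' `|len_pred - len_ref| / len_ref < maxRelDiff`.  A difference of exactly
#' 5% is rejected under the default threshold.
#'
#' @param predicted,reference `XStringSet` sequence stores.
#' @param pairs data.frame with columns `pred_id`, `ref_id`.
#' @param maxRelDiff relative length difference threshold (default 0.05).
#' @return character vector of validated predicted ids.
#' @export
filterByLengthAgreement <- function(predicted, reference, pairs,
                                    maxRelDiff = 0.05) {
  stopifnot(all(c("pred_id", "ref_id") %in% names(pairs)))
  missP <- setdiff(pairs$pred_id, names(predicted))
  missR <- setdiff(pairs$ref_id, names(reference))
  if (length(missP) || length(missR))
    stop("unresolvable ids: ", paste(c(missP, missR), collapse = ", "))
  lp <- Biostrings::width(predicted)[match(pairs$pred_id, names(predicted))]
  lr <- Biostrings::width(reference)[match(pairs$ref_id, names(reference))]
  if (any(lr == 0)) stop("zero-length reference sequence(s): ",
                         paste(pairs$ref_id[lr == 0], collapse = ", "))
  keep <- abs(lp - lr) / lr < maxRelDiff
  pairs$pred_id[keep]
}
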