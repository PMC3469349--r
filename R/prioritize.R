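#' Union of model feature sets
#'
#' Collapses the typically many models collected in one search into the
#' unique set of features they contain, the first prioritisation step.
#'
#' @param models List of models from [ga_search()].
#' @return Character vector of distinct features, in first-seen order.
#' @export
consolidate_models <- function(models) {
  if (!length(models)) stopf("no models to consolidate")
  unique(unlist(lapply(models, `[[`, "features"), use.names = FALSE))
}

#' Cluster-bifurcation qualification of a feature set
#'
#' The algorithmic form of heat-map screening: samples of the slice,
#' restricted to the candidate features, are clustered by agglomerative
#' hierarchical clustering (average linkage, euclidean sample distance by
#' default); the candidate qualifies only if cutting the dendrogram into
#' exactly two clusters reproduces the treated/control partition exactly —
#' complete separation of the classes into two distinct clusters.
#'
#' Euclidean distance is the default because it aggregates between-class
#' separation directly over the feature set; 1 - Pearson-correlation
#' distance is available but over feature sets of classifier size
#' (5-100 features) between-sample correlation estimates carry sampling
#' noise of order 1/sqrt(features), which makes the exact-partition
#' criterion erratic.
#'
#' Degenerate inputs (a zero-variance sample vector, or fewer than two
#' features, under correlation distance) are unqualified with the reason
#' recorded in the `reason` attribute, not an error.
#'
#' @param feature_set Character vector of probe ids.
#' @param study An [expression_study()].
#' @param slice A [condition_slice()].
#' @param linkage,distance Clustering choices (defaults `"average"`,
#'   `"euclidean"`; `"correlation"` also supported).
#' @return `TRUE` or `FALSE` (with attribute `reason` when degenerate).
#' @export
qualify_by_bifurcation <- function(feature_set, study, slice,
                                   linkage = "average",
                                   distance = c("euclidean", "correlation")) {
  stopifnot(length(feature_set) > 0)
  distance <- match.arg(distance)
  rows <- match(feature_set, rownames(study$values))
  if (anyNA(rows)) stopf("feature set contains probes absent from the study")
  cols <- c(slice$treated, slice$control)
  sub <- study$values[rows, cols, drop = FALSE]
  if (distance == "correlation") {
    if (nrow(sub) < 2)
      return(structure(FALSE, reason = "fewer than 2 features: correlation undefined"))
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0))
      return(structure(FALSE, reason = "zero-variance sample vector under the feature set"))
    d <- as.dist(1 - cor(sub))
  } else {
    d <- stats::dist(t(sub))
  }
  cl <- cutree(hclust(d, method = linkage), k = 2)
  treated <- cols %in% slice$treated
  length(unique(cl[treated])) == 1 && length(unique(cl[!treated])) == 1 &&
    cl[treated][1] != cl[!treated][1]
}

#' Remove features shared across conditions
#'
#' Every feature appearing in two or more candidates' sets is removed from
#' all of them (not all-but-one): a feature responsive to multiple chemicals
#' makes a classifier less condition-specific in field deployment. Output
#' sets are pairwise disjoint; a candidate emptied by deduplication is
#' retained with an empty set and flagged.
#'
#' @param candidates Named list of candidate classifiers, each a list with
#'   at least `condition` and `features`.
#' @return The list with shared features removed; emptied candidates carry
#'   `emptied = TRUE`.
#' @export
deduplicate_across_conditions <- function(candidates) {
  if (!length(candidates)) stopf("no candidates to deduplicate")
  all_feats <- unlist(lapply(candidates, function(c) unique(c$features)),
                      use.names = FALSE)
  shared <- unique(all_feats[duplicated(all_feats)])
  lapply(candidates, function(cand) {
    cand$features <- setdiff(cand$features, shared)
    cand$emptied <- length(cand$features) == 0
    cand
  })
}

#' Rank features by network count and truncate to the cap
#'
#' Features are sorted by descending count of networks in which they were
#' selected into a model, ties broken by descending within-network selection
#' frequency (number of models containing the feature) then ascending
#' feature id; the first `cap` features form the classifier.
#'
#' @param candidate A candidate classifier (list with `features`).
#' @param network_counts Named integer vector: networks per feature. Must
#'   cover every feature of the candidate.
#' @param selection_freq Optional named integer vector: models per feature
#'   (tie-break); missing entries count 0.
#' @param cap Maximum classifier size (default 100).
#' @return The candidate with `features` ranked and truncated, and
#'   `truncated` flag set.
#' @export
rank_and_truncate <- function(candidate, network_counts, selection_freq = NULL,
                              cap = 100) {
  feats <- candidate$features
  if (!all(feats %in% names(network_counts)))
    stopf("network_counts missing for feature(s): %s",
          paste(head(setdiff(feats, names(network_counts))), collapse = ", "))
  counts <- network_counts[feats]
  freq <- if (is.null(selection_freq)) rep(0L, length(feats))
          else ifelse(feats %in% names(selection_freq), selection_freq[feats], 0L)
  ord <- order(-counts, -freq, feats)
  candidate$features <- feats[ord][seq_len(min(cap, length(feats)))]
  candidate$truncated <- length(feats) > cap
  candidate
}

#' Per-feature network-selection counts from batch search results
#'
#' For one condition, counts for each feature the number of networks in
#' which it was selected into at least one collected model, and the total
#' number of models containing it (the ranking tie-break).
#'
#' @param batch_result One condition's entry of [batch_network_search()]
#'   output (a named list network -> model list).
#' @param qualified_networks Optional character vector restricting the count
#'   to networks whose consolidated set qualified.
#' @return List with named integer vectors `network_counts` and
#'   `selection_freq`.
#' @export
network_selection_counts <- function(batch_result, qualified_networks = NULL) {
  nets <- names(batch_result)
  if (!is.null(qualified_networks)) nets <- intersect(nets, qualified_networks)
  per_net_feats <- lapply(nets, function(net)
    unique(unlist(lapply(batch_result[[net]], `[[`, "features"), use.names = FALSE)))
  net_tab <- table(unlist(per_net_feats, use.names = FALSE))
  model_feats <- unlist(lapply(nets, function(net)
    unlist(lapply(batch_result[[net]], `[[`, "features"), use.names = FALSE)),
    use.names = FALSE)
  freq_tab <- table(model_feats)
  list(network_counts = setNames(as.integer(net_tab), names(net_tab)),
       selection_freq = setNames(as.integer(freq_tab), names(freq_tab)))
}

#' Export qualified candidates as a gene set collection
#'
#' One gene set per condition; members are gene symbols where a mapping is
#' supplied, original probe ids otherwise. The set description records the
#' condition's tissue so validation can enforce same-tissue pairing. Empty
#' candidates are skipped.
#'
#' @param candidates Named list of candidate classifiers (each with
#'   `condition`, `tissue`, `features`).
#' @param symbol_map Optional named character vector probe id -> gene symbol.
#' @return A [gene_set_collection()].
#' @export
export_gene_sets <- function(candidates, symbol_map = NULL) {
  keep <- Filter(function(c) length(c$features) > 0, candidates)
  if (!length(keep)) stopf("no non-empty candidates to export")
  sets <- lapply(keep, function(cand) {
    if (is.null(symbol_map)) return(cand$features)
    mapped <- symbol_map[cand$features]
    unique(ifelse(is.na(mapped), cand$features, mapped))
  })
  names(sets) <- vapply(keep, `[[`, "", "condition")
  desc <- vapply(keep, function(c) c$tissue %||% "", "")
  gene_set_collection(sets, desc)
}
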