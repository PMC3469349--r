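#' Rank features by a two-class metric
#'
#' Default metric is signal-to-noise: (mu_treated - mu_control) /
#' (sd_treated + sd_control), with each class SD floored at
#' `max(sd, 0.2 * |mu|, 0.2)` to guard near-constant features. Features are
#' sorted by descending metric; ties break by ascending feature id, so the
#' order is deterministic.
#'
#' @param study An [expression_study()].
#' @param slice A [condition_slice()]; both classes need >= 2 samples.
#' @param sd_floor_frac,sd_floor_abs Floor parameters (defaults 0.2, 0.2).
#' @return An object of class `ranked_list`: list with `feature` (ordered
#'   ids) and `metric` (ordered values).
#' @export
rank_genes <- function(study, slice, sd_floor_frac = 0.2, sd_floor_abs = 0.2) {
  stopifnot(inherits(study, "expression_study"), inherits(slice, "condition_slice"))
  if (length(slice$treated) < 2 || length(slice$control) < 2)
    stopf("condition %s: each class needs >= 2 samples", slice$id)
  s2n <- signal_to_noise(study$values, slice$treated, slice$control,
                         sd_floor_frac, sd_floor_abs)
  ord <- order(-s2n, rownames(study$values))
  structure(list(feature = rownames(study$values)[ord],
                 metric = unname(s2n[ord])),
            class = "ranked_list")
}

signal_to_noise <- function(values, treated, control, frac = 0.2, abs_floor = 0.2) {
  x1 <- values[, treated, drop = FALSE]; x2 <- values[, control, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  s1 <- sqrt(rowSums((x1 - mu1)^2) / (ncol(x1) - 1))
  s2 <- sqrt(rowSums((x2 - mu2)^2) / (ncol(x2) - 1))
  s1 <- pmax(s1, frac * abs(mu1), abs_floor)
  s2 <- pmax(s2, frac * abs(mu2), abs_floor)
  (mu1 - mu2) / (s1 + s2)
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, the running sum increments at members of
#' the gene set ("hits") proportionally to `|metric|^p` (normalised so hit
#' increments total 1) and decrements by `1/(N - |S|)` at non-members. The
#' enrichment score is the signed maximum deviation from zero; `|ES| <= 1`.
#' At `p = 0` this is the classic unweighted Kolmogorov-Smirnov-style
#' statistic.
#'
#' @param ranked A `ranked_list` from [rank_genes()].
#' @param gene_set Character vector of member ids; must intersect the list.
#' @param p Metric weight exponent (default 1).
#' @return List with `es` and `running` (the full running-sum profile).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$feature %in% gene_set
  n <- length(hit); nh <- sum(hit)
  if (nh == 0)
    stopf("gene set has empty intersection with the ranked list")
  if (nh == n) stopf("gene set covers the entire ranked list")
  w <- abs(ranked$metric)^p
  wh <- w[hit]
  steps <- numeric(n)
  if (sum(wh) > 0) steps[hit] <- wh / sum(wh) else steps[hit] <- 1 / nh
  steps[!hit] <- -1 / (n - nh)
  running <- cumsum(steps)
  # signed maximum deviation; when the positive and negative extremes tie in
  # magnitude (common at p = 0, where steps are rational), prefer the
  # positive one so the statistic is deterministic
  mx <- max(running); mn <- min(running)
  es <- if (mx >= -mn) mx else mn
  list(es = es, running = running)
}

permute_slices <- function(slice, n_perm, seed) {
  cols <- c(slice$treated, slice$control)
  n <- length(cols); n1 <- length(slice$treated)
  n_distinct <- choose(n, n1)
  if (n_distinct <= n_perm) {
    picks <- utils::combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    picks <- lapply(seq_len(n_perm), function(b) sort(sample(n, n1)))
  }
  lapply(picks, function(ix)
    condition_slice(slice$chemical, slice$tissue,
                    cols[ix], cols[-ix], n_arrays = slice$n_arrays))
}

#' Phenotype-permutation significance, NES and FDR for gene sets
#'
#' Class labels of the slice are permuted (all distinct assignments are
#' enumerated exactly when fewer than `n_perm` exist); for each permutation
#' the ranking metric and each set's enrichment score are recomputed.
#' Nominal p is conditional on the observed sign with an add-one guard:
#' `(1 + same-sign permutations at least as extreme) / (1 + same-sign
#' permutations)`. NES divides each score by the mean same-sign permutation
#' score of its set; the FDR q compares the observed NES to the pooled
#' permutation NES distribution over all sets.
#'
#' @param study An [expression_study()].
#' @param slice A [condition_slice()].
#' @param gene_sets A [gene_set_collection()] (sets with empty intersection
#'   are reported with `NA` scores and a warning-free skip).
#' @param n_perm Number of label permutations (default 1000).
#' @param p Weight exponent passed to [enrichment_score()] (default 1).
#' @param q_threshold FDR threshold for the enriched flag (default 0.25).
#' @param direction `"two_sided"` (default) flags any set with `q` below the
#'   threshold; `"positive"` additionally requires `es > 0` — the diagnostic
#'   reading in classifier validation, where a match means the signature is
#'   coordinately elevated in the treated class, not depleted from it.
#' @param seed Integer seed (permutation draws are deterministic given it).
#' @return Data frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p_value`, `fdr_q`, `enriched`.
#' @export
permutation_significance <- function(study, slice, gene_sets, n_perm = 1000,
                                     p = 1, q_threshold = 0.25,
                                     direction = c("two_sided", "positive"),
                                     seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (length(slice$treated) < 2 || length(slice$control) < 2)
    stopf("phenotype permutation needs >= 2 samples per class")
  ranked <- rank_genes(study, slice)
  sets <- gene_sets$sets
  usable <- vapply(sets, function(s) any(ranked$feature %in% s) &&
                     !all(ranked$feature %in% s), TRUE)
  obs_es <- rep(NA_real_, length(sets))
  obs_es[usable] <- vapply(sets[usable],
                           function(s) enrichment_score(ranked, s, p)$es, 0)

  slices_b <- permute_slices(slice, n_perm, derive_seed(seed, "gsea_perm", slice$id))
  B <- length(slices_b)
  perm_es <- matrix(NA_real_, length(sets), B)
  for (b in seq_len(B)) {
    rb <- rank_genes(study, slices_b[[b]])
    perm_es[usable, b] <- vapply(sets[usable],
                                 function(s) enrichment_score(rb, s, p)$es, 0)
  }

  nes <- rep(NA_real_, length(sets)); pval <- rep(NA_real_, length(sets))
  n_same <- rep(NA_integer_, length(sets))
  perm_nes <- matrix(NA_real_, length(sets), B)
  for (i in which(usable)) {
    es_i <- obs_es[i]; pe <- perm_es[i, ]
    pos_mean <- mean(pe[pe >= 0]); neg_mean <- mean(abs(pe[pe < 0]))
    same_sign <- if (es_i >= 0) pe[pe >= 0] else pe[pe < 0]
    # conditional on sign, with an add-one guard: dividing the same-sign
    # extreme count by the total permutation count would be anti-conservative
    # by roughly the fraction of opposite-sign permutations
    n_same[i] <- length(same_sign)
    pval[i] <- (1 + sum(abs(same_sign) >= abs(es_i))) / (1 + length(same_sign))
    denom <- if (es_i >= 0) pos_mean else neg_mean
    if (!is.finite(denom) || denom == 0) denom <- mean(abs(pe))
    nes[i] <- es_i / denom
    perm_nes[i, ] <- ifelse(pe >= 0,
                            pe / (if (is.finite(pos_mean) && pos_mean > 0) pos_mean else denom),
                            pe / (if (is.finite(neg_mean) && neg_mean > 0) neg_mean else denom))
  }

  pool <- perm_nes[usable, , drop = FALSE]
  obs_pool <- nes[usable]
  fdr <- rep(NA_real_, length(sets))
  for (i in which(usable)) {
    n_i <- nes[i]
    if (n_i >= 0) {
      num_den <- sum(pool >= 0)
      num <- if (num_den > 0) sum(pool >= n_i) / num_den else 0
      den_den <- sum(obs_pool >= 0)
      den <- if (den_den > 0) sum(obs_pool >= n_i) / den_den else 1
    } else {
      num_den <- sum(pool < 0)
      num <- if (num_den > 0) sum(pool <= n_i) / num_den else 0
      den_den <- sum(obs_pool < 0)
      den <- if (den_den > 0) sum(obs_pool <= n_i) / den_den else 1
    }
    fdr[i] <- min(1, if (den > 0) num / den else 1)
  }

  enriched <- !is.na(fdr) & fdr < q_threshold
  if (direction == "positive") enriched <- enriched & !is.na(obs_es) & obs_es > 0
  data.frame(set = names(sets), size = lengths(sets), es = obs_es, nes = nes,
             p_value = pval, n_same_sign = n_same, fdr_q = fdr,
             enriched = enriched,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a classifier collection against expression profiles
#'
#' Every (gene set, GEP) pair sharing a tissue is scored by
#' [permutation_significance()]; cross-tissue pairs are never scored. When a
#' probe cross-mapping is supplied the set members are translated first via
#' [translate_gene_sets()]. Each report row carries the GEP's condition
#' F-ratio from the complexity module.
#'
#' @param gene_sets A [gene_set_collection()] whose descriptions are tissue
#'   labels (as written by [export_gene_sets()]).
#' @param geps List of GEPs, each a list with `study`, `slice`, and
#'   optionally `name` (defaults to the slice condition id) and `tissue`
#'   (defaults to the slice tissue).
#' @param crossmap Optional probe mapping from [match_probes()].
#' @param n_perm,p,q_threshold,seed Passed to [permutation_significance()].
#' @param direction Enrichment direction for the flag; defaults to
#'   `"positive"` here (a classifier diagnoses a GEP when its signature is
#'   elevated in the treated class).
#' @return Data frame: `gep`, `tissue`, `f_ratio`, `set`, `size`, `es`,
#'   `nes`, `p_value`, `fdr_q`, `enriched`.
#' @export
validate_collection <- function(gene_sets, geps, crossmap = NULL,
                                n_perm = 1000, p = 1, q_threshold = 0.25,
                                direction = "positive", seed = 1L) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (!is.null(crossmap)) gene_sets <- translate_gene_sets(gene_sets, crossmap)
  rows <- list()
  any_pair <- FALSE
  for (g in geps) {
    tissue <- g$tissue %||% g$slice$tissue
    name <- g$name %||% g$slice$id
    keep <- names(gene_sets$sets)[gene_sets$description == tissue &
                                    lengths(gene_sets$sets) > 0]
    if (!length(keep)) next
    any_pair <- TRUE
    sub <- gene_set_collection(gene_sets$sets[keep], gene_sets$description[keep])
    fr <- condition_complexity(fisher_ratio_per_feature(g$study, g$slice))$value
    res <- permutation_significance(g$study, g$slice, sub, n_perm = n_perm,
                                    p = p, q_threshold = q_threshold,
                                    direction = direction,
                                    seed = derive_seed(seed, "validate", name))
    res <- cbind(data.frame(gep = name, tissue = tissue, f_ratio = fr,
                            stringsAsFactors = FALSE), res)
    rows[[name]] <- res
  }
  if (!any_pair) stopf("no same-tissue (gene set, GEP) pairs to score")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
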