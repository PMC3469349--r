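#' Specify one synthetic chemical-tissue condition
#'
#' @param chemical,tissue Condition labels.
#' @param n_treated,n_control Samples per class (each >= 2).
#' @param planted Integer feature indices carrying the treatment effect
#'   (may be empty for a null condition).
#' @param delta Effect size: mean shift of planted features in treated
#'   samples, in units of the within-class SD. Non-negative.
#' @return A list describing the condition, consumed by [simulation_params()].
#' @export
sim_condition <- function(chemical, tissue, n_treated, n_control,
                          planted = integer(), delta = 0) {
  if (n_treated < 2 || n_control < 2)
    stopf("condition %s.%s: each class needs >= 2 samples", chemical, tissue)
  if (delta < 0) stopf("effect size delta must be >= 0")
  list(chemical = chemical, tissue = tissue,
       n_treated = as.integer(n_treated), n_control = as.integer(n_control),
       planted = as.integer(planted), delta = delta)
}

#' Parameters for the synthetic study generator
#'
#' Defines a multi-condition two-class log2-intensity study with planted
#' differentially expressed features of controlled effect size, emulating the
#' structure of a multi-chemical, multi-tissue exposure experiment: each
#' condition contributes paired treated/control samples hybridised two to an
#' array, and transcription-factor network structure plus dual probe designs
#' are generated alongside with recorded ground truth.
#'
#' @param n_features Number of probes on the simulated array.
#' @param conditions List of [sim_condition()] specifications. The default is
#'   a miniature multi-condition design: three chemical-tissue conditions at
#'   10 treated vs 10 control, with signal planted in the first two.
#' @param within_class_sd Within-class standard deviation on the log2 scale.
#' @param baseline_mean Mean baseline log2 intensity.
#' @param baseline_feature_sd Between-feature SD of baseline intensity
#'   (default 1.5). Real log-intensity data shows large between-gene
#'   baseline variation; without it all samples are mutually uncorrelated
#'   and correlation-based sample clustering is meaningless. Planted
#'   features take baselines above `baseline_mean` (a detectable shift
#'   presupposes an expressed gene), so they survive intensity filtering.
#' @param sd_heterogeneity Log-normal spread of per-feature SDs (0 = shared
#'   SD across features; exposed because across-gene variance heterogeneity
#'   is a property of real data the default does not assert).
#' @param n_networks Number of regular gene networks to generate.
#' @param network_size_range Length-2 integer vector, inclusive size bounds.
#' @param planted_in_network_fraction Fraction of each condition's planted
#'   features guaranteed to appear in at least one network.
#' @param seed Integer seed; identical params + seed reproduce every artifact.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_features = 2000,
                              conditions = default_conditions(n_features),
                              within_class_sd = 1,
                              baseline_mean = 8,
                              baseline_feature_sd = 1.5,
                              sd_heterogeneity = 0,
                              n_networks = 20,
                              network_size_range = c(20, 50),
                              planted_in_network_fraction = 1,
                              seed = 1L) {
  if (n_features < 1) stopf("n_features must be positive")
  if (within_class_sd <= 0) stopf("within_class_sd must be positive")
  if (sd_heterogeneity < 0) stopf("sd_heterogeneity must be >= 0")
  if (planted_in_network_fraction < 0 || planted_in_network_fraction > 1)
    stopf("planted_in_network_fraction must lie in [0, 1]")
  if (length(network_size_range) != 2 || network_size_range[1] > network_size_range[2])
    stopf("network_size_range must be (min, max) with min <= max")
  for (cond in conditions) {
    if (length(cond$planted) && (min(cond$planted) < 1 || max(cond$planted) > n_features))
      stopf("planted feature ids out of range for %s.%s", cond$chemical, cond$tissue)
  }
  ids <- vapply(conditions, function(c) condition_id(c$chemical, c$tissue), "")
  if (anyDuplicated(ids)) stopf("duplicate chemical-tissue conditions")
  if (baseline_feature_sd < 0) stopf("baseline_feature_sd must be >= 0")
  structure(list(n_features = as.integer(n_features), conditions = conditions,
                 within_class_sd = within_class_sd, baseline_mean = baseline_mean,
                 baseline_feature_sd = baseline_feature_sd,
                 sd_heterogeneity = sd_heterogeneity,
                 n_networks = as.integer(n_networks),
                 network_size_range = as.integer(network_size_range),
                 planted_in_network_fraction = planted_in_network_fraction,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' @rdname simulation_params
#' @export
default_conditions <- function(n_features) {
  # Miniature of a multi-chemical design: signal in two conditions, none in
  # the third, 10 vs 10 samples each (10 arrays -> passes the >= 9-array gate).
  list(
    sim_condition("chemA", "ovary", 10, 10, planted = seq_len(min(5, n_features)), delta = 3),
    sim_condition("chemB", "ovary", 10, 10,
                  planted = seq(6, length.out = min(5, max(0, n_features - 5))), delta = 3),
    sim_condition("chemC", "ovary", 10, 10, planted = integer(), delta = 0)
  )
}

probe_ids_for <- function(n) sprintf("p%05d", seq_len(n))

#' Generate a synthetic expression study with recorded ground truth
#'
#' Within-class values are Gaussian on the log2 scale; planted features of a
#' condition have their treated-class mean shifted by `delta * within_class_sd`.
#' Samples are annotated with chemical, tissue, class, exposure duration
#' (alternating 48/96 h), array id (treated/control pairs share an array) and
#' channel, so the downstream array-count gate and channel bookkeeping can be
#' exercised.
#'
#' @param params A [simulation_params()] object.
#' @return A list with components `study` (an [expression_study()]) and
#'   `truth` (per-condition planted probe ids; network membership and probe
#'   mappings are appended by their own generators).
#' @export
generate_study <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(derive_seed(params$seed, "study"))
  probes <- probe_ids_for(params$n_features)
  feat_sd <- if (params$sd_heterogeneity > 0) {
    params$within_class_sd * exp(stats::rnorm(params$n_features, 0, params$sd_heterogeneity))
  } else rep(params$within_class_sd, params$n_features)
  bdev <- params$baseline_feature_sd %||% 0
  baseline <- params$baseline_mean + bdev * stats::rnorm(params$n_features)
  planted_any <- unique(unlist(lapply(params$conditions, `[[`, "planted")))
  if (length(planted_any))   # planted features are expressed genes
    baseline[planted_any] <- params$baseline_mean +
      bdev * abs(stats::rnorm(length(planted_any)))

  blocks <- list(); annos <- list(); planted_truth <- list()
  for (cond in params$conditions) {
    id <- condition_id(cond$chemical, cond$tissue)
    n <- cond$n_treated + cond$n_control
    vals <- baseline +
      matrix(stats::rnorm(params$n_features * n), params$n_features, n) * feat_sd
    if (length(cond$planted) && cond$delta > 0) {
      shift <- cond$delta * params$within_class_sd
      vals[cond$planted, seq_len(cond$n_treated)] <-
        vals[cond$planted, seq_len(cond$n_treated)] + shift
    }
    cls <- rep(c("treated", "control"), c(cond$n_treated, cond$n_control))
    sample_id <- sprintf("%s.s%02d", id, seq_len(n))
    # pair treated i with control i on one array; leftovers pair within class
    ord <- order(c(seq_len(cond$n_treated), seq_len(cond$n_control)),
                 cls == "control")
    array_no <- integer(n); array_no[ord] <- ceiling(seq_len(n) / 2)
    annos[[id]] <- data.frame(
      sample_id = sample_id, chemical = cond$chemical, tissue = cond$tissue,
      class = cls,
      duration = rep_len(c(48L, 96L), n),
      array_id = sprintf("%s.a%02d", id, array_no),
      channel = rep_len(c("Cy5", "Cy3"), n),
      stringsAsFactors = FALSE)
    colnames(vals) <- sample_id
    blocks[[id]] <- vals
    planted_truth[[id]] <- probes[cond$planted]
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- probes
  samples <- do.call(rbind, c(annos, list(make.row.names = FALSE)))
  list(study = expression_study(values, samples),
       truth = list(planted = planted_truth, networks = NULL, probe_map = NULL))
}

#' Generate gene networks with controlled coverage of planted features
#'
#' Emulates a collection of reverse-engineered transcription-factor networks
#' (a hub plus member genes) used as restricted search spaces. A controlled
#' fraction of each condition's planted features is guaranteed to belong to
#' at least one network; at fraction 0 no network contains any planted
#' feature, so network-restricted search has no recoverable signal.
#'
#' @param params A [simulation_params()] object.
#' @param truth Ground truth from [generate_study()].
#' @param include_special Also emit the two special search spaces modelled on
#'   practice: `master_regulators` (the hub of every network) and `hpg_axis`
#'   (a curated-list stand-in sampled from non-planted features).
#' @return A list with `networks` (a [gene_set_collection()]; the first
#'   member of each regular network is its hub) and `truth` updated with the
#'   membership record.
#' @export
generate_networks <- function(params, truth, include_special = FALSE) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$network_size_range[2] > params$n_features)
    stopf("network_size_range exceeds the number of features")
  set.seed(derive_seed(params$seed, "networks"))
  probes <- probe_ids_for(params$n_features)
  planted_all <- unique(unlist(truth$planted, use.names = FALSE))
  pool <- if (params$planted_in_network_fraction == 0) {
    setdiff(probes, planted_all)
  } else probes

  sizes <- sample(seq(params$network_size_range[1], params$network_size_range[2]),
                  params$n_networks, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(pool, k))
  names(sets) <- sprintf("net%03d", seq_along(sets))

  if (params$planted_in_network_fraction > 0) {
    for (cond_id in names(truth$planted)) {
      planted <- truth$planted[[cond_id]]
      if (!length(planted)) next
      n_cov <- round(params$planted_in_network_fraction * length(planted))
      need <- head(planted, n_cov)
      covered <- unique(unlist(sets, use.names = FALSE))
      for (p in setdiff(need, covered)) {
        j <- sample(length(sets), 1)
        slot <- setdiff(sets[[j]], planted_all)
        if (length(slot)) {
          sets[[j]][match(sample(slot, 1), sets[[j]])] <- p
        } else sets[[j]] <- c(sets[[j]], p)
      }
    }
  }

  desc <- vapply(sets, function(s) s[1], "")  # hub = first member
  if (include_special) {
    hubs <- unique(desc)
    hpg <- sample(setdiff(probes, planted_all),
                  min(params$network_size_range[2], params$n_features %/% 2))
    sets <- c(sets, list(master_regulators = hubs, hpg_axis = hpg))
    desc <- c(desc, master_regulators = "hub_compilation", hpg_axis = "curated_list")
  }
  networks <- gene_set_collection(sets, desc)
  truth$networks <- networks$sets
  list(networks = networks, truth = truth)
}

mutate_sequence <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), min(n_mut, length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

#' Generate two partially overlapping probe designs with known true mapping
#'
#' Emulates two microarray designs sharing a subset of targets, the situation
#' that arises when a validation dataset is profiled on a newer array design
#' than the training data. Shared probe pairs agree by literal sequence
#' identity (optionally degraded by point mutations standing in for
#' alignment-level homology) and/or by genomic coordinate proximity (start
#' positions jittered by at most `coord_jitter_bp`); unique probes have no
#' true partner and act as negative controls.
#'
#' @param n_shared Number of true cross-design probe pairs.
#' @param n_unique_each Probes private to each design.
#' @param probe_len Probe length in nt (>= 20; 60 matches common practice).
#' @param coord_jitter_bp Maximum absolute start-position jitter for design B.
#' @param n_mutations Point mutations applied to design B's copy of each
#'   shared sequence.
#' @param share_mode `"both"` (default): shared pairs agree in sequence and
#'   coordinates; `"sequence"`: sequence only (B placed elsewhere);
#'   `"coordinate"`: coordinates only (B sequence random).
#' @param seed Integer seed.
#' @return A list with `catalog_a`, `catalog_b` ([probe_catalog()] objects)
#'   and `truth` (data frame of true pairs with the applied jitter).
#' @export
generate_probe_designs <- function(n_shared, n_unique_each, probe_len = 60,
                                   coord_jitter_bp = 0, n_mutations = 0,
                                   share_mode = c("both", "sequence", "coordinate"),
                                   seed = 1L) {
  if (probe_len < 20) stopf("probe_len must be >= 20")
  share_mode <- match.arg(share_mode)
  set.seed(derive_seed(seed, "probes"))
  rand_seq <- function(n) {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), probe_len, replace = TRUE), collapse = ""), "")
  }
  n_slots <- n_shared + 2L * n_unique_each + n_shared  # spare slots for "sequence" mode
  chroms <- sprintf("chr%d", ((seq_len(n_slots) - 1L) %% 25L) + 1L)
  starts <- as.integer(1000L + ((seq_len(n_slots) - 1L) %/% 25L) * (20L * probe_len))

  shared_seq <- rand_seq(n_shared)
  jitter <- if (coord_jitter_bp > 0)
    sample(seq(-coord_jitter_bp, coord_jitter_bp), n_shared, replace = TRUE)
  else rep(0L, n_shared)

  slot <- function(i) list(chrom = chroms[i], start = starts[i])
  idx_shared <- seq_len(n_shared)
  idx_ua <- n_shared + seq_len(n_unique_each)
  idx_ub <- n_shared + n_unique_each + seq_len(n_unique_each)
  idx_spare <- n_shared + 2L * n_unique_each + seq_len(n_shared)

  a_ids <- sprintf("A_%04d", seq_len(n_shared + n_unique_each))
  b_ids <- sprintf("B_%04d", seq_len(n_shared + n_unique_each))

  a_seq <- c(shared_seq, rand_seq(n_unique_each))
  b_shared_seq <- if (share_mode == "coordinate") rand_seq(n_shared) else
    vapply(shared_seq, mutate_sequence, "", n_mut = n_mutations)
  b_seq <- c(unname(b_shared_seq), rand_seq(n_unique_each))

  a_slot_idx <- c(idx_shared, idx_ua)
  b_slot_idx <- c(if (share_mode == "sequence") idx_spare else idx_shared, idx_ub)
  b_start <- starts[b_slot_idx]
  if (share_mode != "sequence") b_start[seq_len(n_shared)] <- b_start[seq_len(n_shared)] + jitter

  mk <- function(ids, slot_idx, start, seqs) probe_catalog(data.frame(
    probe_id = ids, chrom = chroms[slot_idx], start = as.integer(start),
    end = as.integer(start + probe_len), strand = "+", sequence = seqs,
    stringsAsFactors = FALSE))

  list(catalog_a = mk(a_ids, a_slot_idx, starts[a_slot_idx], a_seq),
       catalog_b = mk(b_ids, b_slot_idx, b_start, b_seq),
       truth = data.frame(probe_a = a_ids[idx_shared], probe_b = b_ids[seq_len(n_shared)],
                          jitter = jitter, stringsAsFactors = FALSE))
}
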