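#' Configuration for an end-to-end discovery run
#'
#' Bundles per-stage parameters for [run_discovery()]: simulate (or load) a
#' study, preprocess it, characterise condition complexity, search for
#' classifiers transcriptome-wide and within networks, prioritise, and
#' export classifiers as GMT gene sets. A single global `seed`
#' deterministically derives every per-stage, per-condition and per-network
#' seed, so the whole run (and any sub-run) is reproducible.
#'
#' @param out_dir Output directory for all artifacts.
#' @param sim A [simulation_params()] object for synthetic input, or `NULL`
#'   when `files` is given.
#' @param files Optional list with `matrix`, `annotation`, `networks` paths
#'   for file input.
#' @param floor,min_fraction Intensity filter settings (see
#'   [filter_low_intensity()]).
#' @param normalize Quantile-normalize after filtering (default TRUE).
#' @param tissue_mode `"per_tissue"` or `"combined"` (see
#'   [assemble_conditions()]).
#' @param min_arrays Condition sample-size gate (default 9 arrays).
#' @param transcriptome A [search_config()] for the transcriptome-wide scope
#'   (conventionally SVM fitness), or `NULL` to skip the scope.
#' @param network A [search_config()] for the network-restricted scope
#'   (conventionally KNN fitness), or `NULL` to skip.
#' @param cap Classifier size cap (default 100).
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
discovery_config <- function(out_dir, sim = NULL, files = NULL,
                             floor = log2(64), min_fraction = 0.75,
                             normalize = TRUE,
                             tissue_mode = c("per_tissue", "combined"),
                             min_arrays = 9,
                             transcriptome = search_config("svm"),
                             network = search_config("knn"),
                             cap = 100, seed = 1L) {
  tissue_mode <- match.arg(tissue_mode)
  if (is.null(sim) && is.null(files))
    stopf("provide either `sim` (synthetic input) or `files`")
  structure(list(out_dir = out_dir, sim = sim, files = files, floor = floor,
                 min_fraction = min_fraction, normalize = normalize,
                 tissue_mode = tissue_mode, min_arrays = min_arrays,
                 transcriptome = transcriptome, network = network,
                 cap = cap, seed = as.integer(seed)),
            class = "run_config")
}

hash_object <- function(x) {
  f <- tempfile()
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

manifest_row <- function(artifact, path, seed, params_hash) {
  data.frame(artifact = artifact, path = path, md5 = unname(tools::md5sum(path)),
             seed = seed, params_hash = params_hash, stringsAsFactors = FALSE)
}

#' Run discovery end to end
#'
#' Executes preprocess -> condition assembly -> complexity -> GA search
#' (transcriptome and network scopes) -> consolidate / qualify /
#' deduplicate / rank -> GMT export, writing every artifact plus a manifest
#' (with md5 checksums, seeds and a parameter hash) and a structured log of
#' every excluded condition, skipped network, disqualified candidate and
#' dropped feature. Re-running against an existing manifest without
#' `force = TRUE` performs no recomputation.
#'
#' @param config A [discovery_config()].
#' @param force Recompute even if a manifest already exists.
#' @return A list with `manifest`, `study`, `slices`, `complexity`,
#'   `candidates` (per scope), `gene_sets` (per scope), `networks`, `truth`
#'   and `log`. When returning early from an existing manifest, only
#'   `manifest` is populated.
#' @export
run_discovery <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  manifest_path <- file.path(out, "manifest.tsv")
  if (file.exists(manifest_path) && !force)
    return(list(manifest = read.delim(manifest_path, stringsAsFactors = FALSE),
                recomputed = FALSE))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params_hash <- hash_object(config[setdiff(names(config), "out_dir")])
  log_rows <- list()
  note <- function(stage, item, reason)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, item = item, reason = reason, stringsAsFactors = FALSE)

  # ---- input ----
  truth <- NULL; networks <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    gen <- generate_study(sim)
    study <- gen$study; truth <- gen$truth
    nets <- generate_networks(sim, truth, include_special = TRUE)
    networks <- nets$networks; truth <- nets$truth
  } else {
    study <- read_study(config$files$matrix, config$files$annotation)
    if (!is.null(config$files$networks)) networks <- read_gmt(config$files$networks)
  }

  # ---- preprocess ----
  study <- filter_low_intensity(study, config$floor, config$min_fraction)
  if (config$normalize) study <- quantile_normalize(study)
  slices <- assemble_conditions(study, config$min_arrays, config$tissue_mode)
  excl <- attr(slices, "excluded")
  for (i in seq_len(nrow(excl)))
    note("assemble_conditions", excl$condition[i], excl$reason[i])

  # ---- complexity ----
  cx <- complexity_table(study, slices)
  write_tsv(cx, file.path(out, "complexity.tsv"))

  candidates <- list(); gene_sets <- list(); model_rows <- list()

  # ---- transcriptome scope ----
  if (!is.null(config$transcriptome)) {
    cands <- list()
    for (sl in slices) {
      cfg <- config$transcriptome
      cfg$seed <- derive_seed(config$seed, "transcriptome", sl$id)
      models <- ga_search(study, sl, NULL, cfg)
      for (m in seq_along(models))
        model_rows[[length(model_rows) + 1L]] <- data.frame(
          condition = sl$id, scope = "transcriptome", network = "transcriptome",
          model = m, fitness = models[[m]]$fitness,
          features = paste(models[[m]]$features, collapse = ","),
          stringsAsFactors = FALSE)
      if (!length(models)) {
        note("transcriptome_search", sl$id, "no model reached the fitness goal")
        next
      }
      feats <- consolidate_models(models)
      ok <- qualify_by_bifurcation(feats, study, sl)
      if (!isTRUE(ok)) {
        note("qualify", sl$id, attr(ok, "reason") %||% "no two-cluster bifurcation")
        next
      }
      freq <- table(unlist(lapply(models, `[[`, "features"), use.names = FALSE))
      cands[[sl$id]] <- list(condition = sl$id, tissue = sl$tissue,
                             scope = "transcriptome", features = feats,
                             selection_freq = setNames(as.integer(freq), names(freq)),
                             qualified = TRUE)
    }
    if (length(cands)) {
      cands <- deduplicate_across_conditions(cands)
      for (nm in names(cands)) {
        cand <- cands[[nm]]
        if (cand$emptied) { note("deduplicate", nm, "emptied by deduplication"); next }
        ones <- setNames(rep(1L, length(cand$features)), cand$features)
        cands[[nm]] <- rank_and_truncate(cand, ones, cand$selection_freq, config$cap)
      }
      cands <- Filter(function(c) !isTRUE(c$emptied), cands)
    }
    candidates$transcriptome <- cands
    if (length(cands)) {
      gs <- export_gene_sets(cands)
      gene_sets$transcriptome <- gs
      write_gmt(gs, file.path(out, "classifiers_transcriptome.gmt"))
    }
  }

  # ---- network scope ----
  if (!is.null(config$network) && !is.null(networks)) {
    cfg <- config$network
    cfg$seed <- derive_seed(config$seed, "network")
    batch <- batch_network_search(study, slices, networks, cfg)
    skipped <- attr(batch, "skipped")
    for (i in seq_len(nrow(skipped)))
      note("network_search", paste(skipped$condition[i], skipped$network[i]),
           skipped$reason[i])
    cands <- list()
    for (sl in slices) {
      per_net <- batch[[sl$id]]
      qualified_nets <- character()
      for (net in names(per_net)) {
        models <- per_net[[net]]
        for (m in seq_along(models))
          model_rows[[length(model_rows) + 1L]] <- data.frame(
            condition = sl$id, scope = "network", network = net,
            model = m, fitness = models[[m]]$fitness,
            features = paste(models[[m]]$features, collapse = ","),
            stringsAsFactors = FALSE)
        if (!length(models)) next
        feats <- consolidate_models(models)
        if (isTRUE(qualify_by_bifurcation(feats, study, sl)))
          qualified_nets <- c(qualified_nets, net)
        else note("qualify", paste(sl$id, net), "network set not bifurcating")
      }
      if (!length(qualified_nets)) {
        note("network_search", sl$id, "no qualified network classifier")
        next
      }
      counts <- network_selection_counts(per_net, qualified_nets)
      merged <- unique(unlist(lapply(qualified_nets, function(net)
        consolidate_models(per_net[[net]])), use.names = FALSE))
      cands[[sl$id]] <- list(condition = sl$id, tissue = sl$tissue,
                             scope = "network", features = merged,
                             network_counts = counts$network_counts,
                             selection_freq = counts$selection_freq,
                             contributing_networks = qualified_nets,
                             qualified = TRUE)
    }
    if (length(cands)) {
      cands <- deduplicate_across_conditions(cands)
      for (nm in names(cands)) {
        cand <- cands[[nm]]
        if (cand$emptied) { note("deduplicate", nm, "emptied by deduplication"); next }
        cands[[nm]] <- rank_and_truncate(cand, cand$network_counts,
                                         cand$selection_freq, config$cap)
      }
      cands <- Filter(function(c) !isTRUE(c$emptied), cands)
    }
    candidates$network <- cands
    if (length(cands)) {
      gs <- export_gene_sets(cands)
      gene_sets$network <- gs
      write_gmt(gs, file.path(out, "classifiers_network.gmt"))
    }
  }

  # ---- artifacts ----
  models_df <- if (length(model_rows))
    do.call(rbind, c(model_rows, list(make.row.names = FALSE)))
  else data.frame(condition = character(), scope = character(),
                  network = character(), model = integer(), fitness = numeric(),
                  features = character())
  write_tsv(models_df, file.path(out, "models.tsv"))
  log_df <- if (length(log_rows))
    do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  else data.frame(stage = character(), item = character(), reason = character())
  write_tsv(log_df, file.path(out, "run_log.tsv"))

  paths <- c(complexity = file.path(out, "complexity.tsv"),
             models = file.path(out, "models.tsv"),
             run_log = file.path(out, "run_log.tsv"))
  for (scope in names(gene_sets))
    paths[[paste0("classifiers_", scope)]] <-
      file.path(out, sprintf("classifiers_%s.gmt", scope))
  manifest <- do.call(rbind, lapply(names(paths), function(nm)
    manifest_row(nm, paths[[nm]], config$seed, params_hash)))
  write_tsv(manifest, manifest_path)

  list(manifest = manifest, study = study, slices = slices, complexity = cx,
       candidates = candidates, gene_sets = gene_sets, networks = networks,
       truth = truth, log = log_df, recomputed = TRUE)
}

#' Validate exported classifiers on expression profiles
#'
#' Optionally translates set members across array designs, scores every
#' same-tissue (classifier, GEP) pair by phenotype-permutation GSEA, and
#' writes both the full enrichment table and a compact per-GEP report in
#' which each row shows the GEP as `CONDITION (F-ratio)` and its enriched
#' classifiers as `NAME (q)`.
#'
#' @param config A list with `gene_sets` (a [gene_set_collection()]) or
#'   `gmt_path`, `geps` (as for [validate_collection()]), optional
#'   `crossmap`, `n_perm` (default 1000), `q_threshold` (default 0.25),
#'   `seed`, and `out_dir`.
#' @param force Recompute even if a report already exists.
#' @return A list with `report` (full table), `summary` (formatted rows) and
#'   `manifest`.
#' @export
run_validation <- function(config, force = FALSE) {
  out <- config$out_dir
  report_path <- file.path(out, "enrichment_report.tsv")
  manifest_path <- file.path(out, "validation_manifest.tsv")
  if (file.exists(manifest_path) && !force)
    return(list(manifest = read.delim(manifest_path, stringsAsFactors = FALSE),
                recomputed = FALSE))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  gene_sets <- config$gene_sets %||% read_gmt(config$gmt_path)
  report <- validate_collection(gene_sets, config$geps,
                                crossmap = config$crossmap,
                                n_perm = config$n_perm %||% 1000,
                                q_threshold = config$q_threshold %||% 0.25,
                                seed = config$seed %||% 1L)
  write_tsv(report, report_path)
  summary <- format_enrichment_report(report)
  summary_path <- file.path(out, "enrichment_summary.tsv")
  write_tsv(summary, summary_path)
  params_hash <- hash_object(config[setdiff(names(config), c("out_dir", "geps"))])
  manifest <- rbind(manifest_row("enrichment_report", report_path,
                                 config$seed %||% 1L, params_hash),
                    manifest_row("enrichment_summary", summary_path,
                                 config$seed %||% 1L, params_hash))
  write_tsv(manifest, manifest_path)
  list(report = report, summary = summary, manifest = manifest, recomputed = TRUE)
}

#' Compact per-GEP enrichment summary
#'
#' @param report Output of [validate_collection()].
#' @return Data frame with one row per GEP: `gep` formatted as
#'   `CONDITION (F-ratio)` and `enriched_classifiers` as `NAME (q); ...`
#'   (or `"No enrichment"`).
#' @export
format_enrichment_report <- function(report) {
  rows <- lapply(split(report, report$gep), function(df) {
    hit <- df[df$enriched & !is.na(df$fdr_q), , drop = FALSE]
    hit <- hit[order(hit$fdr_q), , drop = FALSE]
    data.frame(
      gep = sprintf("%s (%.2f)", df$gep[1], df$f_ratio[1]),
      enriched_classifiers = if (nrow(hit))
        paste(sprintf("%s (%.3g)", hit$set, hit$fdr_q), collapse = "; ")
      else "No enrichment",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
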