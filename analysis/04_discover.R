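#!/usr/bin/env Rscript
# Search every condition for candidate classifiers: a transcriptome-wide GA
# search per condition plus one GA search per (condition, network) pair.
# KNN fitness is used for both scopes here — the network batch alone is
# dozens of independent searches, and KNN is an order of magnitude cheaper
# per evaluation than SVM while selecting very similar feature sets (the
# SVM path is exercised in the package tests).

library(gaclassify)

seed <- 1L
study <- read_study("results/expression_processed.tsv",
                    "results/annotations_processed.tsv")
slices <- assemble_conditions(study, min_arrays = 9)
networks <- read_gmt("results/data/networks.gmt")

cfg <- search_config("knn", population_size = 30L, max_generations = 60L,
                     n_models_to_collect = 8L, seed = seed)

rows <- list()
for (sl in slices) {
  c1 <- cfg; c1$seed <- derive_seed(seed, "transcriptome", sl$id)
  models <- ga_search(study, sl, NULL, c1)
  cat(sprintf("%s transcriptome: %d model(s)\n", sl$id, length(models)))
  for (i in seq_along(models))
    rows[[length(rows) + 1]] <- data.frame(
      condition = sl$id, scope = "transcriptome", network = "transcriptome",
      model = i, fitness = models[[i]]$fitness,
      features = paste(models[[i]]$features, collapse = ","))
}

batch_cfg <- cfg
batch_cfg$n_models_to_collect <- 4L
batch_cfg$max_generations <- 40L
batch <- batch_network_search(study, slices, networks, batch_cfg)
for (cond in names(batch)) {
  n_models <- sum(lengths(batch[[cond]]))
  n_nets <- sum(lengths(batch[[cond]]) > 0)
  cat(sprintf("%s networks: %d model(s) from %d network(s)\n",
              cond, n_models, n_nets))
  for (net in names(batch[[cond]])) {
    models <- batch[[cond]][[net]]
    for (i in seq_along(models))
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, scope = "network", network = net,
        model = i, fitness = models[[i]]$fitness,
        features = paste(models[[i]]$features, collapse = ","))
  }
}

models_df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.table(models_df, "results/models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
skipped <- attr(batch, "skipped")
if (nrow(skipped)) write.table(skipped, "results/skipped_searches.tsv",
                               sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d models to results/models.tsv\n", nrow(models_df)))
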