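#!/usr/bin/env Rscript
# Turn raw search models into one classifier per condition: per-network
# model unions are screened by the cluster-bifurcation criterion, qualified
# networks are merged, features shared between conditions are removed,
# the rest are ranked by how many networks selected them, capped at 100,
# and exported as GMT gene sets.

library(gaclassify)

study <- read_study("results/expression_processed.tsv",
                    "results/annotations_processed.tsv")
slices <- assemble_conditions(study, min_arrays = 9)
models_df <- read.delim("results/models.tsv", stringsAsFactors = FALSE)
models_df <- models_df[models_df$scope == "network", ]

candidates <- list()
for (sl in slices) {
  sub <- models_df[models_df$condition == sl$id, ]
  if (!nrow(sub)) next
  per_net <- lapply(split(sub, sub$network), function(df)
    lapply(strsplit(df$features, ","), function(f) list(features = f)))
  qualified <- names(per_net)[vapply(per_net, function(models)
    isTRUE(qualify_by_bifurcation(consolidate_models(models), study, sl)), TRUE)]
  cat(sprintf("%s: %d/%d networks qualified\n", sl$id,
              length(qualified), length(per_net)))
  if (!length(qualified)) next
  counts <- network_selection_counts(per_net, qualified)
  merged <- unique(unlist(lapply(per_net[qualified], consolidate_models)))
  candidates[[sl$id]] <- list(condition = sl$id, tissue = sl$tissue,
                              features = merged,
                              network_counts = counts$network_counts,
                              selection_freq = counts$selection_freq)
}

candidates <- deduplicate_across_conditions(candidates)
candidates <- Filter(function(c) !isTRUE(c$emptied), candidates)
candidates <- lapply(candidates, function(cand)
  rank_and_truncate(cand, cand$network_counts, cand$selection_freq, cap = 100))

cand_df <- do.call(rbind, lapply(candidates, function(c)
  data.frame(condition = c$condition, n_features = length(c$features),
             features = paste(c$features, collapse = ","))))
write.table(cand_df, "results/classifiers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gs <- export_gene_sets(candidates)
write_gmt(gs, "results/classifiers.gmt")
cat(sprintf("exported %d classifier(s) to results/classifiers.gmt\n",
            length(gs$sets)))
print(cand_df[, c("condition", "n_features")], row.names = FALSE)
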