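#!/usr/bin/env Rscript
# Generate the synthetic study this analysis works on: a three-condition,
# two-class log2-intensity experiment (signal planted in two conditions, one
# null condition), a collection of gene networks covering the planted
# features, and two probe designs sharing half their targets. Everything is
# written as plain text under results/data/ with the ground truth alongside.

library(gaclassify)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- simulation_params(
  n_features = 400,
  conditions = list(
    sim_condition("prochloraz", "ovary", 10, 10, planted = 1:12,  delta = 3),
    sim_condition("flutamide",  "ovary", 10, 10, planted = 13:24, delta = 3),
    sim_condition("fadrozole",  "ovary", 10, 10)),   # null condition
  n_networks = 12, network_size_range = c(20, 40),
  planted_in_network_fraction = 1, seed = seed)

gen <- generate_study(params)
nets <- generate_networks(params, gen$truth, include_special = TRUE)

write_study(gen$study, file.path(out, "expression.tsv"),
            file.path(out, "annotations.tsv"))
write_gmt(nets$networks, file.path(out, "networks.gmt"))

truth_df <- do.call(rbind, lapply(names(gen$truth$planted), function(cond)
  if (length(gen$truth$planted[[cond]]))
    data.frame(condition = cond, feature = gen$truth$planted[[cond]]) else NULL))
write.table(truth_df, file.path(out, "planted_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

designs <- generate_probe_designs(n_shared = 60, n_unique_each = 20,
                                  coord_jitter_bp = 10, seed = seed)
write_probe_catalog(designs$catalog_a, file.path(out, "design_a.tsv"))
write_probe_catalog(designs$catalog_b, file.path(out, "design_b.tsv"))
write.table(designs$truth, file.path(out, "probe_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("study: %d features x %d samples, %d conditions\n",
            nrow(gen$study$values), ncol(gen$study$values),
            length(params$conditions)))
cat(sprintf("networks: %d (incl. master_regulators, hpg_axis)\n",
            length(nets$networks$sets)))
cat(sprintf("probe designs: %d + %d probes, %d true pairs\n",
            nrow(designs$catalog_a$probes), nrow(designs$catalog_b$probes),
            nrow(designs$truth)))
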