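#!/usr/bin/env Rscript
# Validate the classifiers as gene sets: simulate an independent replicate
# of the study (same planted truth, new noise — the dedicated validation
# experiment), rank each replicate condition's genes by signal-to-noise,
# and test every same-tissue classifier by phenotype-permutation GSEA at
# FDR 0.25. The summary mirrors a training-vs-validation report: one row
# per GEP as "CONDITION (F-ratio)" with its enriched classifiers "(q)".

library(gaclassify)

seed <- 1L
params <- simulation_params(
  n_features = 400,
  conditions = list(
    sim_condition("prochloraz", "ovary", 10, 10, planted = 1:12,  delta = 3),
    sim_condition("flutamide",  "ovary", 10, 10, planted = 13:24, delta = 3),
    sim_condition("fadrozole",  "ovary", 10, 10)),
  n_networks = 12, network_size_range = c(20, 40),
  planted_in_network_fraction = 1, seed = seed + 1000L)  # new draw, same truth

rep_study <- generate_study(params)$study
rep_study <- quantile_normalize(filter_low_intensity(rep_study))
rep_slices <- assemble_conditions(rep_study, min_arrays = 9)
geps <- unname(lapply(rep_slices, function(sl)
  list(study = rep_study, slice = sl, name = sl$id)))

val <- run_validation(list(
  gene_sets = read_gmt("results/classifiers.gmt"),
  geps = geps, n_perm = 1000, q_threshold = 0.25, seed = seed,
  out_dir = "results/validation"), force = TRUE)

cat("validation GEPs vs classifiers (training-style report):\n")
print(val$summary, row.names = FALSE)
cat("\nfull enrichment table: results/validation/enrichment_report.tsv\n")
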