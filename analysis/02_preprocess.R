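#!/usr/bin/env Rscript
# Filter low-intensity probes, quantile-normalize across samples, and
# assemble chemical-tissue condition slices behind the 9-array gate.

library(gaclassify)

out <- "results"
study <- read_study("results/data/expression.tsv", "results/data/annotations.tsv")
cat(sprintf("loaded %d features x %d samples\n", nrow(study$values), ncol(study$values)))

study <- filter_low_intensity(study, floor = log2(64), min_fraction = 0.75)
cat(sprintf("after intensity filter: %d features\n", nrow(study$values)))

study <- quantile_normalize(study)
write_study(study, file.path(out, "expression_processed.tsv"),
            file.path(out, "annotations_processed.tsv"))

slices <- assemble_conditions(study, min_arrays = 9)
cond_df <- do.call(rbind, lapply(slices, function(sl)
  data.frame(condition = sl$id, n_treated = length(sl$treated),
             n_control = length(sl$control), n_arrays = sl$n_arrays)))
write.table(cond_df, file.path(out, "conditions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
excl <- attr(slices, "excluded")
cat(sprintf("%d condition(s) pass the gate, %d excluded\n",
            length(slices), nrow(excl)))
print(cond_df, row.names = FALSE)
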