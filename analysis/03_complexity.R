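#!/usr/bin/env Rscript
# Characterize each condition's data complexity by the per-feature Fisher
# discriminant ratio; the condition summary is the maximum ratio (a smaller
# value means less mean separation relative to variance, i.e. a harder
# classification problem).

library(gaclassify)

study <- read_study("results/expression_processed.tsv",
                    "results/annotations_processed.tsv")
slices <- assemble_conditions(study, min_arrays = 9)

cx <- complexity_table(study, slices)
write.table(cx, "results/complexity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("condition F-ratios (max per-feature Fisher ratio):\n")
print(cx, row.names = FALSE)
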