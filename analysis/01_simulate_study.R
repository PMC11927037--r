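#!/usr/bin/env Rscript
# Step 1: generate the standard synthetic drug-target MR study.
#
# Twenty cis-eQTL genes under the known causal graph
# instruments -> expression -> sepsis-like mediator -> rare ARDS-like outcome:
# 12 genes act on the outcome only through the mediator (a = 0.15, delta = 0),
# 3 carry a strong direct effect (delta = 1.5), 5 are null.  Sample sizes
# mirror a biobank-scale screen (30k eQTL panel; 10 154 / 454 764 mediator
# cases/controls; 216 528-subject rare outcome).  Everything downstream of
# this script consumes the files written here.

library(mrtriage)

seed <- 2026
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

bundle <- simulate_study(standard_scenario(seed = seed))
saveRDS(bundle, file.path("scratch", "synthetic_study.rds"))  # binary intermediate

write.table(bundle$truth, file.path("results", "truth_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_snps <- nrow(bundle$mediator$records)
cat(sprintf("simulated %d genes over %d SNPs (seed %d)\n",
            nrow(bundle$truth), n_snps, seed))
cat("truth categories:\n")
print(table(bundle$truth$category))
cat("wrote results/truth_table.tsv and scratch/synthetic_study.rds\n")
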