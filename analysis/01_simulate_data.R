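#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 5-chromosome toy genome, a DE table
# with 10 injected adjacent co-regulated blocks plus scattered singleton
# deregulation, duplicate gene pairs, and the truth labels.

library(adjacoreg)

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101)  # defaults: 5 x 1000 genes, 10 blocks of 2
catalogue <- simulate_genome(cfg)
sim <- simulate_expression(catalogue, cfg)

write_annotation(catalogue, file.path(out, "genes.tsv"))
write.table(sim$de_table, file.path(out, "de.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$family_map, file.path(out, "families.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d genes on %d chromosomes\n", nrow(catalogue),
            length(unique(catalogue$chromosome))))
print(table(sim$truth$label))
cat("inputs written to", out, "\n")
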