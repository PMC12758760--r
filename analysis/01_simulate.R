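#!/usr/bin/env Rscript
# Step 1: simulate the paper-mirroring synthetic dataset.
#
# Generates the 42-tadpole two-line design (dmrt1.L and dmrt1.S F2 siblings),
# a 10,000-gene two-subgenome count matrix with negative-binomial noise, a
# female-specific marker gene, sex-biased and knockout-dysregulated genes, a
# lane effect in the dmrt1.S line, and the 90-gene sex-related panel.
# Writes counts, metadata, annotation, truth labels and the panel list under
# results/data/.

suppressPackageStartupMessages(library(gonadtx))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_counts(cfg)

write_counts(sim$counts, file.path(out, "counts.tsv"), "tsv")
write.table(sim$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$annotation, file.path(out, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sim$annotation$gene_id[sim$annotation$is_panel_member],
           file.path(out, "panel.txt"))

marker <- sim$counts[sim$truth$is_female_marker, ]
fem <- sim$samples$sex == "F"
cat(sprintf("simulated %d genes x %d samples (seed %d)\n",
            nrow(sim$counts), ncol(sim$counts), seed))
cat(sprintf("subgenome L fraction: %.3f\n",
            mean(sim$annotation$subgenome == "L", na.rm = TRUE)))
cat(sprintf("female marker median count: %.1f in females, %.1f in males\n",
            median(marker[fem]), median(marker[!fem])))
cat("wrote counts.tsv, samples.tsv, annotation.tsv, truth.tsv, panel.txt\n")
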