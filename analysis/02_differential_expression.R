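#!/usr/bin/env Rscript
# Step 2: per-line differential expression.
#
# For each line: apply the mean-count < 2 abundance filter, run the
# knockout-vs-wildtype contrast within each sex under both engine
# configurations (gene-wise dispersions half-shrunk to the trend, and
# trend-only dispersions), take their consensus, intersect significant genes
# with the line's wildtype male-vs-female sex-biased set, and summarize the
# subgenome composition of the calls. Lane enters the design as a covariate
# wherever a line spans two sequencing runs.

suppressPackageStartupMessages(library(gonadtx))

data_dir <- "results/data"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cm <- read_counts(file.path(data_dir, "counts.tsv"), "tsv")
samples <- read.delim(file.path(data_dir, "samples.tsv"))
annotation <- read.delim(file.path(data_dir, "annotation.tsv"))

for (ln in unique(samples$line)) {
  smp <- samples[samples$line == ln, ]
  cml <- cm[, smp$sample_id]
  filt <- low_count_filter(cml, 2.0)
  cat(sprintf("\n== line %s: %d samples, %d genes pass the filter (%d removed)\n",
              ln, nrow(smp), nrow(filt$counts),
              length(filt$removed_gene_ids)))
  covars <- if (length(unique(smp$lane)) > 1) "lane" else character(0)

  wt <- smp$genotype == "wildtype"
  mf <- lapply(c(A = 0.5, B = 1), function(shr)
    de_test(filt$counts[, smp$sample_id[wt]], smp[wt, ],
            contrast = list(factor = "sex", levels = c("F", "M")),
            covariates = covars, dispersion_shrink = shr))
  sexbiased <- lapply(mf, function(r) r$gene_id[r$significant])
  cat(sprintf("   wildtype M vs F: %d / %d significant (consensus %d)\n",
              length(sexbiased$A), length(sexbiased$B),
              consensus_de(mf$A, mf$B)$n_overlap))

  for (sx in c("F", "M")) {
    in_sex <- smp$sex == sx
    cms <- filt$counts[, smp$sample_id[in_sex]]
    res <- lapply(c(A = 0.5, B = 1), function(shr)
      de_test(cms, smp[in_sex, ],
              contrast = list(factor = "genotype",
                              levels = c("wildtype", "knockout")),
              covariates = covars, dispersion_shrink = shr))
    cons <- consensus_de(res$A, res$B)
    key <- paste0(ln, "_", sx)
    write_de_table(res$A, file.path(out, paste0("de_", key, "_A.tsv")),
                   annotation)
    write_de_table(res$B, file.path(out, paste0("de_", key, "_B.tsv")),
                   annotation)
    cat(sprintf("   knockout %s vs wildtype %s: A %d, B %d, overlap %d\n",
                sx, sx, cons$n_A, cons$n_B, cons$n_overlap))
    inter <- sexbias_intersection(cons$sig_A, sexbiased)
    cat(sprintf("     sex-biased among engine-A calls: %d (%s)\n",
                inter$count,
                if (is.na(inter$percent)) "NA"
                else sprintf("%.0f%%", inter$percent)))
    if (cons$n_A > 0) {
      sg <- subgenome_proportion(cons$sig_A, annotation)
      cat(sprintf("     subgenome: %.0f%% L (nL=%d, nS=%d, exact binomial p vs 57%% = %.3g)\n",
                  100 * sg$prop_L, sg$n_L, sg$n_S, sg$p_value))
    }
  }
}
cat("\nwrote per-contrast DE tables under", out, "\n")
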