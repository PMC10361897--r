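#!/usr/bin/env Rscript
# Delineate the non-recombining block from the FST track, assign block
# haplotypes by anchored clustering, and tabulate the haplotype frequency
# trajectory over release periods. Anchors play the role of accessions
# with externally known haplotypes.

suppressPackageStartupMessages(library(haploswitch))
sim_in <- read_matrix("results/panel_genotypes.tsv",
                      "results/panel_meta.csv", build = "synthetic")
gm <- sim_in$genotypes
meta <- sim_in$meta
truth <- utils::read.csv("results/panel_truth.csv")

anchors <- c(stats::setNames(1L, truth$accession[truth$haplotype == 1][1]),
             stats::setNames(2L, truth$accession[truth$haplotype == 2][1]))
res <- recover_block(gm, meta, anchors,
                     spec = window_spec("bp", 1e6, 2.5e5), seed = 1)
print(res$block)

acc <- mean(res$assignment$haplotype ==
              truth$haplotype[match(res$assignment$accession,
                                    truth$accession)])
cat(sprintf("haplotype assignment accuracy vs truth: %.3f\n", acc))
utils::write.csv(as.data.frame(res$assignment),
                 "results/haplotype_assignment.csv", row.names = FALSE)
utils::write.table(res$trajectory, "results/haplotype_trajectory.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("trajectory of the target haplotype (label 2):\n")
print(res$trajectory[res$trajectory$haplotype == 2,
                     c("period", "n", "n_period", "frequency")])

gg <- graphical_genotypes(gm, res$block, flank_bp = 1e6, n_snps = 500,
                          seed = 1,
                          order_by = stats::setNames(res$assignment$haplotype,
                                                     res$assignment$accession),
                          path = "results/graphical_genotypes.tsv")
cat("graphical genotypes written for", nrow(gg), "accessions\n")
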