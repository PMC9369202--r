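#!/usr/bin/env Rscript
# Stage 1: generate the synthetic regulatory dataset.
#
# Emulates the inputs of a TF loss-of-function study: gene/miRNA annotation,
# two replicate ChIP peak tables with summit jitter and noise peaks,
# TSS-anchored promoter sequences with a YTAATYAW motif planted ~200 bp
# upstream of the TSS in bound promoters, gene and miRNA DE tables from the
# mutant-vs-WT contrast, and a miRNA->target map with 40 planted coherent
# type-IV loops.

suppressPackageStartupMessages(library(fflnet))

seed <- as.integer(Sys.getenv("FFLNET_SEED", "1"))
outdir <- "results/simulation"

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)
paths <- write_simulation(sim, outdir)

cat("Simulated", nrow(sim$genes), "gene models on", cfg$n_chroms,
    "chromosomes;", length(sim$truth$bound_gene_ids), "TF-bound.\n")
cat("Replicate peaks:", nrow(sim$chip$rep1), "and", nrow(sim$chip$rep2),
    "(", cfg$n_noise_peaks_per_replicate, "noise peaks each ).\n")
cat("Planted loops:", nrow(sim$truth$planted_ffls), "of type",
    unique(sim$truth$planted_ffls$type), "\n")
cat("Outputs:\n"); print(unname(paths))
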