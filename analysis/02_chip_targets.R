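#!/usr/bin/env Rscript
# Stage 2: consolidate replicate ChIP peaks and assign candidate targets.
#
# Overlapping peaks with summits within 600 bp and disjoint peaks with
# summits within 300 bp are merged per replicate; peaks supported by the
# other replicate within 600 bp and passing p < 1e-5 become high-confidence
# binding sites; genes with a summit between TSS-3kb and TTS+1kb
# (strand-oriented) are candidate targets.

suppressPackageStartupMessages(library(fflnet))

indir <- "results/simulation"
outdir <- "results/chip"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

genes <- read_gene_models_gff3(file.path(indir, "annotation.gff3"))
params <- chip_params()
rep1 <- merge_peaks(read_peaks(file.path(indir, "chip_rep1_peaks.tsv")), params)
rep2 <- merge_peaks(read_peaks(file.path(indir, "chip_rep2_peaks.tsv")), params)
hc <- high_confidence_peaks(rep1, rep2, params)
tsv(hc, "hc_peaks.tsv")

assignments <- assign_candidate_targets(hc, genes, params)
tsv(assignments, "target_assignments.tsv")

profile <- peak_location_profile(hc, genes, anchor = "TSS", params = params)
tsv(profile$histogram, "summit_profile_tss.tsv")
genic <- genic_distribution(hc, genes, params)
tsv(data.frame(region = names(genic), fraction = as.numeric(genic)),
    "summit_genic_distribution.tsv")

cat("Merged peaks:", nrow(rep1), "+", nrow(rep2),
    "-> high-confidence:", nrow(hc), "\n")
cat("Candidate target genes:", length(unique(assignments$gene_id)), "\n")
cat(sprintf("Summits within +/-0.5 kb of the TSS: %.1f%% of %d assigned genes\n",
            100 * profile$fraction_within_500, profile$n_assigned))
cat(sprintf("Genic context: %s\n",
            paste(sprintf("%s %.0f%%", names(genic), 100 * genic),
                  collapse = ", ")))
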