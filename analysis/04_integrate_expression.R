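#!/usr/bin/env Rscript
# Stage 4: integrate the loss-of-function differential expression.
#
# Infers signed TF->feature edges (up in the mutant => repressed by the TF),
# classifies each miRNA's co-expression category against its mapped targets
# (I: miRNA up / targets down; II: miRNA down / targets up; III: significant
# but not anticorrelated), and summarizes DE by gene group.

suppressPackageStartupMessages(library(fflnet))

indir <- "results/simulation"
outdir <- "results/integration"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

gene_de <- parse_de_table(file.path(indir, "gene_de.tsv"), alpha = 0.05)
mirna_de <- parse_de_table(file.path(indir, "mirna_de.tsv"), alpha = 0.05)
target_map <- read.delim(file.path(indir, "target_map.tsv"),
                         stringsAsFactors = FALSE)
truth <- jsonlite::read_json(file.path(indir, "ground_truth.json"),
                             simplifyVector = TRUE)

edges <- rbind(infer_edge_signs(mirna_de, "TF"), infer_edge_signs(gene_de, "TF"))
tsv(edges, "edges.tsv")

cats <- classify_all_mirnas(mirna_de, gene_de, target_map)
tsv(cats, "mirna_categories.tsv")

# group genes by their role in the planted structure: the anticorrelated
# target family, the DE background, and the remainder
family <- rep("other", nrow(gene_de))
family[gene_de$feature_id %in% truth$planted_ffls$target] <- "planted_targets"
family[gene_de$feature_id %in% unlist(truth$background_de_genes)] <-
  "de_background"
fam <- family_de_summary(gene_de, data.frame(feature_id = gene_de$feature_id,
                                             family = family))
tsv(fam, "family_summary.tsv")

cat("Edges inferred:", nrow(edges),
    "(", sum(edges$sign == -1), "repressed,", sum(edges$sign == 1),
    "activated )\n")
cat("miRNA categories:\n")
print(table(cats$category))
cat("Per-group DE summary:\n")
print(fam)
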