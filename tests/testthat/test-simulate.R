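small_cfg <- function(...) {
  defaults <- list(seed = 11, n_chroms = 1, chrom_length = 400000,
                   n_genes = 30, n_mirna_genes = 5, n_bound_genes = 8,
                   n_planted_c4 = 5, n_de_background_mirnas = 2,
                   n_de_background_genes = 4)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("annotation places non-overlapping strand-assigned gene models", {
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length = 200000,
                    n_genes = 10, n_mirna_genes = 2, n_bound_genes = 4,
                    n_planted_c4 = 2, n_de_background_mirnas = 0,
                    n_de_background_genes = 0)
  ann <- simulate_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 12)
  expect_setequal(unique(g$biotype), c("protein_coding", "miRNA_gene"))
  expect_equal(sum(g$biotype == "miRNA_gene"), 2)
  expect_true(all(g$strand %in% c("+", "-")))
  # windows (gene +/- 3kb/1kb) must not overlap within the chromosome
  ord <- g[order(g$start), ]
  expect_true(all(ord$start[-1] - 3000 >= ord$end[-nrow(ord)] + 1000))
  expect_true(all(g$end <= cfg$chrom_length))
})

test_that("generators are deterministic under the seed", {
  cfg <- small_cfg()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$chip, b$chip)
  expect_identical(a$gene_de, b$gene_de)
  expect_identical(a$target_map, b$target_map)
  expect_identical(as.character(a$promoters), as.character(b$promoters))
  expect_identical(a$truth, b$truth)
})

test_that("impossible gene placement raises a capacity error", {
  # required span per gene is its length plus 3 kb upstream, 1 kb downstream
  # and the inter-gene spacer; 1000 genes cannot fit in 100 kb
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length = 100000,
                    n_genes = 1000, n_mirna_genes = 0, n_bound_genes = 0,
                    n_planted_c4 = 0, n_de_background_mirnas = 0,
                    n_de_background_genes = 0)
  expect_error(simulate_annotation(cfg), "capacity")
})

test_that("zero jitter gives identical replicate summits", {
  cfg <- small_cfg(summit_jitter_sd = 0, n_noise_peaks_per_replicate = 0)
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_experiment(ann, cfg)
  expect_equal(nrow(chip$rep1), cfg$n_bound_genes)
  expect_identical(chip$rep1$summit, chip$rep2$summit)
  expect_identical(sort(chip$rep1$summit),
                   sort(unname(ann$truth$planted_peak_summits)))
})

test_that("replicate summit distance matches the half-normal expectation", {
  # |N(0,s) - N(0,s)| has mean 2s/sqrt(pi); checked against a brute-force
  # Monte-Carlo estimate of the same quantity
  s <- 50
  cfg <- sim_config(seed = 3, n_chroms = 2, chrom_length = 2000000,
                    n_genes = 200, n_mirna_genes = 10, n_bound_genes = 200,
                    summit_jitter_sd = s, n_noise_peaks_per_replicate = 0,
                    n_planted_c4 = 5, n_de_background_mirnas = 0,
                    n_de_background_genes = 0)
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_experiment(ann, cfg)
  r1 <- chip$rep1[order(chip$rep1$name), ]
  r2 <- chip$rep2[order(chip$rep2$name), ]
  observed_mean <- mean(abs(r1$summit - r2$summit))
  analytic <- 2 * s / sqrt(pi)
  mc <- withr::with_seed(99, mean(abs(rnorm(2e5, 0, s) - rnorm(2e5, 0, s))))
  expect_lt(abs(mc - analytic), 0.5)  # oracle agrees with the closed form
  # SE of the mean over 200 genes is ~3 bp; allow 4 SE
  expect_lt(abs(observed_mean - analytic), 12)
})

test_that("noise peaks never survive the high-confidence filters", {
  cfg <- small_cfg(n_bound_genes = 0, n_planted_c4 = 0,
                   n_noise_peaks_per_replicate = 10)
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_experiment(ann, cfg)
  expect_equal(nrow(chip$rep1), 10)
  hc <- suppressWarnings(high_confidence_peaks(merge_peaks(chip$rep1),
                                               merge_peaks(chip$rep2)))
  expect_equal(nrow(hc), 0)
})

test_that("planted expression has the constructed signs and significance", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(ann, cfg)
  truth <- expr$truth
  ffl <- truth$planted_ffls
  expect_equal(nrow(ffl), 5)
  expect_true(all(ffl$type == "C4"))
  mir <- expr$mirna_de[match(unique(ffl$mirna), expr$mirna_de$feature_id), ]
  expect_true(all(mir$log2fc > 0))          # repressed miRNA up in mutant
  expect_true(all(mir$padj < cfg$alpha_sig))
  tg <- expr$gene_de[match(ffl$target, expr$gene_de$feature_id), ]
  expect_true(all(tg$log2fc < 0))           # activated target down
  expect_true(all(tg$padj < cfg$alpha_sig))
  # planted loops are embedded in the map
  key <- paste(expr$target_map$mirna_id, expr$target_map$target_id)
  expect_true(all(paste(ffl$mirna, ffl$target) %in% key))
  # every planted FFL's nodes carry edge signs consistent with its type
  expect_true(all(truth$edge_signs[ffl$mirna] == -1L))
  expect_true(all(truth$edge_signs[ffl$target] == +1L))
})

test_that("null features are flagged at about the nominal rate", {
  # binomial 99% interval around 0.05 for n = 1000: (0.032, 0.068)
  cfg <- sim_config(seed = 5, n_chroms = 2, chrom_length = 4000000,
                    n_genes = 1000, n_mirna_genes = 10, n_bound_genes = 0,
                    n_planted_c4 = 0, n_de_background_mirnas = 0,
                    n_de_background_genes = 0)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(ann, cfg)
  frac <- mean(expr$gene_de$padj < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("over-committed planted loops raise capacity errors", {
  cfg <- small_cfg(n_planted_c4 = 40, targets_per_mirna = 2)
  ann <- simulate_annotation(cfg)
  expect_error(simulate_expression(ann, cfg), "capacity")
})

test_that("promoters carry the planted motif at the recorded offset", {
  cfg <- small_cfg(motif_offset_sd = 0)
  ann <- simulate_annotation(cfg)
  prom <- simulate_promoters(ann, cfg)
  expect_true(all(Biostrings::width(prom) == 2001))
  for (gid in ann$truth$bound_gene_ids) {
    seq <- prom[startsWith(names(prom), paste0(gid, "|"))]
    m <- iupac_scan(seq, cfg$planted_motif)
    expect_true(-200 %in% m$offset_to_tss[m$strand == "+"])
  }
  # byte-identical reproducibility
  prom2 <- simulate_promoters(ann, cfg)
  expect_identical(as.character(prom), as.character(prom2))
})

test_that("background motif counts match the analytic IUPAC expectation", {
  # per-position match probability of YTAATYAW under uniform bases is
  # (2*1*1*1*1*2*1*2)/4^8 = 8/65536; 1994 positions x 2 strands per 2001-bp
  # window
  p_pos <- 8 / 4^8
  n_prom <- 2000
  lambda <- 1994 * 2 * p_pos * n_prom
  seqs <- withr::with_seed(21, {
    Biostrings::DNAStringSet(vapply(seq_len(n_prom), function(i) {
      paste(sample(c("A", "C", "G", "T"), 2001, TRUE), collapse = "")
    }, character(1)))
  })
  count <- sum(Biostrings::vcountPattern("YTAATYAW", seqs, fixed = "subject")) +
    sum(Biostrings::vcountPattern("WTRATTAR", seqs, fixed = "subject"))
  expect_lt(abs(count - lambda), 3 * sqrt(lambda))
})

test_that("sign recovery never decreases with the planted effect size", {
  rec <- vapply(c(0.5, 1, 2), function(eff) {
    cfg <- small_cfg(lfc_effect_mean = eff)
    ann <- simulate_annotation(cfg)
    expr <- simulate_expression(ann, cfg)
    edges <- infer_edge_signs(mark_significant(expr$gene_de))
    es <- expr$truth$edge_signs
    planted <- names(es)[es != 0 & names(es) %in% expr$gene_de$feature_id]
    mean(edges$sign[match(planted, edges$dest)] == es[planted], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_gte(rec[3], 0.95)
})
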