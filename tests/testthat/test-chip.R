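test_that("summit-distance merge rule follows the printed distances", {
  # overlapping peaks, summits 400 bp apart -> merged
  p <- pk("chr1", start = c(100, 350), end = c(700, 1000),
          summit = c(300, 700), p = c(10, 20))
  m <- merge_peaks(p)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100)
  expect_equal(m$end, 1000)
  expect_equal(m$summit, 700)           # most significant member
  expect_equal(m$best_neg_log10_p, 20)

  # disjoint peaks, summits 250 bp apart -> merged
  p <- pk("chr1", start = c(100, 450), end = c(400, 700),
          summit = c(200, 450))
  expect_equal(nrow(merge_peaks(p)), 1)

  # disjoint peaks, summits 400 bp apart -> NOT merged
  p <- pk("chr1", start = c(100, 500), end = c(400, 800),
          summit = c(200, 600))
  expect_equal(nrow(merge_peaks(p)), 2)

  # overlapping peaks, summits 700 bp apart -> NOT merged
  p <- pk("chr1", start = c(100, 600), end = c(900, 1500),
          summit = c(200, 900))
  expect_equal(nrow(merge_peaks(p)), 2)

  # single peak is unchanged
  p <- pk("chr1", 100, 400, 250)
  m <- merge_peaks(p)
  expect_equal(m[, c("start", "end", "summit")],
               data.frame(start = 100, end = 400, summit = 250))

  # significance tie -> leftmost summit wins
  p <- pk("chr1", start = c(100, 350), end = c(700, 1000),
          summit = c(300, 700), p = c(15, 15))
  expect_equal(merge_peaks(p)$summit, 300)
})

test_that("merge is idempotent, order-invariant and matches the O(n^2) oracle", {
  peaks <- random_peaks(300, seed = 7)
  m1 <- merge_peaks(peaks)
  expect_identical(merged_partition(m1), oracle_merge_partition(peaks))
  # permutation invariance
  shuf <- withr::with_seed(8, peaks[sample.int(nrow(peaks)), ])
  expect_identical(merge_peaks(shuf), m1)
  # idempotence on re-application (merged peaks re-enter as peaks)
  m1b <- m1
  m1b$name <- m1b$members
  m1b$neg_log10_p <- m1b$best_neg_log10_p
  m2 <- merge_peaks(m1b)
  expect_identical(m2[, c("chrom", "start", "end", "summit")],
                   m1[, c("chrom", "start", "end", "summit")])
})

test_that("replicate support and significance filters drive high-confidence calls", {
  r1 <- merge_peaks(pk("chr1", c(800, 5000), c(1200, 5400), c(1000, 5200)))
  r2 <- merge_peaks(pk("chr1", 1150, 1600, 1350))
  hc <- high_confidence_peaks(r1, r2)
  # summit 1000 vs 1350: supported (350 <= 600); 5200 unsupported: dropped
  expect_equal(hc$summit, 1000)
  expect_equal(hc$start, 800)
  expect_equal(hc$end, 1600)            # union with the supporting partner

  # supported pair with p = 1e-4 fails the p < 1e-5 threshold
  r1w <- merge_peaks(pk("chr1", 800, 1200, 1000, p = 4))
  r2w <- merge_peaks(pk("chr1", 900, 1300, 1100, p = 4))
  expect_equal(nrow(high_confidence_peaks(r1w, r2w)), 0)

  # empty replicate warns and returns empty
  expect_warning(res <- high_confidence_peaks(r1, empty <- r1[0, ]), "empty")
  expect_equal(nrow(res), 0)
})

test_that("replicate support is symmetric on the selected loci", {
  a <- merge_peaks(random_peaks(120, seed = 31))
  b <- merge_peaks(random_peaks(120, seed = 32))
  ab <- high_confidence_peaks(a, b)
  ba <- high_confidence_peaks(b, a)
  near <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i) {
      any(y$chrom == x$chrom[i] & abs(y$summit - x$summit[i]) <= 600)
    }, logical(1))
  }
  if (nrow(ab)) expect_true(all(near(ab, ba)))
  if (nrow(ba)) expect_true(all(near(ba, ab)))
})

test_that("candidate-target windows are strand-oriented TSS-3kb / TTS+1kb", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"), start = c(10000, 40000),
                      end = c(12000, 42000), biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  hits <- function(summit) {
    hc <- pk("chr1", summit - 150, summit + 150, summit)
    names(hc)[names(hc) == "neg_log10_p"] <- "best_neg_log10_p"
    assign_candidate_targets(hc, genes)
  }
  # + strand: TSS - 2999 assigned upstream
  a <- hits(10000 - 2999)
  expect_equal(a$gene_id, "gp")
  expect_equal(a$region_class, "upstream")
  expect_equal(a$summit_to_tss, -2999)
  # + strand: TTS + 999 assigned downstream
  a <- hits(11999 + 999)
  expect_equal(a$gene_id, "gp")
  expect_equal(a$region_class, "downstream")
  # outside: TSS - 3001 not assigned
  expect_equal(nrow(hits(10000 - 3001)), 0)
  # - strand gene: TSS at end-1; summit 2999 bp greater genomic coordinate
  # is 2999 bp upstream in gene orientation
  a <- hits(41999 + 2999)
  expect_equal(a$gene_id, "gm")
  expect_equal(a$summit_to_tss, -2999)
  expect_equal(a$region_class, "upstream")
  # genic summit
  a <- hits(11000)
  expect_equal(a$region_class, "genic")
})

test_that("assignment equals the per-base window membership oracle", {
  cfg <- sim_config(seed = 17, n_chroms = 2, chrom_length = 500000,
                    n_genes = 25, n_mirna_genes = 5, n_bound_genes = 10,
                    n_planted_c4 = 3, n_de_background_mirnas = 1,
                    n_de_background_genes = 2)
  ann <- simulate_annotation(cfg)
  hc <- merge_peaks(random_peaks(150, seed = 18, span = 490000))
  names(hc)[names(hc) == "neg_log10_p"] <- "best_neg_log10_p"
  got <- assign_candidate_targets(hc, ann$genes)
  expect_identical(sort(paste(got$gene_id, got$summit, sep = "@")),
                   oracle_assigned_pairs(hc, ann$genes))
})

test_that("positional profile recovers planted summit geometry", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                      strand = "+", start = seq(20000, 400000, by = 20000),
                      end = seq(22000, 402000, by = 20000),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  # all summits exactly at the TSS
  hc <- pk("chr1", genes$start - 150, genes$start + 150, genes$start)
  names(hc)[names(hc) == "neg_log10_p"] <- "best_neg_log10_p"
  prof <- peak_location_profile(hc, genes)
  expect_equal(prof$fraction_within_500, 1.0)
  expect_equal(sum(prof$histogram$count), 20)
  expect_equal(prof$histogram$count[prof$histogram$bin_lo == 0], 20)

  # summits uniform over [-3000, 3000) around each TSS: the +/-0.5 kb
  # fraction approaches 1000/6000
  offs <- withr::with_seed(5, as.integer(round(runif(2000, -3000, 2999))))
  g1 <- genes[rep(1, 2000), ]
  g1$gene_id <- sprintf("u%04d", 1:2000)
  g1$start <- seq(20000, by = 20000, length.out = 2000)
  g1$end <- g1$start + 2000
  hc <- pk("chr1", g1$start + offs - 50, g1$start + offs + 50, g1$start + offs)
  names(hc)[names(hc) == "neg_log10_p"] <- "best_neg_log10_p"
  prof <- peak_location_profile(hc, g1)
  expect_lt(abs(prof$fraction_within_500 - 1/6), 0.03)
})

test_that("genic distribution classifies every summit like the hand oracle", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      strand = c("+", "-"), start = c(50000, 100000),
                      end = c(52000, 103000), biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  # one summit per class: upstream of a, genic in a, downstream of a,
  # intergenic
  summits <- c(48000, 51000, 52500, 80000)
  hc <- pk("chr1", summits - 100, summits + 100, summits)
  names(hc)[names(hc) == "neg_log10_p"] <- "best_neg_log10_p"
  frac <- genic_distribution(hc, genes)
  expect_equal(as.numeric(frac), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(frac), 1)
  counts <- attr(frac, "counts")
  expect_equal(unname(counts), c(1L, 1L, 1L, 1L))
})

test_that("zero-noise synthetic ChIP recovers exactly the planted bound genes", {
  cfg <- sim_config(seed = 23, n_chroms = 2, chrom_length = 1500000,
                    n_genes = 120, n_mirna_genes = 15, n_bound_genes = 25,
                    summit_jitter_sd = 0, n_noise_peaks_per_replicate = 0,
                    n_planted_c4 = 10, n_de_background_mirnas = 2,
                    n_de_background_genes = 5)
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_experiment(ann, cfg)
  hc <- high_confidence_peaks(merge_peaks(chip$rep1), merge_peaks(chip$rep2))
  found <- unique(assign_candidate_targets(hc, ann$genes)$gene_id)
  expect_setequal(found, ann$truth$bound_gene_ids)
})
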