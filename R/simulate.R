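#' Simulation configuration
#'
#' Parameters of the synthetic regulatory-network generator. The defaults
#' describe the study conditions exercised throughout the package: a single
#' TF in a loss-of-function contrast, two ChIP replicates, 30 miRNA genes and
#' 200 protein-coding genes with 40 planted coherent type-IV loops, a
#' YTAATYAW binding motif planted ~200 bp upstream of the TSS, and effect
#' sizes of 2 log2 units (sd 0.3) against a 0.3-sd null background.
#'
#' @param seed integer; master seed. Every generator derives its stream from
#'   it, so identical configs give byte-identical outputs.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of protein-coding genes.
#' @param n_mirna_genes number of miRNA host genes.
#' @param n_bound_genes number of genes (any biotype) bound by the TF.
#' @param summit_jitter_sd per-replicate ChIP summit jitter sd, bp.
#' @param n_noise_peaks_per_replicate replicate-specific noise peaks.
#' @param planted_motif IUPAC pattern planted in bound promoters.
#' @param motif_offset_mean,motif_offset_sd offset of the planted motif
#'   relative to the TSS, bp (negative = upstream).
#' @param lfc_effect_mean,lfc_effect_sd magnitude of planted log2
#'   fold changes (mutant vs WT).
#' @param null_lfc_sd sd of null-feature log2 fold changes.
#' @param alpha_sig significance level; null features are flagged at about
#'   this rate.
#' @param n_planted_c4 number of planted coherent type-IV loops.
#' @param n_planted_per_other_type planted loops of each of I1, I2, C3.
#' @param n_de_background_mirnas differentially expressed miRNAs outside any
#'   planted loop, with alternating signs (up, down, up, ...). These emulate
#'   the DE miRNAs a real small-RNA contrast always contains in both
#'   directions; they also keep the permutation null well-defined for every
#'   loop type (a sign pattern absent from the measured tuples can never
#'   form a loop under shuffling, making its strict-inequality p-value
#'   degenerately zero).
#' @param n_de_background_genes differentially expressed genes outside the
#'   miRNA-target structure, with alternating signs. These emulate the
#'   broad TF-family expression response a TF-mutant RNA-seq contrast shows
#'   beyond the miRNA targets; they are never drawn as map decoys.
#' @param targets_per_mirna size of each miRNA's entry in the target map.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1500000L,
                       n_genes = 200L,
                       n_mirna_genes = 30L,
                       n_bound_genes = 40L,
                       summit_jitter_sd = 50,
                       n_noise_peaks_per_replicate = 10L,
                       planted_motif = "YTAATYAW",
                       motif_offset_mean = -200,
                       motif_offset_sd = 50,
                       lfc_effect_mean = 2,
                       lfc_effect_sd = 0.3,
                       null_lfc_sd = 0.3,
                       alpha_sig = 0.05,
                       n_planted_c4 = 40L,
                       n_planted_per_other_type = 0L,
                       n_de_background_mirnas = 6L,
                       n_de_background_genes = 20L,
                       targets_per_mirna = 5L) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    n_mirna_genes = as.integer(n_mirna_genes),
    n_bound_genes = as.integer(n_bound_genes),
    summit_jitter_sd = summit_jitter_sd,
    n_noise_peaks_per_replicate = as.integer(n_noise_peaks_per_replicate),
    planted_motif = check_iupac(planted_motif),
    motif_offset_mean = motif_offset_mean,
    motif_offset_sd = motif_offset_sd,
    lfc_effect_mean = lfc_effect_mean, lfc_effect_sd = lfc_effect_sd,
    null_lfc_sd = null_lfc_sd, alpha_sig = alpha_sig,
    n_planted_c4 = as.integer(n_planted_c4),
    n_planted_per_other_type = as.integer(n_planted_per_other_type),
    n_de_background_mirnas = as.integer(n_de_background_mirnas),
    n_de_background_genes = as.integer(n_de_background_genes),
    targets_per_mirna = as.integer(targets_per_mirna)
  )
  stopifnot(
    cfg$n_chroms >= 1L, cfg$chrom_length > 0L, cfg$n_genes >= 0L,
    cfg$n_mirna_genes >= 0L, cfg$n_bound_genes >= 0L,
    cfg$n_bound_genes <= cfg$n_genes + cfg$n_mirna_genes,
    cfg$summit_jitter_sd >= 0, cfg$n_noise_peaks_per_replicate >= 0L,
    cfg$motif_offset_sd >= 0, cfg$lfc_effect_sd >= 0, cfg$null_lfc_sd >= 0,
    cfg$alpha_sig > 0, cfg$alpha_sig < 1,
    cfg$n_planted_c4 >= 0L, cfg$n_planted_per_other_type >= 0L,
    cfg$n_de_background_mirnas >= 0L, cfg$n_de_background_genes >= 0L,
    cfg$targets_per_mirna >= 1L
  )
  class(cfg) <- "sim_config"
  cfg
}

# spacer between the downstream window of one gene and the upstream window of
# the next, so candidate-target windows never overlap
SIM_SPACER <- 500L
SIM_UPSTREAM <- 3000L
SIM_DOWNSTREAM <- 1000L

#' Simulate a gene annotation with planted binding ground truth
#'
#' Places non-overlapping, strand-assigned gene models on `n_chroms`
#' chromosomes, spaced so that each gene's 3 kb-upstream / 1 kb-downstream
#' candidate-target window is disjoint from its neighbours'. A random subset
#' of `n_bound_genes` genes is marked TF-bound, and each bound gene gets a
#' motif offset drawn from Normal(`motif_offset_mean`, `motif_offset_sd`)
#' (clipped to the promoter window); the corresponding genomic position
#' serves as the planted ChIP summit.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (data.frame: gene_id, chrom, strand, start, end,
#'   biotype; 0-based half-open), `mirna_gene_map` (mature miRNA id -> host
#'   gene id), and `truth` (bound_gene_ids, planted_motif_offsets,
#'   planted_peak_summits, edge_signs, planted_ffls).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_total <- cfg$n_genes + cfg$n_mirna_genes
  with_seed(cfg$seed + 101L, {
    lens <- as.integer(round(runif(n_total, 1000, 3000)))
    chrom_of <- rep(seq_len(cfg$n_chroms), length.out = n_total)
    # capacity check before placement
    need <- tapply(lens + SIM_UPSTREAM + SIM_DOWNSTREAM + SIM_SPACER,
                   chrom_of, sum)
    if (any(need > cfg$chrom_length)) {
      stop("capacity error: chromosome of length ", cfg$chrom_length,
           " bp cannot hold the requested gene models (need ",
           max(need), " bp)")
    }
    biotype <- rep("protein_coding", n_total)
    if (cfg$n_mirna_genes > 0) {
      biotype[sample.int(n_total, cfg$n_mirna_genes)] <- "miRNA_gene"
    }
    strand <- sample(c("+", "-"), n_total, replace = TRUE)

    start <- integer(n_total)
    end <- integer(n_total)
    for (chr in seq_len(cfg$n_chroms)) {
      idx <- which(chrom_of == chr)
      cursor <- 0L
      for (i in idx) {
        start[i] <- cursor + SIM_UPSTREAM
        end[i] <- start[i] + lens[i]
        cursor <- end[i] + SIM_DOWNSTREAM + SIM_SPACER
      }
    }
    ipc <- which(biotype == "protein_coding")
    imir <- which(biotype == "miRNA_gene")
    gene_id <- character(n_total)
    gene_id[ipc] <- sprintf("g%04d", seq_along(ipc))
    gene_id[imir] <- sprintf("MIRg%03d", seq_along(imir))
    genes <- data.frame(
      gene_id = gene_id, chrom = paste0("chr", chrom_of), strand = strand,
      start = start, end = end, biotype = biotype,
      stringsAsFactors = FALSE
    )
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    mirna_gene_map <- setNames(gene_id[imir],
                               sprintf("miR%03d", seq_along(imir)))

    bound <- sort(sample(genes$gene_id, cfg$n_bound_genes))
    w <- nchar(cfg$planted_motif)
    off <- as.integer(round(rnorm(length(bound), cfg$motif_offset_mean,
                                  cfg$motif_offset_sd)))
    off <- pmin(pmax(off, -1000L), 1000L - w)
    names(off) <- bound
    gi <- match(bound, genes$gene_id)
    tss <- ifelse(genes$strand[gi] == "+", genes$start[gi], genes$end[gi] - 1L)
    summit <- as.integer(ifelse(genes$strand[gi] == "+", tss + off, tss - off))
    names(summit) <- bound

    truth <- list(
      bound_gene_ids = bound,
      planted_motif_offsets = off,
      planted_peak_summits = summit,
      edge_signs = setNames(rep(0L, n_total + length(imir)),
                            c(genes$gene_id, names(mirna_gene_map))),
      planted_ffls = data.frame(mirna = character(), target = character(),
                                type = character(), stringsAsFactors = FALSE)
    )
    list(genes = genes, mirna_gene_map = mirna_gene_map, truth = truth)
  })
}

#' Simulate a two-replicate ChIP experiment
#'
#' Each bound gene gets one peak per replicate whose summit is the planted
#' motif position plus Normal(0, `summit_jitter_sd`) jitter, with
#' significance far beyond the high-confidence threshold; each replicate
#' additionally gets `n_noise_peaks_per_replicate` independently placed
#' noise peaks whose significance is above p = 1e-5, so they fail both the
#' replicate-support and the significance filters downstream.
#'
#' @param annotation output of [simulate_annotation()].
#' @param cfg a [sim_config()].
#' @return list of two peak data.frames (`rep1`, `rep2`), each with columns
#'   chrom, start, end, name, neg_log10_p, summit, replicate.
#' @export
simulate_chip_experiment <- function(annotation, cfg) {
  genes <- annotation$genes
  truth <- annotation$truth
  stopifnot(all(truth$bound_gene_ids %in% genes$gene_id))
  with_seed(cfg$seed + 202L, {
    one_rep <- function(rep_id) {
      gi <- match(truth$bound_gene_ids, genes$gene_id)
      n <- length(gi)
      summit <- truth$planted_peak_summits +
        as.integer(round(rnorm(n, 0, cfg$summit_jitter_sd)))
      summit <- pmax(summit, 150L)
      signal <- data.frame(
        chrom = genes$chrom[gi],
        start = summit - 150L, end = summit + 150L,
        name = sprintf("%s_peak_%d", rep_id, seq_len(n)),
        neg_log10_p = runif(n, 12, 30),
        summit = summit, replicate = rep(rep_id, n),
        stringsAsFactors = FALSE
      )
      m <- cfg$n_noise_peaks_per_replicate
      if (m > 0) {
        chrom <- paste0("chr", sample.int(cfg$n_chroms, m, replace = TRUE))
        nsum <- as.integer(round(runif(m, 150, cfg$chrom_length - 150)))
        noise <- data.frame(
          chrom = chrom, start = nsum - 150L, end = nsum + 150L,
          name = sprintf("%s_noise_%d", rep_id, seq_len(m)),
          neg_log10_p = runif(m, 2, 4.9),
          summit = nsum, replicate = rep(rep_id, m),
          stringsAsFactors = FALSE
        )
        signal <- rbind(signal, noise)
      }
      signal <- signal[order(signal$chrom, signal$summit), , drop = FALSE]
      rownames(signal) <- NULL
      signal
    }
    list(rep1 = one_rep("rep1"), rep2 = one_rep("rep2"))
  })
}

#' Simulate the loss-of-function differential-expression contrast
#'
#' Plants `n_planted_c4` coherent type-IV loops and
#' `n_planted_per_other_type` loops of each remaining type. In the mutant
#' contrast a TF-repressed feature goes up (log2FC = +|Normal(effect)|) and
#' a TF-activated feature goes down; planted features get adjusted p-values
#' well below `alpha_sig`. Null features get Normal(0, `null_lfc_sd`) fold
#' changes with uniform p-values, so about `alpha_sig` of them are flagged.
#' The miRNA->target map embeds every planted loop among decoy targets drawn
#' from null genes.
#'
#' @param annotation output of [simulate_annotation()].
#' @param cfg a [sim_config()].
#' @return list: `gene_de`, `mirna_de` (data.frames feature_id, log2fc,
#'   pvalue, padj), `target_map` (data.frame mirna_id, target_id), and the
#'   updated `truth` (edge_signs over mature miRNA and gene ids;
#'   planted_ffls).
#' @export
simulate_expression <- function(annotation, cfg) {
  genes <- annotation$genes
  truth <- annotation$truth
  mirnas <- names(annotation$mirna_gene_map)
  gene_ids <- genes$gene_id[genes$biotype == "protein_coding"]

  n_other <- cfg$n_planted_per_other_type
  up_types <- c(rep("C4", cfg$n_planted_c4), rep("I2", n_other))
  down_types <- c(rep("I1", n_other), rep("C3", n_other))
  n_loops <- length(up_types) + length(down_types)
  tpm <- cfg$targets_per_mirna
  if (n_loops > length(gene_ids)) {
    stop("capacity error: ", n_loops, " planted loops need as many distinct ",
         "targets but only ", length(gene_ids), " genes are available")
  }
  # planted loops pack each miRNA's map entry before using the next miRNA,
  # emulating the concentrated anticorrelation pattern of a miR157-like
  # regulator with a whole target family responding
  need_up <- ceiling(length(up_types) / tpm)
  need_down <- ceiling(length(down_types) / tpm)
  if (need_up + need_down + cfg$n_de_background_mirnas > length(mirnas)) {
    stop("capacity error: planted loops plus background DE miRNAs need ",
         need_up + need_down + cfg$n_de_background_mirnas,
         " miRNAs but only ", length(mirnas), " are available")
  }

  with_seed(cfg$seed + 303L, {
    up_pool <- mirnas[seq_len(need_up)]
    down_pool <- mirnas[need_up + seq_len(need_down)]
    bg_mirnas <- mirnas[need_up + need_down +
                        seq_len(cfg$n_de_background_mirnas)]

    targets <- sample(gene_ids, n_loops)
    # DE genes outside the miRNA-target structure, alternating signs
    bg_genes <- sample(setdiff(gene_ids, targets),
                       min(cfg$n_de_background_genes,
                           length(gene_ids) - n_loops))
    ffls <- data.frame(
      mirna = c(up_pool[ceiling(seq_along(up_types) / tpm)],
                down_pool[ceiling(seq_along(down_types) / tpm)]),
      target = targets,
      type = c(up_types, down_types),
      stringsAsFactors = FALSE
    )

    # edge signs: type -> (sign TF->miRNA, sign TF->target)
    type_signs <- list(I1 = c(1L, 1L), I2 = c(-1L, -1L),
                       C3 = c(1L, -1L), C4 = c(-1L, 1L))
    es <- truth$edge_signs
    for (k in seq_len(nrow(ffls))) {
      s <- type_signs[[ffls$type[k]]]
      es[ffls$mirna[k]] <- s[1]
      es[ffls$target[k]] <- s[2]
    }
    # DE miRNAs outside any loop, alternating repressed (up in the mutant)
    # and activated (down)
    if (length(bg_mirnas)) {
      es[bg_mirnas] <- rep(c(-1L, 1L), length.out = length(bg_mirnas))
    }
    if (length(bg_genes)) {
      es[bg_genes] <- rep(c(-1L, 1L), length.out = length(bg_genes))
    }

    draw_de <- function(ids) {
      s <- es[ids]
      lfc <- numeric(length(ids))
      pval <- numeric(length(ids))
      planted <- s != 0L
      # loss-of-function: repressed (-1) goes up, activated (+1) goes down
      mag <- abs(rnorm(sum(planted), cfg$lfc_effect_mean, cfg$lfc_effect_sd))
      lfc[planted] <- -s[planted] * mag
      pval[planted] <- runif(sum(planted), 0, cfg$alpha_sig / 100)
      lfc[!planted] <- rnorm(sum(!planted), 0, cfg$null_lfc_sd)
      pval[!planted] <- runif(sum(!planted))
      data.frame(feature_id = ids, log2fc = lfc, pvalue = pval, padj = pval,
                 stringsAsFactors = FALSE)
    }
    mirna_de <- draw_de(mirnas)
    gene_de <- draw_de(gene_ids)

    # decoys model non-responding miRNA targets: planted targets and the
    # non-target DE background are excluded
    null_genes <- setdiff(gene_ids, c(ffls$target, bg_genes))
    map <- lapply(mirnas, function(m) {
      own <- ffls$target[ffls$mirna == m]
      need <- cfg$targets_per_mirna - length(own)
      if (need > 0) {
        own <- c(own, sample(null_genes, min(need, length(null_genes))))
      }
      data.frame(mirna_id = m, target_id = own, stringsAsFactors = FALSE)
    })
    target_map <- do.call(rbind, map)
    rownames(target_map) <- NULL

    truth$edge_signs <- es
    truth$planted_ffls <- ffls
    truth$background_de_mirnas <- bg_mirnas
    truth$background_de_genes <- bg_genes
    list(gene_de = gene_de, mirna_de = mirna_de, target_map = target_map,
         truth = truth)
  })
}

#' Simulate promoter sequences with planted motif instances
#'
#' One strand-oriented 2001-bp sequence per gene covering TSS +/- 1000 over
#' an i.i.d. uniform ACGT background. Bound genes carry one exact instance
#' of a concrete expansion of the planted IUPAC motif at the offset recorded
#' in the ground truth (the same position the planted ChIP summit uses).
#'
#' @param annotation output of [simulate_annotation()].
#' @param cfg a [sim_config()].
#' @return a [Biostrings::DNAStringSet] named `geneID|chrom:start-end(strand)`
#'   (coordinates 1-based inclusive); the TSS is at position 1001 of every
#'   sequence.
#' @export
simulate_promoters <- function(annotation, cfg) {
  genes <- annotation$genes
  truth <- annotation$truth
  w <- nchar(cfg$planted_motif)
  if (w > 2001L) stop("motif longer than the promoter window")
  with_seed(cfg$seed + 404L, {
    seqs <- character(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      s <- sample(BASES, 2001L, replace = TRUE)
      gid <- genes$gene_id[i]
      if (gid %in% truth$bound_gene_ids) {
        off <- truth$planted_motif_offsets[[gid]]
        inst <- vapply(strsplit(cfg$planted_motif, "")[[1]],
                       function(ch) sample(IUPAC_SETS[[ch]], 1L), character(1))
        pos <- off + 1001L  # offset 0 = TSS at index 1001
        s[pos:(pos + w - 1L)] <- inst
      }
      seqs[i] <- paste(s, collapse = "")
    }
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    lo <- tss - 1000L
    hi <- tss + 1000L
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("%s|%s:%d-%d(%s)", genes$gene_id, genes$chrom,
                          lo + 1L, hi + 1L, genes$strand)
    out
  })
}

#' Run the whole generator
#'
#' Convenience wrapper chaining [simulate_annotation()],
#' [simulate_chip_experiment()], [simulate_expression()] and
#' [simulate_promoters()].
#'
#' @param cfg a [sim_config()].
#' @return list: genes, mirna_gene_map, chip (rep1/rep2), gene_de, mirna_de,
#'   target_map, promoters, truth, cfg.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  chip <- simulate_chip_experiment(ann, cfg)
  expr <- simulate_expression(ann, cfg)
  ann$truth <- expr$truth
  prom <- simulate_promoters(ann, cfg)
  list(genes = ann$genes, mirna_gene_map = ann$mirna_gene_map,
       chip = chip, gene_de = expr$gene_de, mirna_de = expr$mirna_de,
       target_map = expr$target_map, promoters = prom,
       truth = expr$truth, cfg = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard-format files the downstream modules read: annotation
#' as GFF3 (1-based inclusive) and tabular TSV (0-based half-open), peaks as
#' BED-like TSV per replicate, promoters as FASTA, DE tables and the target
#' map as TSV, and the ground truth as JSON.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gff = file.path(dir, "annotation.gff3"),
    genes = file.path(dir, "gene_models.tsv"),
    rep1 = file.path(dir, "chip_rep1_peaks.tsv"),
    rep2 = file.path(dir, "chip_rep2_peaks.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    gene_de = file.path(dir, "gene_de.tsv"),
    mirna_de = file.path(dir, "mirna_de.tsv"),
    target_map = file.path(dir, "target_map.tsv"),
    mirna_genes = file.path(dir, "mirna_gene_map.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_gene_models_gff3(sim$genes, paths[["gff"]])
  tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(sim$genes, paths[["genes"]])
  tsv(sim$chip$rep1, paths[["rep1"]])
  tsv(sim$chip$rep2, paths[["rep2"]])
  Biostrings::writeXStringSet(sim$promoters, paths[["promoters"]])
  tsv(sim$gene_de, paths[["gene_de"]])
  tsv(sim$mirna_de, paths[["mirna_de"]])
  tsv(sim$target_map, paths[["target_map"]])
  tsv(data.frame(mirna_id = names(sim$mirna_gene_map),
                 host_gene_id = unname(sim$mirna_gene_map)),
      paths[["mirna_genes"]])
  truth <- sim$truth
  truth$planted_motif_offsets <- as.list(truth$planted_motif_offsets)
  truth$planted_peak_summits <- as.list(truth$planted_peak_summits)
  truth$edge_signs <- as.list(truth$edge_signs)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
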