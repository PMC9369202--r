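# Independent brute-force oracles the fast implementations are checked
# against. These deliberately use naive O(n^2) / per-base / per-window /
# exhaustive-enumeration logic and share no code with the package internals.

# Transitive-closure peak merging: full pairwise adjacency + BFS components.
# Returns a list of member-name sets (canonically sorted).
oracle_merge_partition <- function(peaks, params = chip_params()) {
  n <- nrow(peaks)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || peaks$chrom[i] != peaks$chrom[j]) next
      d <- abs(peaks$summit[i] - peaks$summit[j])
      overlaps <- peaks$start[i] < peaks$end[j] && peaks$start[j] < peaks$end[i]
      adj[i, j] <- if (overlaps) d <= params$overlap_merge_dist
                   else d <= params$gap_merge_dist
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  parts <- unname(split(peaks$name, comp))
  parts <- lapply(parts, function(x) sort(x))
  parts[order(vapply(parts, function(x) x[1], character(1)))]
}

merged_partition <- function(merged) {
  parts <- unname(lapply(strsplit(merged$members, ","), sort))
  parts[order(vapply(parts, function(x) x[1], character(1)))]
}

# Per-base window membership: enumerate every bp of the strand-oriented
# candidate window and test summit membership by set inclusion.
oracle_assigned_pairs <- function(hc_peaks, genes, params = chip_params()) {
  out <- character()
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    if (gene$strand == "+") {
      win <- seq(gene$start - params$upstream_window,
                 gene$end + params$downstream_window - 1L)
    } else {
      win <- seq(gene$start - params$downstream_window,
                 gene$end + params$upstream_window - 1L)
    }
    for (i in seq_len(nrow(hc_peaks))) {
      if (hc_peaks$chrom[i] == gene$chrom &&
          hc_peaks$summit[i] %in% win) {
        out <- c(out, paste(gene$gene_id, hc_peaks$summit[i], sep = "@"))
      }
    }
  }
  sort(out)
}

# Naive per-window PWM rescoring, both strands, explicit loops.
oracle_pwm_scan <- function(seq_chr, motif, threshold, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq_chr, "")[[1]]
  w <- motif$width
  L <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_window <- function(win) {
    s <- 0
    for (j in seq_len(w)) {
      b <- match(win[j], bases)
      if (!is.na(b)) s <- s + log2(motif$matrix[j, b] / background[b])
    }
    s
  }
  hits <- data.frame(start_index = integer(), strand = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  for (s in seq_len(L - w + 1L)) {
    win <- chars[s:(s + w - 1L)]
    sc <- score_window(win)
    if (sc >= threshold) {
      hits <- rbind(hits, data.frame(start_index = s, strand = "+",
                                     score = sc, stringsAsFactors = FALSE))
    }
    rc <- rev(unname(comp[win]))
    rc[is.na(rc)] <- "N"
    sc <- score_window(rc)
    if (sc >= threshold) {
      hits <- rbind(hits, data.frame(start_index = s, strand = "-",
                                     score = sc, stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$start_index, hits$strand), , drop = FALSE]
}

# Exhaustive permutation enrichment on a tiny network: iterate over all
# nM! x nT! joint tuple assignments.
oracle_exhaustive_enrichment <- function(net) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  count_net <- function(pm, pt) {
    m <- net$mirna_records[pm, ]
    t <- net$target_records[pt, ]
    counts <- c(I1 = 0L, I2 = 0L, C3 = 0L, C4 = 0L)
    for (k in seq_len(nrow(net$target_map))) {
      mi <- match(net$target_map$mirna_id[k], net$mirna_records$feature_id)
      ti <- match(net$target_map$target_id[k], net$target_records$feature_id)
      mr <- m[mi, ]; tr <- t[ti, ]
      if (!mr$significant || !tr$significant ||
          mr$log2fc == 0 || tr$log2fc == 0) next
      tp <- if (mr$log2fc > 0) { if (tr$log2fc < 0) "C4" else "I2" }
            else               { if (tr$log2fc < 0) "I1" else "C3" }
      counts[tp] <- counts[tp] + 1L
    }
    counts
  }
  nM <- nrow(net$mirna_records); nT <- nrow(net$target_records)
  obs <- count_net(seq_len(nM), seq_len(nT))
  all_counts <- NULL
  for (pm in perms(seq_len(nM))) {
    for (pt in perms(seq_len(nT))) {
      all_counts <- rbind(all_counts, count_net(pm, pt))
    }
  }
  list(observed = obs,
       p = colSums(all_counts > rep(obs, each = nrow(all_counts))) /
         nrow(all_counts),
       mean = colMeans(all_counts))
}

# small peak constructor used across chip tests
pk <- function(chrom, start, end, summit, p = 20, name = NULL, rep = "rep1") {
  n <- length(start)
  data.frame(chrom = chrom, start = start, end = end,
             name = if (is.null(name)) sprintf("p%d", seq_len(n)) else name,
             neg_log10_p = rep_len(p, n), summit = summit,
             replicate = rep_len(rep, n), stringsAsFactors = FALSE)
}

# random peak table on a toy genome
random_peaks <- function(n, seed, chroms = c("chr1", "chr2"), span = 100000) {
  withr::with_seed(seed, {
    summit <- as.integer(round(runif(n, 200, span - 200)))
    half <- as.integer(round(runif(n, 50, 400)))
    off <- vapply(half, function(h) sample.int(h, 1L) - 1L, integer(1))
    pk(chrom = sample(chroms, n, replace = TRUE),
       start = summit - off, end = summit + (half - off) + 1L,
       summit = summit, p = round(runif(n, 1, 30), 2))
  })
}

# n random uniform-ACGT sequences of the given length
with_seed_dna <- function(seed, n, len) {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    }, character(1)))
  })
}

# tiny DE record table
de_rec <- function(id, lfc, padj = 1e-6, alpha = 0.05) {
  mark_significant(data.frame(feature_id = id, log2fc = lfc,
                              pvalue = padj, padj = padj,
                              stringsAsFactors = FALSE), alpha = alpha)
}
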