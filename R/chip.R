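#' ChIP peak-processing parameters
#'
#' Defaults follow the analysis conventions for MACS-style floral ChIP data:
#' overlapping peaks with summits within 600 bp and non-overlapping peaks
#' with summits within 300 bp are merged; replicate support within 600 bp;
#' high-confidence significance p < 1e-5; candidate-target window from 3 kb
#' upstream of the TSS to 1 kb downstream of the TTS.
#'
#' @param overlap_merge_dist summit distance for merging overlapping peaks, bp.
#' @param gap_merge_dist summit distance for merging disjoint peaks, bp.
#' @param replicate_support_dist max summit distance for replicate support, bp.
#' @param p_threshold p-value cutoff for high-confidence peaks.
#' @param upstream_window bp upstream of the TSS included in the target window.
#' @param downstream_window bp downstream of the TTS included.
#' @return a `chip_params` list.
#' @export
chip_params <- function(overlap_merge_dist = 600, gap_merge_dist = 300,
                        replicate_support_dist = 600, p_threshold = 1e-5,
                        upstream_window = 3000, downstream_window = 1000) {
  p <- list(overlap_merge_dist = overlap_merge_dist,
            gap_merge_dist = gap_merge_dist,
            replicate_support_dist = replicate_support_dist,
            p_threshold = p_threshold,
            upstream_window = upstream_window,
            downstream_window = downstream_window)
  stopifnot(all(unlist(p) >= 0), p$p_threshold <= 1)
  class(p) <- "chip_params"
  p
}

#' Merge peaks by summit distance
#'
#' Transitive closure of the pairwise rule: two peaks merge iff their
#' intervals overlap and their summits are within `overlap_merge_dist`, or
#' their intervals are disjoint and their summits are within
#' `gap_merge_dist`. The merged span is the union of member spans; the
#' merged summit and significance come from the member with the highest
#' -log10 p (ties broken toward the leftmost summit). Idempotent and
#' independent of input order.
#'
#' @param peaks peak data.frame (chrom, start, end, summit, neg_log10_p, and
#'   optionally name/replicate), one replicate at a time.
#' @param params a [chip_params()].
#' @return merged-peak data.frame: chrom, start, end, summit,
#'   best_neg_log10_p, member_count, replicates_supporting, members.
#' @export
merge_peaks <- function(peaks, params = chip_params()) {
  stopifnot(all(peaks$start <= peaks$summit), all(peaks$summit < peaks$end))
  if (!"name" %in% names(peaks)) peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  if (!"replicate" %in% names(peaks)) peaks$replicate <- "rep1"
  peaks <- peaks[order(peaks$chrom, peaks$summit, peaks$start), , drop = FALSE]
  if (nrow(peaks) == 0) return(empty_merged())

  out <- lapply(split(peaks, peaks$chrom), function(pk) {
    n <- nrow(pk)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    max_d <- max(params$overlap_merge_dist, params$gap_merge_dist)
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && pk$summit[j] - pk$summit[i] <= max_d) {
        d <- pk$summit[j] - pk$summit[i]
        overlaps <- pk$start[i] < pk$end[j] && pk$start[j] < pk$end[i]
        hit <- if (overlaps) d <= params$overlap_merge_dist
               else d <= params$gap_merge_dist
        if (hit) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1L
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    rows <- lapply(split(seq_len(n), comp), function(idx) {
      m <- pk[idx, , drop = FALSE]
      best <- which(m$neg_log10_p == max(m$neg_log10_p))
      best <- best[which.min(m$summit[best])]
      data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        summit = m$summit[best], best_neg_log10_p = max(m$neg_log10_p),
        member_count = nrow(m),
        replicates_supporting = paste(sort(unique(m$replicate)), collapse = ","),
        members = paste(m$name, collapse = ","),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$summit, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_merged <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit = integer(), best_neg_log10_p = numeric(),
             member_count = integer(), replicates_supporting = character(),
             members = character(), stringsAsFactors = FALSE)
}

#' High-confidence peaks from two replicates
#'
#' A replicate-1 peak is retained iff some replicate-2 peak on the same
#' chromosome has a summit within `replicate_support_dist`. The retained
#' peak's span is the union with its nearest supporting partner (ties toward
#' the leftmost partner summit) and its significance is the maximum over
#' itself and all supporting partners; the result is then filtered to
#' `best_neg_log10_p > -log10(p_threshold)` and sorted.
#'
#' @param rep1,rep2 merged-peak data.frames (see [merge_peaks()]).
#' @param params a [chip_params()].
#' @return merged-peak data.frame of supported, significant peaks.
#' @export
high_confidence_peaks <- function(rep1, rep2, params = chip_params()) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    warning("empty replicate: no high-confidence peaks")
    return(empty_merged())
  }
  keep <- logical(nrow(rep1))
  out <- rep1
  for (i in seq_len(nrow(rep1))) {
    cand <- which(rep2$chrom == rep1$chrom[i] &
                  abs(rep2$summit - rep1$summit[i]) <= params$replicate_support_dist)
    if (!length(cand)) next
    keep[i] <- TRUE
    d <- abs(rep2$summit[cand] - rep1$summit[i])
    near <- cand[d == min(d)]
    near <- near[which.min(rep2$summit[near])]
    out$start[i] <- min(rep1$start[i], rep2$start[near])
    out$end[i] <- max(rep1$end[i], rep2$end[near])
    out$best_neg_log10_p[i] <- max(rep1$best_neg_log10_p[i],
                                   rep2$best_neg_log10_p[cand])
    out$member_count[i] <- rep1$member_count[i] + rep2$member_count[near]
    out$replicates_supporting[i] <- paste(sort(unique(c(
      strsplit(rep1$replicates_supporting[i], ",")[[1]],
      strsplit(rep2$replicates_supporting[near], ",")[[1]]))), collapse = ",")
  }
  res <- out[keep & out$best_neg_log10_p > -log10(params$p_threshold), ,
             drop = FALSE]
  res <- res[order(res$chrom, res$start, res$summit), , drop = FALSE]
  res <- res[!duplicated(res[c("chrom", "start", "end", "summit")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# strand-oriented candidate-target window, genomic half-open coordinates
gene_window <- function(genes, params) {
  up <- params$upstream_window; down <- params$downstream_window
  lo <- ifelse(genes$strand == "+", genes$start - up, genes$start - down)
  hi <- ifelse(genes$strand == "+", genes$end + down, genes$end + up)
  data.frame(win_lo = lo, win_hi = hi)
}

# signed summit-to-TSS distance in gene orientation (negative = upstream)
summit_to_tss <- function(summit, gene) {
  tss <- if (gene$strand == "+") gene$start else gene$end - 1L
  if (gene$strand == "+") summit - tss else tss - summit
}

#' Assign candidate target genes to high-confidence peaks
#'
#' A gene is a candidate target iff a high-confidence summit lies in the
#' strand-oriented window from `upstream_window` bp upstream of its TSS to
#' `downstream_window` bp downstream of its TTS (gene body included). One
#' row per (gene, peak) pair.
#'
#' @param hc_peaks merged-peak data.frame (see [high_confidence_peaks()]).
#' @param genes gene-model data.frame.
#' @param params a [chip_params()].
#' @return data.frame: gene_id, chrom, peak_start, peak_end, summit,
#'   best_neg_log10_p, summit_to_tss (signed, negative = upstream),
#'   region_class in upstream/genic/downstream.
#' @export
assign_candidate_targets <- function(hc_peaks, genes, params = chip_params()) {
  ov <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  if (nrow(ov) > 1) {
    same <- ov$chrom[-1] == ov$chrom[-nrow(ov)]
    if (any(same & ov$start[-1] < ov$end[-nrow(ov)])) {
      warning("overlapping gene models; assignment is per-gene independent")
    }
  }
  win <- gene_window(genes, params)
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    hits <- which(hc_peaks$chrom == gene$chrom &
                  hc_peaks$summit >= win$win_lo[g] &
                  hc_peaks$summit < win$win_hi[g])
    for (i in hits) {
      s <- hc_peaks$summit[i]
      d <- summit_to_tss(s, gene)
      cls <- if (s >= gene$start && s < gene$end) "genic"
             else if (d < 0) "upstream" else "downstream"
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, chrom = gene$chrom,
        peak_start = hc_peaks$start[i], peak_end = hc_peaks$end[i],
        summit = s, best_neg_log10_p = hc_peaks$best_neg_log10_p[i],
        summit_to_tss = d, region_class = cls, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      peak_start = integer(), peak_end = integer(),
                      summit = integer(), best_neg_log10_p = numeric(),
                      summit_to_tss = integer(), region_class = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$gene_id, res$summit), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Positional profile of summits around a gene anchor
#'
#' For every gene, takes the nearest high-confidence summit (strand-oriented
#' signed distance to the anchor) within `flank` and histograms the
#' distances. Also reports the fraction of candidate-target genes whose
#' nearest summit lies within 500 bp of the TSS.
#'
#' @param hc_peaks merged-peak data.frame.
#' @param genes gene-model data.frame.
#' @param anchor "TSS" or "TTS".
#' @param flank half-window, bp; must be a multiple of `bin`.
#' @param bin bin width, bp.
#' @param params a [chip_params()] (used for the candidate-target fraction).
#' @return list: `histogram` (data.frame bin_lo, bin_hi, count),
#'   `fraction_within_500`, `n_assigned`.
#' @export
peak_location_profile <- function(hc_peaks, genes, anchor = c("TSS", "TTS"),
                                  flank = 3000, bin = 100,
                                  params = chip_params()) {
  anchor <- match.arg(anchor)
  if (bin <= 0) stop("bin must be positive")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  nearest <- function(gene, pos) {
    s <- hc_peaks$summit[hc_peaks$chrom == gene$chrom]
    if (!length(s)) return(NA_integer_)
    d <- if (gene$strand == "+") s - pos else pos - s
    d[which.min(abs(d))]
  }
  dist_anchor <- vapply(seq_len(nrow(genes)), function(g) {
    gene <- genes[g, ]
    pos <- if (anchor == "TSS") {
      if (gene$strand == "+") gene$start else gene$end - 1L
    } else {
      if (gene$strand == "+") gene$end - 1L else gene$start
    }
    nearest(gene, pos)
  }, numeric(1))
  d_in <- dist_anchor[!is.na(dist_anchor) & dist_anchor >= -flank &
                      dist_anchor < flank]
  breaks <- seq(-flank, flank, by = bin)
  idx <- findInterval(d_in, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  hist <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     count = counts)

  assigned <- assign_candidate_targets(hc_peaks, genes, params)
  if (nrow(assigned)) {
    near_tss <- tapply(assigned$summit_to_tss, assigned$gene_id,
                       function(d) d[which.min(abs(d))])
    frac <- mean(abs(near_tss) <= 500)
    n_assigned <- length(near_tss)
  } else {
    frac <- NA_real_; n_assigned <- 0L
  }
  list(histogram = hist, fraction_within_500 = frac, n_assigned = n_assigned)
}

#' Genome-wide distribution of summits over genic context
#'
#' Classifies every high-confidence summit as upstream, genic, downstream
#' (relative to the candidate-target windows of the gene models) or
#' intergenic. When windows of distinct genes both contain a summit the
#' precedence is upstream > genic > downstream, with ties broken toward the
#' gene with the smaller |summit-to-TSS|.
#'
#' @param hc_peaks merged-peak data.frame.
#' @param genes gene-model data.frame.
#' @param params a [chip_params()].
#' @return named numeric vector of fractions over upstream/genic/downstream/
#'   intergenic, summing to 1; per-class counts in attribute `counts`.
#' @export
genic_distribution <- function(hc_peaks, genes, params = chip_params()) {
  classes <- c("upstream", "genic", "downstream", "intergenic")
  win <- gene_window(genes, params)
  cls_of <- vapply(seq_len(nrow(hc_peaks)), function(i) {
    s <- hc_peaks$summit[i]
    hits <- which(genes$chrom == hc_peaks$chrom[i] &
                  s >= win$win_lo & s < win$win_hi)
    if (!length(hits)) return("intergenic")
    cand <- data.frame(cls = character(length(hits)),
                       adist = numeric(length(hits)))
    for (k in seq_along(hits)) {
      gene <- genes[hits[k], ]
      d <- summit_to_tss(s, gene)
      cand$cls[k] <- if (s >= gene$start && s < gene$end) "genic"
                     else if (d < 0) "upstream" else "downstream"
      cand$adist[k] <- abs(d)
    }
    for (cl in c("upstream", "genic", "downstream")) {
      if (any(cand$cls == cl)) return(cl)
    }
    "intergenic"
  }, character(1))
  counts <- setNames(vapply(classes, function(cl) sum(cls_of == cl),
                            integer(1)), classes)
  n <- max(nrow(hc_peaks), 1L)
  frac <- counts / n
  attr(frac, "counts") <- counts
  frac
}
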