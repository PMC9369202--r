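#' Construct a motif model
#'
#' @param id motif identifier.
#' @param matrix numeric width-by-4 matrix of per-position base
#'   probabilities, columns A, C, G, T; rows must sum to 1 (within 1e-6).
#' @param iupac_consensus optional IUPAC consensus of the same width.
#' @return a `motif_model` list (id, width, matrix, iupac_consensus).
#' @export
motif_model <- function(id, matrix, iupac_consensus = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4, nrow(matrix) >= 1,
            all(matrix >= 0))
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    stop("motif matrix rows must sum to 1")
  }
  colnames(matrix) <- BASES
  if (!is.null(iupac_consensus)) {
    iupac_consensus <- check_iupac(iupac_consensus)
    stopifnot(nchar(iupac_consensus) == nrow(matrix))
  }
  structure(list(id = id, width = nrow(matrix), matrix = matrix,
                 iupac_consensus = iupac_consensus),
            class = "motif_model")
}

#' Read a PWM in MEME minimal format
#'
#' Parses the first motif of a MEME minimal-format file. If any matrix cell
#' is exactly zero, a pseudocount of 1e-3 is added to every cell before
#' per-row renormalization.
#'
#' @param path MEME minimal-format text file.
#' @return a [motif_model()].
#' @export
load_pwm <- function(path) {
  lines <- readLines(path)
  mi <- grep("^MOTIF\\b", lines)
  if (!length(mi)) stop("malformed MEME file: no MOTIF line")
  id <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]][2]
  hi <- grep("^letter-probability matrix:", lines)
  hi <- hi[hi > mi[1]]
  if (!length(hi)) stop("malformed MEME file: no letter-probability matrix ",
                        "header after line ", mi[1])
  hdr <- lines[hi[1]]
  w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
  alen <- if (grepl("alength=", hdr))
    as.integer(sub(".*\\balength=\\s*(\\d+).*", "\\1", hdr)) else 4L
  if (is.na(w)) stop("malformed matrix header at line ", hi[1])
  if (!is.na(alen) && alen != 4L)
    stop("alphabet length must be 4 at line ", hi[1])
  rows <- matrix(NA_real_, w, 4)
  ln <- hi[1]
  got <- 0L
  while (got < w) {
    ln <- ln + 1L
    if (ln > length(lines)) stop("unexpected end of file: expected ", w,
                                 " matrix rows, got ", got)
    txt <- trimws(lines[ln])
    if (txt == "") next
    vals <- suppressWarnings(as.numeric(strsplit(txt, "\\s+")[[1]]))
    if (length(vals) != 4 || anyNA(vals)) {
      stop("malformed matrix row at line ", ln, ": expected 4 numeric cells")
    }
    got <- got + 1L
    rows[got, ] <- vals
  }
  if (any(rows == 0)) {
    rows <- rows + 1e-3
  }
  rows <- rows / rowSums(rows)
  motif_model(id = id, matrix = rows)
}

#' Write a motif in MEME minimal format
#'
#' @param motif a [motif_model()].
#' @param path output file.
#' @param background background base frequencies (A, C, G, T).
#' @return invisibly, `path`.
#' @export
write_meme_pwm <- function(motif, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", background[1], background[2],
            background[3], background[4]), "",
    sprintf("MOTIF %s", motif$id),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            motif$width),
    apply(motif$matrix, 1, function(r) sprintf(" %.9f %.9f %.9f %.9f",
                                               r[1], r[2], r[3], r[4]))
  ), con)
  invisible(path)
}

# TSS anchors for a sequence set: explicit data.frame, parsed from the
# simulator's FASTA header convention, or window midpoint by default
get_anchors <- function(seqs, anchors = NULL) {
  if (!is.null(anchors)) {
    stopifnot(all(c("seq_id", "tss_index") %in% names(anchors)),
              nrow(anchors) == length(seqs))
    return(anchors)
  }
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("seq_%d", seq_along(seqs))
  data.frame(seq_id = sub("\\|.*$", "", nm),
             tss_index = as.integer((Biostrings::width(seqs) + 1L) / 2L),
             stringsAsFactors = FALSE)
}

empty_matches <- function() {
  data.frame(seq_id = character(), offset_to_tss = integer(),
             strand = character(), score = numeric(), start_index = integer(),
             stringsAsFactors = FALSE)
}

#' Scan sequences with a PWM
#'
#' Log-odds scoring in bits against a background base distribution, both
#' strands; `N` bases contribute 0 bits. A match is any window scoring at or
#' above the threshold. Offsets are reported for the match's 5'-most base
#' relative to the TSS in gene orientation (so a minus-strand match reports
#' the offset of its rightmost base).
#'
#' @param seqs a [Biostrings::DNAStringSet] of TSS-anchored sequences.
#' @param motif a [motif_model()].
#' @param score_threshold threshold in bits; default
#'   `threshold_frac * max attainable score`.
#' @param background base frequencies (A, C, G, T); default uniform.
#' @param threshold_frac fraction of the maximum score used when
#'   `score_threshold` is NULL.
#' @param anchors optional data.frame (seq_id, tss_index); by default parsed
#'   from the simulator's FASTA headers or set to the window midpoint.
#' @return data.frame: seq_id, offset_to_tss, strand, score, start_index
#'   (1-based window start on the forward sequence).
#' @export
scan_pwm <- function(seqs, motif, score_threshold = NULL,
                     background = rep(0.25, 4), threshold_frac = 0.8,
                     anchors = NULL) {
  stopifnot(inherits(motif, "motif_model"), length(background) == 4,
            abs(sum(background) - 1) < 1e-6)
  anchors <- get_anchors(seqs, anchors)
  lo <- log2(motif$matrix / rep(background, each = motif$width))
  max_score <- sum(apply(lo, 1, max))
  if (is.null(score_threshold)) score_threshold <- threshold_frac * max_score
  if (score_threshold > max_score) {
    warning("score threshold ", format(score_threshold),
            " exceeds the maximum attainable score ", format(max_score))
    return(empty_matches())
  }
  # minus-strand scores come from the reverse-complemented matrix scanned
  # on the forward sequence
  lo_rc <- lo[rev(seq_len(motif$width)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(lo_rc) <- BASES
  w <- motif$width
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(as.character(seqs[[i]]), "")[[1]]
    codes <- match(chars, BASES)  # N and anything else -> NA -> 0 bits
    L <- length(codes)
    if (L < w) { out[[i]] <- empty_matches(); next }
    ns <- L - w + 1L
    score_f <- numeric(ns)
    score_r <- numeric(ns)
    for (j in seq_len(w)) {
      cj <- codes[j:(ns + j - 1L)]
      sf <- lo[j, ][cj]; sf[is.na(sf)] <- 0
      sr <- lo_rc[j, ][cj]; sr[is.na(sr)] <- 0
      score_f <- score_f + sf
      score_r <- score_r + sr
    }
    tss <- anchors$tss_index[i]
    hit_f <- which(score_f >= score_threshold)
    hit_r <- which(score_r >= score_threshold)
    out[[i]] <- data.frame(
      seq_id = rep(anchors$seq_id[i], length(hit_f) + length(hit_r)),
      offset_to_tss = c(hit_f - tss, hit_r + w - 1L - tss),
      strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
      score = c(score_f[hit_f], score_r[hit_r]),
      start_index = c(hit_f, hit_r),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start_index, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan sequences for a degenerate IUPAC pattern
#'
#' Exact degenerate matching on both strands (the reverse complement of the
#' pattern is matched on the forward sequence for the minus strand). Offsets
#' follow the [scan_pwm()] convention.
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param pattern IUPAC string.
#' @param anchors optional (seq_id, tss_index) data.frame.
#' @return data.frame as in [scan_pwm()]; `score` is the match width.
#' @export
iupac_scan <- function(seqs, pattern, anchors = NULL) {
  pattern <- check_iupac(pattern)
  anchors <- get_anchors(seqs, anchors)
  w <- nchar(pattern)
  rc <- revcomp_chr(pattern)
  fwd <- Biostrings::vmatchPattern(pattern, seqs, fixed = "subject")
  rev <- Biostrings::vmatchPattern(rc, seqs, fixed = "subject")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sf <- BiocGenerics::start(fwd[[i]])
    sr <- BiocGenerics::start(rev[[i]])
    tss <- anchors$tss_index[i]
    out[[i]] <- data.frame(
      seq_id = rep(anchors$seq_id[i], length(sf) + length(sr)),
      offset_to_tss = c(sf - tss, sr + w - 1L - tss),
      strand = c(rep("+", length(sf)), rep("-", length(sr))),
      score = rep(w, length(sf) + length(sr)),
      start_index = c(sf, sr),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_matches())
  res <- res[order(res$seq_id, res$start_index, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Positional distribution of motif matches around the TSS
#'
#' @param matches match data.frame from [scan_pwm()] or [iupac_scan()].
#' @param flank half-window, bp.
#' @param bin bin width; must divide `2 * flank`.
#' @return list: `histogram` (bin_lo, bin_hi, count), `modal_bin` (lo, hi of
#'   the most populated bin; ties broken toward the TSS-proximal bin, then
#'   upstream), `total` (matches within the window).
#' @export
positional_distribution <- function(matches, flank = 1000, bin = 50) {
  if (bin <= 0) stop("bin must be positive")
  if ((2 * flank) %% bin != 0) stop("bin must divide 2*flank")
  breaks <- seq(-flank, flank, by = bin)
  off <- matches$offset_to_tss
  off <- off[!is.na(off) & off >= -flank & off < flank]
  idx <- findInterval(off, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  hist <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     count = counts)
  if (sum(counts) == 0) {
    modal <- c(NA_real_, NA_real_)
  } else {
    centers <- (hist$bin_lo + hist$bin_hi) / 2
    best <- which(counts == max(counts))
    best <- best[order(abs(centers[best]), centers[best])][1]
    modal <- c(hist$bin_lo[best], hist$bin_hi[best])
  }
  list(histogram = hist, modal_bin = modal, total = sum(counts))
}

# count matches for either motif representation
count_matches <- function(seqs, motif, score_threshold = NULL,
                          background = rep(0.25, 4), threshold_frac = 0.8) {
  if (is.character(motif)) {
    pattern <- check_iupac(motif)
    sum(Biostrings::vcountPattern(pattern, seqs, fixed = "subject")) +
      sum(Biostrings::vcountPattern(revcomp_chr(pattern), seqs,
                                    fixed = "subject"))
  } else {
    nrow(scan_pwm(seqs, motif, score_threshold = score_threshold,
                  background = background, threshold_frac = threshold_frac))
  }
}

#' Empirical motif over-representation test
#'
#' Counts motif occurrences in the foreground promoters and in `n_bg_sets`
#' random background sets of matched cardinality and lengths; the empirical
#' p-value is `(#{background sets with count >= observed} + 1) /
#' (n_bg_sets + 1)` (add-one, so p is never 0).
#'
#' @param fg_promoters foreground [Biostrings::DNAStringSet].
#' @param motif a [motif_model()] or an IUPAC pattern string.
#' @param n_bg_sets number of background sets (>= 1).
#' @param seed RNG seed for background sampling.
#' @param bg_sampler function(lengths) returning a DNAStringSet of random
#'   genomic sequences; default i.i.d. uniform ACGT.
#' @param score_threshold,background,threshold_frac passed to [scan_pwm()]
#'   when `motif` is a PWM.
#' @return list: `p_value`, `observed`, `bg_counts` (length `n_bg_sets`).
#' @export
overrepresentation_test <- function(fg_promoters, motif, n_bg_sets = 999,
                                    seed = 1L, bg_sampler = NULL,
                                    score_threshold = NULL,
                                    background = rep(0.25, 4),
                                    threshold_frac = 0.8) {
  if (n_bg_sets < 1) stop("n_bg_sets must be >= 1")
  if (is.null(bg_sampler)) bg_sampler <- random_dna
  lens <- Biostrings::width(fg_promoters)
  observed <- count_matches(fg_promoters, motif, score_threshold,
                            background, threshold_frac)
  bg_counts <- with_seed(seed, {
    vapply(seq_len(n_bg_sets), function(k) {
      count_matches(bg_sampler(lens), motif, score_threshold,
                    background, threshold_frac)
    }, numeric(1))
  })
  p <- (sum(bg_counts >= observed) + 1) / (n_bg_sets + 1)
  list(p_value = p, observed = observed, bg_counts = bg_counts)
}
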