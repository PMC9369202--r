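#' Write gene models as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is written 1-based
#' inclusive via rtracklayer.
#'
#' @param genes gene-model data.frame (gene_id, chrom, strand, start, end,
#'   biotype).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$biotype <- genes$biotype
  S4Vectors::mcols(gr)$source <- "fflnet"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` features carrying `ID` and optionally
#'   `biotype` attributes.
#' @return gene-model data.frame with 0-based half-open coordinates.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("biotype" %in% names(mc)) as.character(mc$biotype)
             else rep("protein_coding", length(gr))
  biotype[is.na(biotype)] <- "protein_coding"
  out <- data.frame(
    gene_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read a replicate peak table
#'
#' BED-like TSV in the layout the simulator writes (MACS-style): chrom,
#' start, end, name, neg_log10_p, summit (absolute bp), replicate.
#'
#' @param path TSV file with a header.
#' @return peak data.frame.
#' @export
read_peaks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "neg_log10_p", "summit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- "rep1"
  stopifnot(all(df$start <= df$summit), all(df$summit < df$end),
            all(df$neg_log10_p >= 0))
  df
}

#' Parse TSS anchors from promoter FASTA headers
#'
#' The simulator names promoter sequences `geneID|chrom:start-end(strand)`;
#' the TSS is the window midpoint. Returns one row per sequence.
#'
#' @param promoters a [Biostrings::DNAStringSet] with such names.
#' @return data.frame: seq_id (gene id), tss_index (1-based position of the
#'   TSS within the sequence).
#' @export
promoter_anchors <- function(promoters) {
  nm <- names(promoters)
  gene <- sub("\\|.*$", "", nm)
  data.frame(seq_id = gene,
             tss_index = as.integer((Biostrings::width(promoters) + 1L) / 2L),
             stringsAsFactors = FALSE)
}
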