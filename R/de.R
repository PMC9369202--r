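#' Parse a differential-expression table
#'
#' TSV with header columns `feature_id`, `log2fc`, `pvalue`, `padj` (extra
#' columns ignored). Fold changes are mutant-vs-WT log2 units. Significance
#' is computed at `alpha` on the adjusted p-value (or the raw p-value with
#' `use_padj = FALSE`).
#'
#' @param path TSV file.
#' @param alpha significance level.
#' @param use_padj use `padj` (default) or `pvalue` for the flag.
#' @return data.frame: feature_id, log2fc, pvalue, padj, significant; the
#'   alpha used is stored in attribute `alpha`.
#' @export
parse_de_table <- function(path, alpha = 0.05, use_padj = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  dup <- df$feature_id[duplicated(df$feature_id)]
  if (length(dup)) stop("duplicated feature_id: ",
                        paste(unique(dup), collapse = ", "))
  drop <- is.na(df$log2fc)
  if (any(drop)) {
    warning(sum(drop), " record(s) with NA log2fc dropped")
    df <- df[!drop, , drop = FALSE]
  }
  stopifnot(all(df$pvalue >= 0 & df$pvalue <= 1, na.rm = TRUE),
            all(df$padj >= 0 & df$padj <= 1, na.rm = TRUE))
  mark_significant(df, alpha = alpha, use_padj = use_padj)
}

#' Flag significance on a DE data.frame
#'
#' @param df data.frame with log2fc/pvalue/padj columns.
#' @param alpha significance level.
#' @param use_padj use the adjusted p-value.
#' @return `df` with a logical `significant` column and attribute `alpha`.
#' @export
mark_significant <- function(df, alpha = 0.05, use_padj = TRUE) {
  p <- if (use_padj) df$padj else df$pvalue
  df$significant <- !is.na(p) & p < alpha
  attr(df, "alpha") <- alpha
  rownames(df) <- NULL
  df
}

#' Infer signed TF->feature edges from the loss-of-function contrast
#'
#' A feature up-regulated in the TF mutant is inferred to be repressed by
#' the TF (sign -1); a down-regulated one activated (+1). Non-significant
#' features yield no edge; a significant feature with log2fc exactly 0 is a
#' degenerate case and yields no edge (with a warning).
#'
#' @param records DE data.frame with `significant` (see [mark_significant()]).
#' @param tf TF identifier for the edge source.
#' @return data.frame: source, dest, sign (+1/-1), evidence = "de_inferred".
#' @export
infer_edge_signs <- function(records, tf = "TF") {
  keep <- records$significant & records$log2fc != 0
  if (any(records$significant & records$log2fc == 0)) {
    warning("significant feature with log2fc == 0; no edge inferred")
  }
  data.frame(
    source = rep(tf, sum(keep)),
    dest = records$feature_id[keep],
    sign = -as.integer(sign(records$log2fc[keep])),
    evidence = rep("de_inferred", sum(keep)),
    stringsAsFactors = FALSE
  )
}

#' Classify a miRNA's co-expression category
#'
#' Category I: miRNA significantly up and a strict majority of its
#' significant targets down (the anticorrelated pattern of miR157 and the
#' SPL genes). Category II: miRNA significantly down with a strict majority
#' of significant targets up. Category III: miRNA significant but the
#' target pattern is not anticorrelated (majority co-directional, tie, or
#' no significant targets). Unclassified: miRNA not significant. Invariant
#' to target order.
#'
#' @param mirna one-row DE data.frame (with `significant`) for the miRNA.
#' @param targets DE data.frame of its mapped targets.
#' @return one of "I", "II", "III", "unclassified".
#' @export
classify_mirna_category <- function(mirna, targets) {
  stopifnot(nrow(mirna) == 1)
  if (!mirna$significant) return("unclassified")
  sig <- targets[targets$significant & targets$log2fc != 0, , drop = FALSE]
  n_up <- sum(sig$log2fc > 0)
  n_down <- sum(sig$log2fc < 0)
  n <- n_up + n_down
  if (mirna$log2fc > 0 && n > 0 && n_down * 2 > n) return("I")
  if (mirna$log2fc < 0 && n > 0 && n_up * 2 > n) return("II")
  "III"
}

#' Classify every miRNA in a target map
#'
#' @param mirna_de miRNA DE data.frame with `significant`.
#' @param gene_de gene DE data.frame with `significant`.
#' @param target_map data.frame (mirna_id, target_id).
#' @return data.frame: mirna_id, category, n_significant_targets.
#' @export
classify_all_mirnas <- function(mirna_de, gene_de, target_map) {
  ids <- unique(target_map$mirna_id)
  ids <- ids[ids %in% mirna_de$feature_id]
  rows <- lapply(ids, function(m) {
    tg <- target_map$target_id[target_map$mirna_id == m]
    targets <- gene_de[gene_de$feature_id %in% tg, , drop = FALSE]
    data.frame(
      mirna_id = m,
      category = classify_mirna_category(
        mirna_de[mirna_de$feature_id == m, , drop = FALSE], targets),
      n_significant_targets = sum(targets$significant),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(mirna_id = character(),
                                      category = character(),
                                      n_significant_targets = integer())
  out
}

#' Per-family differential-expression summary
#'
#' Aggregates DE calls by TF family: family size among measured features,
#' number differentially expressed, mean log2 fold change over the DE
#' members only (NA when none), and the up/down tally.
#'
#' @param records DE data.frame with `significant`.
#' @param family_map data.frame (feature_id, family).
#' @return data.frame: family, n_family, n_de, mean_log2fc_de, n_up, n_down.
#' @export
family_de_summary <- function(records, family_map) {
  stopifnot(all(c("feature_id", "family") %in% names(family_map)))
  fams <- unique(family_map$family)
  rows <- lapply(fams, function(f) {
    ids <- family_map$feature_id[family_map$family == f]
    rec <- records[records$feature_id %in% ids, , drop = FALSE]
    de <- rec[rec$significant, , drop = FALSE]
    data.frame(
      family = f, n_family = nrow(rec), n_de = nrow(de),
      mean_log2fc_de = if (nrow(de)) mean(de$log2fc) else NA_real_,
      n_up = sum(de$log2fc > 0), n_down = sum(de$log2fc < 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(family = character(),
                                      n_family = integer(), n_de = integer(),
                                      mean_log2fc_de = numeric(),
                                      n_up = integer(), n_down = integer())
  out
}
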