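FFL_TYPES <- c("I1", "I2", "C3", "C4")

#' Classify a feed-forward loop from its TF edge signs
#'
#' With the miRNA->target edge fixed as repression (-1), the two TF edge
#' signs determine the loop type bijectively: (+1,+1) -> I1, (-1,-1) -> I2,
#' (+1,-1) -> C3, (-1,+1) -> C4. C4 is the coherent case in which the TF
#' activates the target directly while repressing the target's repressor
#' (the HB34 -| miR157 -| SPL10, HB34 -> SPL10 module). A loop is coherent
#' iff sign(TF->miRNA) * (-1) = sign(TF->target).
#'
#' @param sign_tf_mirna,sign_tf_target integer vectors over {+1, -1}.
#' @return character vector over {"I1", "I2", "C3", "C4"}.
#' @export
classify_ffl <- function(sign_tf_mirna, sign_tf_target) {
  stopifnot(length(sign_tf_mirna) == length(sign_tf_target))
  if (any(sign_tf_mirna == 0 | sign_tf_target == 0)) {
    stop("zero edge sign: edges require significance upstream")
  }
  ifelse(sign_tf_mirna > 0,
         ifelse(sign_tf_target > 0, "I1", "C3"),
         ifelse(sign_tf_target > 0, "C4", "I2"))
}

#' Build a TF-miRNA-target network
#'
#' @param mirna_records miRNA DE data.frame with `significant`
#'   (see [mark_significant()]).
#' @param target_records gene DE data.frame with `significant`.
#' @param target_map data.frame (mirna_id, target_id); rows referencing
#'   unmeasured features are dropped with a warning, self-loops are an error.
#' @param tf TF identifier.
#' @return an `ffl_network` list.
#' @export
ffl_network <- function(mirna_records, target_records, target_map,
                        tf = "TF") {
  stopifnot(!anyDuplicated(mirna_records$feature_id),
            !anyDuplicated(target_records$feature_id),
            all(c("mirna_id", "target_id") %in% names(target_map)))
  if (any(target_map$mirna_id == target_map$target_id)) {
    stop("self-loop in target map")
  }
  ok <- target_map$mirna_id %in% mirna_records$feature_id &
        target_map$target_id %in% target_records$feature_id
  if (any(!ok)) {
    warning(sum(!ok), " target-map pair(s) reference unmeasured features; dropped")
    target_map <- target_map[ok, , drop = FALSE]
  }
  structure(list(tf = tf, mirna_records = mirna_records,
                 target_records = target_records, target_map = target_map),
            class = "ffl_network")
}

# per-pair node indices into the miRNA and target record tables
pair_indices <- function(net) {
  list(mi = match(net$target_map$mirna_id, net$mirna_records$feature_id),
       ti = match(net$target_map$target_id, net$target_records$feature_id))
}

# per-type counts from pair-wise lfc/significance vectors; order FFL_TYPES
count_types <- function(lfc_m, sig_m, lfc_t, sig_t) {
  ok <- sig_m & sig_t & lfc_m != 0 & lfc_t != 0
  # TF edge sign = -sign(lfc); code enumerates the four sign pairs
  code <- 1L + (lfc_m[ok] > 0) + 2L * (lfc_t[ok] > 0)
  raw <- tabulate(code, nbins = 4L)  # (m-,t-)=I1 (m+,t-)=C4 (m-,t+)=C3 (m+,t+)=I2
  setNames(raw[c(1L, 4L, 3L, 2L)], FFL_TYPES)
}

#' Enumerate typed feed-forward loops
#'
#' One instance per (significant miRNA, significant mapped target) pair,
#' typed from the DE-inferred TF edge signs. Deterministic order
#' (miRNA id, target id).
#'
#' @param net an [ffl_network()].
#' @return list: `instances` (data.frame tf, mirna, target, type) and
#'   `counts` (named integer vector over I1, I2, C3, C4).
#' @export
enumerate_ffls <- function(net) {
  idx <- pair_indices(net)
  m <- net$mirna_records[idx$mi, ]
  t <- net$target_records[idx$ti, ]
  ok <- m$significant & t$significant & m$log2fc != 0 & t$log2fc != 0
  inst <- data.frame(
    tf = rep(net$tf, sum(ok)),
    mirna = m$feature_id[ok],
    target = t$feature_id[ok],
    type = classify_ffl(-sign(m$log2fc[ok]), -sign(t$log2fc[ok])),
    stringsAsFactors = FALSE
  )
  inst <- inst[order(inst$mirna, inst$target), , drop = FALSE]
  rownames(inst) <- NULL
  counts <- setNames(vapply(FFL_TYPES, function(tp) sum(inst$type == tp),
                            integer(1)), FFL_TYPES)
  list(instances = inst, counts = counts)
}

#' Permutation enrichment of feed-forward loop types
#'
#' Each randomization independently permutes the expression tuples (log2fc,
#' p-values, significance) among the miRNA nodes and, separately, among the
#' target nodes, keeping the miRNA->target topology fixed, and recounts the
#' loop types. The per-type p-value is the fraction of randomizations in
#' which the randomized network has strictly more loops of that type than
#' the observed network; the randomized mean is over the same shuffles.
#'
#' @param net an [ffl_network()].
#' @param n_randomizations number of shuffles (default 10000).
#' @param seed RNG seed.
#' @param shuffle_scope permute tuples among "all" measured features
#'   (default) or only among the "significant" ones.
#' @return an `ffl_enrichment` list: `table` (data.frame type, observed,
#'   randomized_mean, p_value), `total_observed`, `n_randomizations`,
#'   `instances`.
#' @export
permutation_enrichment <- function(net, n_randomizations = 10000L,
                                   seed = 1L,
                                   shuffle_scope = c("all", "significant")) {
  shuffle_scope <- match.arg(shuffle_scope)
  stopifnot(n_randomizations >= 1)
  nM <- nrow(net$mirna_records)
  nT <- nrow(net$target_records)
  if (nM == 0 || nT == 0 || nrow(net$target_map) == 0) {
    stop("degenerate network: no measured features or empty target map")
  }
  idx <- pair_indices(net)
  lfc_m <- net$mirna_records$log2fc
  sig_m <- net$mirna_records$significant
  lfc_t <- net$target_records$log2fc
  sig_t <- net$target_records$significant

  obs <- count_types(lfc_m[idx$mi], sig_m[idx$mi],
                     lfc_t[idx$ti], sig_t[idx$ti])

  poolM <- if (shuffle_scope == "all") seq_len(nM) else which(sig_m)
  poolT <- if (shuffle_scope == "all") seq_len(nT) else which(sig_t)
  rand <- matrix(0L, nrow = n_randomizations, ncol = 4,
                 dimnames = list(NULL, FFL_TYPES))
  with_seed(seed, {
    pm <- seq_len(nM)
    pt <- seq_len(nT)
    for (r in seq_len(n_randomizations)) {
      pm[poolM] <- poolM[sample.int(length(poolM))]
      pt[poolT] <- poolT[sample.int(length(poolT))]
      rand[r, ] <- count_types(lfc_m[pm[idx$mi]], sig_m[pm[idx$mi]],
                               lfc_t[pt[idx$ti]], sig_t[pt[idx$ti]])
    }
  })
  p <- colSums(rand > rep(obs, each = n_randomizations)) / n_randomizations
  tab <- data.frame(
    type = FFL_TYPES,
    observed = as.integer(obs),
    randomized_mean = colMeans(rand),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, total_observed = sum(obs),
                 n_randomizations = as.integer(n_randomizations),
                 instances = enumerate_ffls(net)$instances),
            class = "ffl_enrichment")
}

#' Flag loops with direct ChIP support
#'
#' A loop is direct iff both the miRNA's host gene and the target are
#' candidate ChIP targets of the TF.
#'
#' @param ffls instance data.frame (tf, mirna, target, type).
#' @param chip_targets character vector of candidate-target gene ids.
#' @param mirna_gene_map named character vector, mature miRNA id -> host
#'   gene id.
#' @return `ffls` with a logical `direct` column; unresolvable miRNA ids get
#'   `direct = FALSE` with a warning.
#' @export
annotate_direct <- function(ffls, chip_targets, mirna_gene_map) {
  host <- mirna_gene_map[ffls$mirna]
  if (nrow(ffls) && any(is.na(host))) {
    warning("unresolvable miRNA id(s): ",
            paste(unique(ffls$mirna[is.na(host)]), collapse = ", "))
  }
  ffls$direct <- !is.na(host) & host %in% chip_targets &
    ffls$target %in% chip_targets
  ffls
}

#' Format an enrichment result as a motif-analysis report table
#'
#' Four type rows plus a Total row whose observed count and randomized mean
#' are the sums over types; the stars column marks p < 0.001 with `***`,
#' otherwise `NS`; randomized means are printed to 4 decimals.
#'
#' @param enrichment an `ffl_enrichment`, or a data.frame shaped like its
#'   `table` element.
#' @return data.frame: type, observed, randomized_mean, p_value, stars.
#' @export
format_enrichment_table <- function(enrichment) {
  tab <- if (inherits(enrichment, "ffl_enrichment")) enrichment$table
         else enrichment
  stopifnot(all(c("type", "observed", "randomized_mean") %in% names(tab)),
            identical(tab$type, FFL_TYPES))
  has_p <- "p_value" %in% names(tab)
  labels <- c(I1 = "Incoherent type I", I2 = "Incoherent type II",
              C3 = "Coherent type III", C4 = "Coherent type IV")
  out <- data.frame(
    type = c(unname(labels[tab$type]), "Total"),
    observed = c(tab$observed, sum(tab$observed)),
    randomized_mean = sprintf("%.4f", c(tab$randomized_mean,
                                        sum(tab$randomized_mean))),
    p_value = if (has_p) c(tab$p_value, NA_real_) else NA_real_,
    stars = if (has_p) {
      c(ifelse(tab$p_value < 0.001, "***", "NS"), "")
    } else "",
    stringsAsFactors = FALSE
  )
  out
}

#' Write the enrichment report to TSV
#'
#' @param enrichment an `ffl_enrichment`.
#' @param path output TSV.
#' @return invisibly, the formatted table.
#' @export
write_table1_report <- function(enrichment, path) {
  tab <- format_enrichment_table(enrichment)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
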