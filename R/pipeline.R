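#' Run the full synthetic analysis pipeline
#'
#' simulate -> ChIP consolidation/assignment -> motif scan -> DE
#' integration -> FFL enrichment, with every stage's outputs written before
#' the next starts. Reruns with the same configuration and seed reproduce
#' identical outputs.
#'
#' @param outdir output directory.
#' @param cfg a [sim_config()]; its seed drives every stochastic stage.
#' @param chip a [chip_params()].
#' @param alpha DE significance level.
#' @param n_randomizations FFL permutation count.
#' @param n_bg_sets background sets for the motif over-representation test.
#' @param flank,bin motif positional-histogram window and bin width, bp.
#' @param stages character subset of c("simulate", "chip", "scan",
#'   "integrate", "ffl"); later stages read the files earlier ones wrote,
#'   so a disabled stage requires its outputs to already exist in `outdir`.
#' @return a run report: per-stage record counts, parameter echo, wall
#'   times, the enrichment table, the miRNA category table and a
#'   target-assignment summary.
#' @export
run_pipeline <- function(outdir, cfg = sim_config(), chip = chip_params(),
                         alpha = 0.05, n_randomizations = 10000L,
                         n_bg_sets = 199L, flank = 1000, bin = 50,
                         stages = c("simulate", "chip", "scan",
                                    "integrate", "ffl")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(sim = unclass(cfg), chip = unclass(chip),
                                   alpha = alpha,
                                   n_randomizations = n_randomizations,
                                   n_bg_sets = n_bg_sets,
                                   flank = flank, bin = bin),
                 version = as.character(utils::packageVersion("fflnet")),
                 counts = list(), wall_times = list())
  tic <- function() proc.time()[["elapsed"]]
  run_stage <- function(name, fun) {
    t0 <- tic()
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    report$wall_times[[name]] <<- round(tic() - t0, 3)
    res
  }
  tsv <- function(x, name) {
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", function() {
      s <- simulate_dataset(cfg)
      write_simulation(s, outdir)
      s
    })
    report$counts$genes <- nrow(sim$genes)
    report$counts$peaks_rep1 <- nrow(sim$chip$rep1)
    report$counts$peaks_rep2 <- nrow(sim$chip$rep2)
  }
  genes <- read_gene_models_gff3(file.path(outdir, "annotation.gff3"))
  mirna_map_df <- read.delim(file.path(outdir, "mirna_gene_map.tsv"),
                             stringsAsFactors = FALSE)
  mirna_gene_map <- setNames(mirna_map_df$host_gene_id, mirna_map_df$mirna_id)

  if ("chip" %in% stages) {
    hc <- run_stage("chip", function() {
      rep1 <- merge_peaks(read_peaks(file.path(outdir, "chip_rep1_peaks.tsv")),
                          chip)
      rep2 <- merge_peaks(read_peaks(file.path(outdir, "chip_rep2_peaks.tsv")),
                          chip)
      hc <- high_confidence_peaks(rep1, rep2, chip)
      tsv(hc, "hc_peaks.tsv")
      assignments <- assign_candidate_targets(hc, genes, chip)
      tsv(assignments, "target_assignments.tsv")
      profile <- peak_location_profile(hc, genes, "TSS", params = chip)
      tsv(profile$histogram, "summit_profile_tss.tsv")
      genic <- genic_distribution(hc, genes, chip)
      tsv(data.frame(region = names(genic), fraction = as.numeric(genic)),
          "summit_genic_distribution.tsv")
      list(hc = hc, assignments = assignments, profile = profile,
           genic = genic)
    })
    report$counts$hc_peaks <- nrow(hc$hc)
    report$counts$target_assignments <- nrow(hc$assignments)
    report$assignment_summary <- list(
      n_candidate_genes = length(unique(hc$assignments$gene_id)),
      fraction_within_500bp_of_tss = hc$profile$fraction_within_500,
      genic_distribution = as.list(as.numeric(hc$genic)) |>
        setNames(names(hc$genic))
    )
  }

  if ("scan" %in% stages) {
    scan <- run_stage("scan", function() {
      promoters <- Biostrings::readDNAStringSet(
        file.path(outdir, "promoters.fa"))
      chip_ids <- unique(read.delim(file.path(outdir, "target_assignments.tsv"),
                                    stringsAsFactors = FALSE)$gene_id)
      fg <- promoters[sub("\\|.*$", "", names(promoters)) %in% chip_ids]
      matches <- iupac_scan(fg, cfg$planted_motif)
      tsv(matches, "motif_matches.tsv")
      pos <- positional_distribution(matches, flank = flank, bin = bin)
      tsv(pos$histogram, "motif_positional_histogram.tsv")
      ort <- overrepresentation_test(fg, cfg$planted_motif,
                                     n_bg_sets = n_bg_sets,
                                     seed = cfg$seed + 505L)
      jsonlite::write_json(
        list(observed = ort$observed, p_value = ort$p_value,
             n_bg_sets = n_bg_sets),
        file.path(outdir, "motif_overrepresentation.json"),
        auto_unbox = TRUE, digits = NA)
      list(matches = matches, pos = pos, ort = ort)
    })
    report$counts$motif_matches <- nrow(scan$matches)
    report$motif_summary <- list(modal_bin = scan$pos$modal_bin,
                                 overrepresentation_p = scan$ort$p_value)
  }

  if ("integrate" %in% stages) {
    integ <- run_stage("integrate", function() {
      gene_de <- parse_de_table(file.path(outdir, "gene_de.tsv"), alpha)
      mirna_de <- parse_de_table(file.path(outdir, "mirna_de.tsv"), alpha)
      target_map <- read.delim(file.path(outdir, "target_map.tsv"),
                               stringsAsFactors = FALSE)
      edges <- rbind(infer_edge_signs(mirna_de, "TF"),
                     infer_edge_signs(gene_de, "TF"))
      tsv(edges, "edges.tsv")
      cats <- classify_all_mirnas(mirna_de, gene_de, target_map)
      tsv(cats, "mirna_categories.tsv")
      list(gene_de = gene_de, mirna_de = mirna_de, target_map = target_map,
           edges = edges, categories = cats)
    })
    report$counts$edges <- nrow(integ$edges)
    report$category_table <- integ$categories
  }

  if ("ffl" %in% stages) {
    ffl <- run_stage("ffl", function() {
      gene_de <- parse_de_table(file.path(outdir, "gene_de.tsv"), alpha)
      mirna_de <- parse_de_table(file.path(outdir, "mirna_de.tsv"), alpha)
      target_map <- read.delim(file.path(outdir, "target_map.tsv"),
                               stringsAsFactors = FALSE)
      net <- ffl_network(mirna_de, gene_de, target_map, tf = "TF")
      enr <- permutation_enrichment(net, n_randomizations,
                                    seed = cfg$seed + 606L)
      chip_ids <- unique(read.delim(file.path(outdir, "target_assignments.tsv"),
                                    stringsAsFactors = FALSE)$gene_id)
      inst <- annotate_direct(enr$instances, chip_ids, mirna_gene_map)
      tsv(inst, "ffl_instances.tsv")
      write_table1_report(enr, file.path(outdir, "ffl_enrichment.tsv"))
      jsonlite::write_json(
        list(table = enr$table, total_observed = enr$total_observed,
             n_randomizations = enr$n_randomizations),
        file.path(outdir, "ffl_enrichment.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      enr
    })
    report$counts$ffl_instances <- nrow(ffl$instances)
    report$enrichment_table <- ffl$table
  }

  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  report
}
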