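#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()].
#' Defaults: 12.5 kb stitch distance, 100 kb association window, adjusted
#' p-value thresholds 0.001 (silencing) and 0.05 (time course), promoter
#' -2 kb/+500 bp, binding-site padding 1 kb, top-50 SE listing.
#'
#' @param peaks,chip,input,aerbs,genes,de_sirna,de_e2,pairs input file
#'   paths (BED / bedGraph / GTF / TSV / BEDPE). `aerbs_classes`, `de_e2`
#'   and `pairs` may be NULL; the corresponding outputs are skipped.
#' @param aerbs_classes optional TSV (node_id, epigenetic_class).
#' @param out_dir output directory.
#' @param stitch_distance,window,alpha_sirna,alpha_timecourse,promoter_up,promoter_down,aerbs_pad,top_k
#'   analysis parameters (bp, probabilities, count).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(peaks, chip, input, aerbs, genes, de_sirna,
                            de_e2 = NULL, pairs = NULL,
                            aerbs_classes = NULL, out_dir = "results",
                            stitch_distance = 12500, window = 100000,
                            alpha_sirna = 0.001, alpha_timecourse = 0.05,
                            promoter_up = 2000, promoter_down = 500,
                            aerbs_pad = 1000, top_k = 50) {
  stopifnot(stitch_distance >= 0, window >= 0,
            alpha_sirna > 0, alpha_sirna < 1,
            alpha_timecourse > 0, alpha_timecourse < 1,
            promoter_up >= 0, promoter_down >= 0, aerbs_pad >= 0, top_k >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

log_msg <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

require_input <- function(path, stage) {
  if (is.null(path)) return(invisible(NULL))
  if (!file.exists(path)) {
    stop(sprintf("pipeline stage '%s' aborted: missing input %s",
                 stage, path), call. = FALSE)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Composition of every stage: SE calling (stitch, rank, tangent cutoff)
#' -> binding-site overlap selection -> gene association by center
#' distance -> DE classification -> binding-bias summary -> lncRNA
#' biotype breakdown -> silencing x estrogen cross-tabulation -> ChIA-PET
#' network construction. Writes each stage table plus `report.tsv` with
#' the headline numbers, and logs parameters and input MD5 checksums to
#' `pipeline.log` (and stderr). Re-running with identical inputs and
#' configuration reproduces every output byte for byte. An empty peak
#' file degrades gracefully (zero SEs, empty downstream tables); a
#' missing input aborts naming the stage and the path.
#'
#' @param config [pipeline_config()].
#' @return list with all stage objects (`se`, `se_aerbs`, `associations`,
#'   `labels_sirna`, `labels_e2`, `bias`, `breakdown`, `crosstab`,
#'   `network`, `report`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  inputs <- c(peaks = config$peaks, chip = config$chip, input = config$input,
              aerbs = config$aerbs, genes = config$genes,
              de_sirna = config$de_sirna, de_e2 = config$de_e2,
              pairs = config$pairs, aerbs_classes = config$aerbs_classes)
  for (nm in names(inputs)) require_input(inputs[[nm]], nm)
  params <- config[c("stitch_distance", "window", "alpha_sirna",
                     "alpha_timecourse", "promoter_up", "promoter_down",
                     "aerbs_pad", "top_k")]
  log_msg(log_con, "parameters: ",
          paste(names(params), unlist(params), sep = "=", collapse = " "))
  sums <- tools::md5sum(unlist(inputs))
  log_msg(log_con, "input checksums:")
  for (i in seq_along(sums)) {
    log_msg(log_con, "  ", names(sums)[i], " ", sums[i])
  }

  peaks <- read_bed(config$peaks)
  chip <- read_bedgraph(config$chip)
  input <- read_bedgraph(config$input)
  sites <- read_bed(config$aerbs)
  genes <- read_genes_gtf(config$genes)
  de_sirna <- read_de_table(config$de_sirna)

  se <- call_super_enhancers(peaks, chip, input,
                             se_params(config$stitch_distance))
  log_msg(log_con, "se_caller: ", nrow(se), " stitched regions, ",
          sum(se$is_super), " super-enhancers")
  write_se_table(se, file.path(config$out_dir, "se_table.tsv"))

  supers <- se[se$is_super, , drop = FALSE]
  se_aerbs <- select_se_aerbs(supers, sites)
  log_msg(log_con, "regulatory_integration: ", nrow(se_aerbs),
          " SE-aERBS of ", nrow(supers), " SEs")
  write_se_table(se_aerbs, file.path(config$out_dir, "se_aerbs.tsv"))

  assoc <- associate_genes(se_aerbs, genes, config$window)
  write_tsv(assoc$associations,
            file.path(config$out_dir, "associations.tsv"))
  write_tsv(assoc$nearest, file.path(config$out_dir, "nearest_gene.tsv"))

  labels_sirna <- classify_de(de_sirna, config$alpha_sirna)
  bias <- binding_bias_summary(labels_sirna, sites, genes, config$window)
  write_tsv(bias$table, file.path(config$out_dir, "bias_summary.tsv"))

  assoc_labels <- labels_sirna[
    labels_sirna$gene_id %in% assoc$associations$gene_id, , drop = FALSE]
  de_assoc <- assoc_labels[assoc_labels$label != "unchanged", , drop = FALSE]
  lnc_assoc <- assoc$associations[
    is_lncrna(genes$biotype[match(assoc$associations$gene_id,
                                  genes$gene_id)]) &
      assoc$associations$gene_id %in% de_assoc$gene_id, , drop = FALSE]
  breakdown <- biotype_breakdown(lnc_assoc, genes)
  write_tsv(breakdown$table,
            file.path(config$out_dir, "biotype_breakdown.tsv"))

  labels_e2 <- NULL
  ct <- NULL
  if (!is.null(config$de_e2)) {
    labels_e2 <- classify_de(read_de_table(config$de_e2),
                             config$alpha_timecourse)
    ct <- crosstab_sirna_e2(labels_sirna, labels_e2,
                            unique(assoc$associations$gene_id))
    ct_df <- as.data.frame.table(ct$matrix, stringsAsFactors = FALSE)
    names(ct_df) <- c("sirna", "e2", "n")
    write_tsv(ct_df, file.path(config$out_dir, "crosstab.tsv"))
  }

  network <- NULL
  if (!is.null(config$pairs)) {
    pairs <- read_bedpe(config$pairs)
    nodes <- rbind(
      build_promoter_footprints(genes, config$promoter_up,
                                config$promoter_down)[
        , c("node_id", "node_kind", "chrom", "start", "end")],
      extend_aerbs(sites, config$aerbs_pad)[
        , c("node_id", "node_kind", "chrom", "start", "end")])
    nodes$gene_id <- ifelse(nodes$node_kind == "gene_promoter",
                            sub("^gene:", "", nodes$node_id), NA)
    network <- build_network(pairs, nodes)
    site_classes <- if (!is.null(config$aerbs_classes)) {
      utils::read.delim(config$aerbs_classes, stringsAsFactors = FALSE)
    } else NULL
    network <- annotate_nodes(network, de_sirna, site_classes)
    write_tsv(network$nodes, file.path(config$out_dir, "nodes.tsv"))
    write_tsv(network$edges, file.path(config$out_dir, "edges.tsv"))
    write_network_graphml(network,
                          file.path(config$out_dir, "network.graphml"))
    log_msg(log_con, "chiapet_network: ", nrow(network$edges), " edges, ",
            sum(network$unassigned$n_pairs), " unassigned pairs")
  }

  n_down_assoc <- sum(de_assoc$label == "down")
  report <- data.frame(
    metric = c("n_stitched_regions", "n_SE", "n_SE_aERBS",
               "n_associated_DE_genes", "n_associated_lncRNAs",
               "pct_down_of_SE_associated_DE", "pct_down_bound",
               "pct_up_bound", "top_k"),
    value = c(nrow(se), nrow(supers), nrow(se_aerbs),
              nrow(de_assoc), breakdown$total,
              if (nrow(de_assoc) > 0) {
                round_half_up(100 * n_down_assoc / nrow(de_assoc), 1)
              } else NA,
              bias$table$pct_bound[bias$table$label == "down"],
              bias$table$pct_bound[bias$table$label == "up"],
              config$top_k),
    stringsAsFactors = FALSE)
  write_tsv(report, file.path(config$out_dir, "report.tsv"))
  if (nrow(supers) > 0) {
    write_se_table(supers[seq_len(min(config$top_k, nrow(supers))), ],
                   file.path(config$out_dir, "top_se.tsv"))
  }
  log_msg(log_con, "report written to ",
          file.path(config$out_dir, "report.tsv"))

  invisible(list(se = se, se_aerbs = se_aerbs, associations = assoc,
                 labels_sirna = labels_sirna, labels_e2 = labels_e2,
                 bias = bias, breakdown = breakdown, crosstab = ct,
                 network = network, report = report))
}
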