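#' Select super-enhancers overlapping receptor binding sites
#'
#' Returns the subset of SEs whose stitched interval overlaps at least one
#' binding site (half-open overlap; a shared boundary is not an overlap),
#' with the overlapping site indices attached. The selection is monotone
#' in the site set: adding sites can only add SEs.
#'
#' @param ses region data.frame (from [call_super_enhancers()] or any
#'   interval table with a `region_id` column).
#' @param sites binding-site interval data.frame.
#' @return subset of `ses` with list-column `aerbs_hits` (row indices into
#'   `sites`) and `n_aerbs`.
#' @export
select_se_aerbs <- function(ses, sites) {
  if (nrow(ses) == 0L) {
    out <- ses
    out$n_aerbs <- integer()
    return(out)
  }
  hits <- overlap_pairs(ses, sites)
  sel <- sort(unique(hits$query))
  out <- ses[sel, , drop = FALSE]
  out$aerbs_hits <- lapply(sel, function(i) hits$subject[hits$query == i])
  out$n_aerbs <- lengths(out$aerbs_hits)
  rownames(out) <- NULL
  out
}

#' Classify a differential-expression table
#'
#' `down` iff `adj_p < alpha` and `log2fc < 0`; `up` iff `adj_p < alpha`
#' and `log2fc > 0`; everything else — including an exact zero fold
#' change — is `unchanged`, so the three labels partition the table.
#' Records with missing `adj_p` are skipped with a warning reporting how
#' many were dropped.
#'
#' @param de data.frame with gene_id, log2fc, adj_p.
#' @param alpha significance threshold on the adjusted p-value, in (0, 1).
#' @return data.frame gene_id, label (factor down/up/unchanged).
#' @export
classify_de <- function(de, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  miss <- is.na(de$adj_p)
  if (any(miss)) {
    warning(sprintf("classify_de: skipped %d records with missing adj_p",
                    sum(miss)))
    de <- de[!miss, , drop = FALSE]
  }
  label <- ifelse(de$adj_p < alpha & de$log2fc < 0, "down",
                  ifelse(de$adj_p < alpha & de$log2fc > 0, "up", "unchanged"))
  data.frame(gene_id = de$gene_id,
             label = factor(label, levels = c("down", "up", "unchanged")),
             stringsAsFactors = FALSE)
}

#' Associate regions with gene TSSs by center distance
#'
#' Creates an association for every (region, gene) pair on the same
#' chromosome whose |TSS - region center| is at most `max_distance`
#' (inclusive). A gene may associate with several regions and vice versa.
#' Also reports each region's nearest gene (ties broken by the
#' lexicographically smaller gene_id) — the "first proximal gene TSS".
#'
#' @param regions interval data.frame with `region_id` and `center`
#'   columns (center defaults to the floor midpoint when absent).
#' @param genes gene table with gene_id and tss.
#' @param max_distance association window in bp (default 100 kb).
#' @param edge_based if TRUE, distance is measured from the nearest region
#'   edge instead of the center (0 inside the region).
#' @return list with `associations` (region_id, gene_id, distance) and
#'   `nearest` (region_id, gene_id, distance — one row per region that has
#'   any gene on its chromosome).
#' @export
associate_genes <- function(regions, genes, max_distance = 100000,
                            edge_based = FALSE) {
  stopifnot(max_distance >= 0)
  empty <- data.frame(region_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(genes) == 0L) {
    return(list(associations = empty, nearest = empty))
  }
  if (!"center" %in% names(regions)) {
    regions$center <- floor((regions$start + regions$end) / 2)
  }
  assoc <- vector("list", nrow(regions))
  nearest <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- if (edge_based) {
      pmax(pmax(regions$start[i] - g$tss, g$tss - (regions$end[i] - 1)), 0)
    } else {
      abs(g$tss - regions$center[i])
    }
    keep <- which(d <= max_distance)
    if (length(keep)) {
      assoc[[i]] <- data.frame(region_id = regions$region_id[i],
                               gene_id = g$gene_id[keep],
                               distance = d[keep], stringsAsFactors = FALSE)
    }
    near <- which(d == min(d))
    near <- near[order(g$gene_id[near])][1]
    nearest[[i]] <- data.frame(region_id = regions$region_id[i],
                               gene_id = g$gene_id[near],
                               distance = d[near], stringsAsFactors = FALSE)
  }
  list(associations = if (length(a <- Filter(Negate(is.null), assoc))) do.call(rbind, a) else empty,
       nearest = if (length(p <- Filter(Negate(is.null), nearest))) do.call(rbind, p) else empty)
}

#' Binding-site bias by differential-expression class
#'
#' For each DE class, counts the genes with at least one binding site
#' within `window` bp of their TSS and reports the percentage of the
#' class, rounded half-up to one decimal (empty class -> NA). From the
#' study's printed counts — 485 of 1376 down-regulated and 300 of 1110
#' up-regulated genes bound — this yields 35.2% and 27.0%. A two-sided
#' Fisher exact test on the down/up x bound/unbound 2x2 table is attached
#' as an annotation (it is not part of the published analysis, which
#' reports the bias without a test).
#'
#' @param labels data.frame gene_id, label (from [classify_de()]).
#' @param sites binding-site interval data.frame.
#' @param genes gene table (gene_id, chrom, tss).
#' @param window TSS distance window in bp (default 100 kb).
#' @return list with `table` (label, n_genes, n_bound, pct_bound) and
#'   `fisher_p` (NA when either class is empty).
#' @export
binding_bias_summary <- function(labels, sites, genes, window = 100000) {
  genes <- genes[genes$gene_id %in% labels$gene_id, , drop = FALSE]
  bound_ids <- character()
  if (nrow(genes) > 0L && nrow(sites) > 0L) {
    tss_win <- genomic_intervals(genes$chrom, pmax(genes$tss - window, 0),
                                 genes$tss + window + 1)
    hits <- overlap_pairs(tss_win, sites)
    bound_ids <- unique(genes$gene_id[unique(hits$query)])
  }
  lv <- levels(labels$label)
  n_genes <- vapply(lv, function(l) sum(labels$label == l), 0L)
  n_bound <- vapply(lv, function(l) {
    sum(labels$label == l & labels$gene_id %in% bound_ids)
  }, 0L)
  pct <- ifelse(n_genes > 0, round_half_up(100 * n_bound / n_genes, 1), NA)
  tab <- data.frame(label = lv, n_genes = as.integer(n_genes),
                    n_bound = as.integer(n_bound), pct_bound = pct,
                    stringsAsFactors = FALSE)
  fisher_p <- NA_real_
  dn <- tab[tab$label == "down", ]
  up <- tab[tab$label == "up", ]
  if (nrow(dn) == 1 && nrow(up) == 1 && dn$n_genes > 0 && up$n_genes > 0) {
    m <- matrix(c(dn$n_bound, dn$n_genes - dn$n_bound,
                  up$n_bound, up$n_genes - up$n_bound), nrow = 2)
    fisher_p <- stats::fisher.test(m)$p.value
  }
  list(table = tab, fisher_p = fisher_p)
}

# lncRNA biotypes as annotated in Gencode-style gene models; everything
# that is not protein coding in the generator's vocabulary plus the
# classes the study enumerates.
LNCRNA_BIOTYPES <- c("antisense", "lincRNA", "processed_pseudogene",
                     "processed_transcript",
                     "transcribed_unprocessed_pseudogene", "snoRNA", "TEC")

#' Is a biotype a lncRNA class?
#' @param biotype character vector.
#' @return logical vector.
#' @export
is_lncrna <- function(biotype) biotype %in% LNCRNA_BIOTYPES

#' Per-biotype breakdown of associated genes
#'
#' Counts distinct genes per biotype among an association set; the counts
#' sum exactly to the number of distinct genes (each gene has one
#' biotype).
#'
#' @param associations data.frame with gene_id (e.g., the `associations`
#'   element of [associate_genes()], filtered as desired).
#' @param genes gene table with gene_id and biotype.
#' @return list with `table` (biotype, n, sorted by decreasing n then
#'   biotype) and `total`.
#' @export
biotype_breakdown <- function(associations, genes) {
  ids <- unique(associations$gene_id)
  if (length(ids) == 0L) {
    return(list(table = data.frame(biotype = character(), n = integer()),
                total = 0L))
  }
  bt <- genes$biotype[match(ids, genes$gene_id)]
  tab <- as.data.frame(table(biotype = bt), stringsAsFactors = FALSE)
  names(tab) <- c("biotype", "n")
  tab$n <- as.integer(tab$n)
  tab <- tab[order(-tab$n, tab$biotype), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, total = sum(tab$n))
}

#' Cross-tabulate two differential-expression labelings
#'
#' 3x3 matrix of counts (silencing label x treatment label) restricted to
#' a gene set (typically SE-associated genes). Genes present in only one
#' labeling are never dropped silently: they are counted in `unmeasured`
#' margins, and cell total + margins = |restricted gene universe|.
#'
#' @param sirna_labels,timecourse_labels data.frames from [classify_de()].
#' @param gene_ids character vector restricting the universe; NULL keeps
#'   every gene seen in either labeling.
#' @return list with `matrix` (3x3, rows = siRNA label, cols = time-course
#'   label), `unmeasured_sirna`, `unmeasured_timecourse` (counts), and
#'   `universe` (the gene ids considered).
#' @export
crosstab_sirna_e2 <- function(sirna_labels, timecourse_labels,
                              gene_ids = NULL) {
  lv <- c("down", "up", "unchanged")
  universe <- union(sirna_labels$gene_id, timecourse_labels$gene_id)
  if (!is.null(gene_ids)) universe <- intersect(universe, gene_ids)
  s <- sirna_labels$label[match(universe, sirna_labels$gene_id)]
  t <- timecourse_labels$label[match(universe, timecourse_labels$gene_id)]
  both <- !is.na(s) & !is.na(t)
  m <- table(factor(as.character(s[both]), levels = lv),
             factor(as.character(t[both]), levels = lv))
  m <- matrix(as.integer(m), nrow = 3, dimnames = list(sirna = lv, e2 = lv))
  list(matrix = m,
       unmeasured_sirna = sum(is.na(s)),
       unmeasured_timecourse = sum(!is.na(s) & is.na(t)),
       universe = universe)
}

#' Convert a normalized count to FPKM
#'
#' Fragments per kilobase of exon per million mapped fragments, using the
#' longest isoform's length as the gene's effective length:
#' `count / ((length/1000) * millions)`.
#'
#' @param normalized_count normalized fragment count (>= 0).
#' @param longest_isoform_length effective gene length in bp (>= 1).
#' @param counted_fragments_millions library size in millions (> 0).
#' @return numeric FPKM (vectorized).
#' @export
fpkm_from_counts <- function(normalized_count, longest_isoform_length,
                             counted_fragments_millions) {
  if (any(longest_isoform_length < 1)) {
    stop("longest_isoform_length must be >= 1")
  }
  if (any(counted_fragments_millions <= 0)) {
    stop("counted_fragments_millions must be > 0")
  }
  normalized_count /
    ((longest_isoform_length / 1000) * counted_fragments_millions)
}
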