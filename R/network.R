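#' Build promoter footprint nodes
#'
#' A promoter covers 2 kb upstream and 500 bp downstream of the TSS in the
#' gene's transcriptional sense: `[TSS-2000, TSS+500)` for `+` genes and
#' the genomic mirror `[TSS-499, TSS+2001)` for `-` genes (2500 bp either
#' way, clipped at position 0 near chromosome starts).
#'
#' @param genes gene table with gene_id, chrom, strand, tss.
#' @param upstream,downstream extents in bp (defaults 2000 / 500).
#' @return node data.frame: node_id, node_kind ("gene_promoter"), chrom,
#'   start, end, gene_id.
#' @export
build_promoter_footprints <- function(genes, upstream = 2000,
                                      downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (nrow(genes) == 0L) {
    return(data.frame(node_id = character(), node_kind = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), gene_id = character()))
  }
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss - downstream + 1, genes$tss - upstream)
  end <- ifelse(minus, genes$tss + upstream + 1, genes$tss + downstream)
  data.frame(node_id = paste0("gene:", genes$gene_id),
             node_kind = "gene_promoter",
             chrom = genes$chrom, start = pmax(start, 0), end = end,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Build extended binding-site nodes
#'
#' Each binding site is padded by `pad` bp on both sides (clipped at 0),
#' widening the anchor-capture footprint.
#'
#' @param sites binding-site interval data.frame; an optional
#'   `epigenetic_class` column is carried through.
#' @param pad padding in bp (default 1000).
#' @return node data.frame: node_id, node_kind ("aerbs"), chrom, start,
#'   end, epigenetic_class.
#' @export
extend_aerbs <- function(sites, pad = 1000) {
  stopifnot(pad >= 0)
  if (nrow(sites) == 0L) {
    return(data.frame(node_id = character(), node_kind = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), epigenetic_class = character()))
  }
  data.frame(node_id = sprintf("aerbs:%s:%d-%d", sites$chrom,
                               as.integer(sites$start), as.integer(sites$end)),
             node_kind = "aerbs",
             chrom = sites$chrom,
             start = pmax(sites$start - pad, 0),
             end = sites$end + pad,
             epigenetic_class = if ("epigenetic_class" %in% names(sites)) {
               sites$epigenetic_class
             } else NA_character_,
             stringsAsFactors = FALSE)
}

#' Build the chromatin interaction network
#'
#' Every node footprint overlapping a pair's anchor1 is linked to every
#' node overlapping its anchor2 (self-links discarded; footprints sharing
#' one anchor are never linked to each other — only anchor1/anchor2 links
#' carry interaction evidence). Within each experiment the pair counts
#' connecting a node pair are summed; the edge weight is the mean of those
#' sums across the experiments contributing at least one pair. Node pairs
#' are canonicalized (unordered), so the network is undirected and
#' invariant to pair and experiment order. Pairs with an anchor touching
#' no footprint are tallied as unassigned per experiment.
#'
#' In `first_match` mode each anchor is assigned to at most one node — the
#' one with maximal overlap (ties: first node in table order) — so each
#' pair contributes to at most one edge and pair mass is conserved
#' exactly: assigned + unassigned counts = total input counts per
#' experiment.
#'
#' @param pairs BEDPE data.frame from [read_bedpe()].
#' @param nodes node table (rbind of [build_promoter_footprints()] and
#'   [extend_aerbs()]).
#' @param first_match logical; maximal-overlap single assignment per
#'   anchor (diagnostic mode).
#' @return list: `nodes` (input nodes), `edges` (node_a, node_b,
#'   pair_kind, weight, n_experiments), `unassigned` (experiment_id,
#'   n_pairs, total_count), `assigned_count` (per experiment_id, summed
#'   counts that reached an edge).
#' @export
build_network <- function(pairs, nodes, first_match = FALSE) {
  empty_edges <- data.frame(node_a = character(), node_b = character(),
                            pair_kind = character(), weight = numeric(),
                            n_experiments = integer())
  if (nrow(pairs) == 0L || nrow(nodes) == 0L) {
    unassigned <- if (nrow(pairs)) {
      stats::aggregate(cbind(n_pairs = rep(1L, nrow(pairs)),
                             total_count = pairs$count),
                       by = list(experiment_id = pairs$experiment_id),
                       FUN = sum)
    } else {
      data.frame(experiment_id = character(), n_pairs = integer(),
                 total_count = numeric())
    }
    return(list(nodes = nodes, edges = empty_edges, unassigned = unassigned,
                assigned_count = data.frame(experiment_id = character(),
                                            count = numeric())))
  }
  a1 <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                   end = pairs$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                   end = pairs$end2, stringsAsFactors = FALSE)
  h1 <- overlap_pairs(a1, nodes)
  h2 <- overlap_pairs(a2, nodes)
  if (first_match) {
    pick_best <- function(h) {
      if (nrow(h) == 0L) return(h)
      o <- order(h$query, -h$overlap_bp, h$subject)
      h <- h[o, , drop = FALSE]
      h[!duplicated(h$query), , drop = FALSE]
    }
    h1 <- pick_best(h1)
    h2 <- pick_best(h2)
  }
  n1 <- split(h1$subject, h1$query)
  n2 <- split(h2$subject, h2$query)
  links <- vector("list", nrow(pairs))
  assigned <- logical(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    s1 <- n1[[as.character(p)]]
    s2 <- n2[[as.character(p)]]
    if (is.null(s1) || is.null(s2)) next
    grid <- expand.grid(i = s1, j = s2)
    grid <- grid[grid$i != grid$j, , drop = FALSE]
    if (nrow(grid) == 0L) next
    assigned[p] <- TRUE
    links[[p]] <- data.frame(
      node_a = nodes$node_id[pmin(grid$i, grid$j)],
      node_b = nodes$node_id[pmax(grid$i, grid$j)],
      experiment_id = pairs$experiment_id[p],
      count = pairs$count[p], stringsAsFactors = FALSE)
  }
  links <- Filter(Negate(is.null), links)
  if (length(links) == 0L) {
    edges <- empty_edges
  } else {
    lk <- do.call(rbind, links)
    per_exp <- stats::aggregate(
      count ~ node_a + node_b + experiment_id, data = lk, FUN = sum)
    agg <- stats::aggregate(count ~ node_a + node_b, data = per_exp,
                            FUN = mean)
    nexp <- stats::aggregate(count ~ node_a + node_b, data = per_exp,
                             FUN = length)
    kind_of <- function(id) nodes$node_kind[match(id, nodes$node_id)]
    kinds <- cbind(kind_of(agg$node_a), kind_of(agg$node_b))
    pair_kind <- apply(kinds, 1, function(k) {
      k <- sort(sub("gene_promoter", "gene", k))
      paste(k, collapse = "-")
    })
    edges <- data.frame(node_a = agg$node_a, node_b = agg$node_b,
                        pair_kind = pair_kind, weight = agg$count,
                        n_experiments = as.integer(nexp$count),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  una <- pairs[!assigned, , drop = FALSE]
  unassigned <- if (nrow(una)) {
    stats::aggregate(cbind(n_pairs = rep(1L, nrow(una)),
                           total_count = una$count),
                     by = list(experiment_id = una$experiment_id), FUN = sum)
  } else {
    data.frame(experiment_id = character(), n_pairs = integer(),
               total_count = numeric())
  }
  asg <- pairs[assigned, , drop = FALSE]
  assigned_count <- if (nrow(asg)) {
    stats::aggregate(cbind(count = asg$count),
                     by = list(experiment_id = asg$experiment_id), FUN = sum)
  } else {
    data.frame(experiment_id = character(), count = numeric())
  }
  list(nodes = nodes, edges = edges, unassigned = unassigned,
       assigned_count = assigned_count)
}

#' Annotate network nodes
#'
#' Gene-promoter nodes get the silencing log2 fold change (NA when the
#' gene is absent from the DE table); binding-site nodes get their
#' epigenetic class ("unclassified" when unknown). These are the node
#' colorings of the published network figure.
#'
#' @param network list from [build_network()].
#' @param de data.frame gene_id, log2fc (adj_p ignored if present).
#' @param site_classes optional data.frame node_id, epigenetic_class.
#' @return `network` with `log2fc` and `epigenetic_class` columns on
#'   `nodes`.
#' @export
annotate_nodes <- function(network, de = NULL, site_classes = NULL) {
  nodes <- network$nodes
  nodes$log2fc <- NA_real_
  if (!is.null(de) && nrow(de) > 0L && "gene_id" %in% names(nodes)) {
    idx <- match(nodes$gene_id, de$gene_id)
    nodes$log2fc <- de$log2fc[idx]
  }
  if (!"epigenetic_class" %in% names(nodes)) {
    nodes$epigenetic_class <- NA_character_
  }
  if (!is.null(site_classes) && nrow(site_classes) > 0L) {
    idx <- match(nodes$node_id, site_classes$node_id)
    hit <- !is.na(idx)
    nodes$epigenetic_class[hit] <- site_classes$epigenetic_class[idx[hit]]
  }
  is_site <- nodes$node_kind == "aerbs"
  nodes$epigenetic_class[is_site & is.na(nodes$epigenetic_class)] <-
    "unclassified"
  network$nodes <- nodes
  network
}

#' Export a network as GraphML
#'
#' Writes the node/edge tables through igraph's GraphML writer (plain XML
#' text) with weight, pair_kind and node annotations attached.
#'
#' @param network annotated network list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  nodes <- network$nodes
  vdf <- data.frame(name = nodes$node_id, kind = nodes$node_kind,
                    chrom = nodes$chrom, start = nodes$start,
                    end = nodes$end, stringsAsFactors = FALSE)
  if ("log2fc" %in% names(nodes)) vdf$log2fc <- nodes$log2fc
  if ("epigenetic_class" %in% names(nodes)) {
    vdf$epigenetic_class <- ifelse(is.na(nodes$epigenetic_class), "",
                                   nodes$epigenetic_class)
  }
  edf <- network$edges[, c("node_a", "node_b", "weight", "pair_kind")]
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
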