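test_that("promoter footprints follow strand orientation and clip at zero", {
  plus <- build_promoter_footprints(make_genes("chr1", 10000, "+"))
  expect_equal(c(plus$start, plus$end), c(8000, 10500))
  minus <- build_promoter_footprints(make_genes("chr1", 10000, "-"))
  expect_equal(minus$end - minus$start, 2500)
  expect_equal(c(minus$start, minus$end), c(9501, 12001))
  clipped <- build_promoter_footprints(make_genes("chr1", 1000, "+"))
  expect_equal(c(clipped$start, clipped$end), c(0, 1500))
})

test_that("promoter windows on opposite strands mirror around the TSS", {
  set.seed(41)
  for (tss in sample(5000:1e6, 10)) {
    p <- build_promoter_footprints(make_genes("chr1", tss, "+"))
    m <- build_promoter_footprints(make_genes("chr1", tss, "-"))
    # reflecting the + footprint through the TSS base gives the - footprint
    expect_equal(m$start, 2 * tss - (p$end - 1))
    expect_equal(m$end, 2 * tss - p$start + 1)
  }
})

test_that("binding-site extension pads symmetrically and clips", {
  ext <- extend_aerbs(genomic_intervals("chr1", 5000, 5200), pad = 1000)
  expect_equal(c(ext$start, ext$end), c(4000, 6200))
  clip <- extend_aerbs(genomic_intervals("chr1", 500, 600), pad = 1000)
  expect_equal(c(clip$start, clip$end), c(0, 1600))
  ident <- extend_aerbs(genomic_intervals("chr1", 500, 600), pad = 0)
  expect_equal(c(ident$start, ident$end), c(500, 600))
})

two_node_fixture <- function() {
  genes <- make_genes("chr1", 100000, "+", gene_id = "gA")
  sites <- genomic_intervals("chr1", 5000, 5400)
  rbind(build_promoter_footprints(genes)[, c("node_id", "node_kind", "chrom",
                                             "start", "end")],
        extend_aerbs(sites)[, c("node_id", "node_kind", "chrom", "start",
                                "end")])
}

test_that("a single pair linking a site footprint to a promoter makes one edge", {
  nodes <- two_node_fixture()
  pairs <- data.frame(chrom1 = "chr1", start1 = 4500, end1 = 5500,
                      chrom2 = "chr1", start2 = 98500, end2 = 99500,
                      experiment_id = "e1", count = 1)
  net <- build_network(pairs, nodes)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1.0)
  expect_equal(net$edges$pair_kind, "aerbs-gene")
  expect_equal(nrow(net$unassigned), 0)
})

test_that("edge weight is the mean of per-experiment pair-count sums", {
  nodes <- two_node_fixture()
  pairs <- data.frame(chrom1 = "chr1", start1 = c(4500, 4600),
                      end1 = c(5500, 5600),
                      chrom2 = "chr1", start2 = c(98500, 98600),
                      end2 = c(99500, 99600),
                      experiment_id = c("e1", "e2"), count = c(2, 4))
  net <- build_network(pairs, nodes)
  expect_equal(net$edges$weight, 3.0)
  expect_equal(net$edges$n_experiments, 2L)
})

test_that("an anchor overlapping two promoters fans out into two edges", {
  genes <- make_genes("chr1", c(100000, 100400), "+", gene_id = c("gA", "gB"))
  nodes <- rbind(build_promoter_footprints(genes)[, c("node_id", "node_kind",
                                                      "chrom", "start", "end")],
                 extend_aerbs(genomic_intervals("chr1", 5000, 5400))[
                   , c("node_id", "node_kind", "chrom", "start", "end")])
  pairs <- data.frame(chrom1 = "chr1", start1 = 4500, end1 = 5500,
                      chrom2 = "chr1", start2 = 99000, end2 = 100000,
                      experiment_id = "e1", count = 2)
  net <- build_network(pairs, nodes)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$node_a, c("gene:gA", "gene:gB"))
  # first-match mode assigns the anchor only to its maximal-overlap node
  fm <- build_network(pairs, nodes, first_match = TRUE)
  expect_equal(nrow(fm$edges), 1)
})

test_that("network construction is invariant to pair order and never links same-anchor nodes", {
  set.seed(51)
  genes <- make_genes("chr1", seq(2e5, 1e6, 2e5), "+",
                      gene_id = sprintf("g%d", 1:5))
  sites <- genomic_intervals("chr1", seq(1e4, 5e4, 1e4), seq(1e4, 5e4, 1e4) + 400)
  nodes <- rbind(build_promoter_footprints(genes)[, c("node_id", "node_kind",
                                                      "chrom", "start", "end")],
                 extend_aerbs(sites)[, c("node_id", "node_kind", "chrom",
                                         "start", "end")])
  k <- 20
  s1 <- sample(nodes$start, k, replace = TRUE)
  s2 <- sample(nodes$start, k, replace = TRUE)
  pairs <- data.frame(chrom1 = "chr1", start1 = s1, end1 = s1 + 800,
                      chrom2 = "chr1", start2 = s2, end2 = s2 + 800,
                      experiment_id = sample(c("e1", "e2"), k, TRUE),
                      count = sample(1:4, k, TRUE))
  net <- build_network(pairs, nodes)
  perm <- pairs[sample(k), , drop = FALSE]
  net2 <- build_network(perm, nodes)
  expect_equal(net$edges, net2$edges)
  expect_true(all(net$edges$weight > 0))
  expect_true(all(net$edges$node_a != net$edges$node_b))
})

test_that("first-match mode conserves pair mass exactly", {
  set.seed(61)
  genes <- make_genes("chr1", seq(2e5, 1e6, 2e5), "+",
                      gene_id = sprintf("g%d", 1:5))
  sites <- genomic_intervals("chr1", seq(1e4, 5e4, 1e4),
                             seq(1e4, 5e4, 1e4) + 400)
  nodes <- rbind(build_promoter_footprints(genes)[, c("node_id", "node_kind",
                                                      "chrom", "start", "end")],
                 extend_aerbs(sites)[, c("node_id", "node_kind", "chrom",
                                         "start", "end")])
  k <- 30
  s1 <- sample.int(1.2e6, k)
  s2 <- sample.int(1.2e6, k)
  pairs <- data.frame(chrom1 = "chr1", start1 = s1, end1 = s1 + 1000,
                      chrom2 = "chr1", start2 = s2, end2 = s2 + 1000,
                      experiment_id = "e1", count = sample(1:3, k, TRUE))
  fm <- build_network(pairs, nodes, first_match = TRUE)
  assigned <- if (nrow(fm$assigned_count)) sum(fm$assigned_count$count) else 0
  unassigned <- if (nrow(fm$unassigned)) sum(fm$unassigned$total_count) else 0
  expect_equal(assigned + unassigned, sum(pairs$count))
})

test_that("node annotation attaches log2FC and epigenetic classes with defaults", {
  nodes <- two_node_fixture()
  nodes$gene_id <- ifelse(nodes$node_kind == "gene_promoter", "gA", NA)
  net <- list(nodes = nodes,
              edges = data.frame(node_a = character(), node_b = character(),
                                 pair_kind = character(), weight = numeric(),
                                 n_experiments = integer()))
  ann <- annotate_nodes(net, de = data.frame(gene_id = "gA", log2fc = -1.7))
  expect_equal(ann$nodes$log2fc[ann$nodes$node_kind == "gene_promoter"], -1.7)
  expect_equal(ann$nodes$epigenetic_class[ann$nodes$node_kind == "aerbs"],
               "unclassified")
  # gene absent from the DE table stays, annotated NA
  ann2 <- annotate_nodes(net, de = data.frame(gene_id = "other", log2fc = 1))
  expect_true(is.na(ann2$nodes$log2fc[ann2$nodes$node_kind == "gene_promoter"]))
  # class table keyed by node id
  aid <- nodes$node_id[nodes$node_kind == "aerbs"]
  ann3 <- annotate_nodes(net, site_classes = data.frame(
    node_id = aid, epigenetic_class = "EnhT"))
  expect_equal(ann3$nodes$epigenetic_class[nodes$node_kind == "aerbs"], "EnhT")
})

test_that("GraphML export writes readable XML round-trippable by igraph", {
  nodes <- two_node_fixture()
  nodes$gene_id <- ifelse(nodes$node_kind == "gene_promoter", "gA", NA)
  pairs <- data.frame(chrom1 = "chr1", start1 = 4500, end1 = 5500,
                      chrom2 = "chr1", start2 = 98500, end2 = 99500,
                      experiment_id = "e1", count = 1)
  net <- annotate_nodes(build_network(pairs, nodes),
                        de = data.frame(gene_id = "gA", log2fc = -2))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)
})
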