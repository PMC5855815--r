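se_fixture <- function(starts, ends, chrom = "chr1") {
  data.frame(region_id = sprintf("se%02d", seq_along(starts)),
             chrom = chrom, start = starts, end = ends,
             center = floor((starts + ends) / 2), stringsAsFactors = FALSE)
}

test_that("SE selection by binding-site overlap uses half-open semantics", {
  ses <- se_fixture(0, 10000)
  expect_equal(nrow(select_se_aerbs(
    ses, genomic_intervals("chr1", 9999, 10200))), 1)
  expect_equal(nrow(select_se_aerbs(
    ses, genomic_intervals("chr1", 10000, 10200))), 0)

  ses3 <- se_fixture(c(0, 50000, 100000), c(10000, 60000, 110000))
  sites <- genomic_intervals("chr1", c(5000, 105000), c(5400, 105400))
  sel <- select_se_aerbs(ses3, sites)
  expect_equal(sel$region_id, c("se01", "se03"))
  expect_equal(sel$n_aerbs, c(1L, 1L))
})

test_that("SE selection is a monotone subset of its input", {
  set.seed(21)
  for (rep in 1:10) {
    s <- sort(sample(seq(0, 5e5, 1e4), 6))
    ses <- se_fixture(starts = s, ends = s + 5000)
    sites <- random_peaks(8, max_pos = 5e5, width_max = 500)
    sites$chrom <- "chr1"
    sel1 <- select_se_aerbs(ses, sites[1:4, ])
    sel2 <- select_se_aerbs(ses, sites)
    expect_true(all(sel1$region_id %in% ses$region_id))
    expect_true(all(sel1$region_id %in% sel2$region_id))
  }
})

test_that("DE classification partitions genes at the alpha threshold", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(-2, 3, 0, -1),
                   adj_p = c(1e-5, 0.01, 1e-9, 0.0009))
  lab <- classify_de(de, 0.001)
  expect_equal(as.character(lab$label), c("down", "unchanged", "unchanged", "down"))
  # labels always partition: every gene gets exactly one label
  expect_equal(nrow(lab), 4)
  expect_false(any(is.na(lab$label)))
})

test_that("DE classification skips missing adj_p with a warning", {
  de <- data.frame(gene_id = c("a", "b"), log2fc = c(-2, -2),
                   adj_p = c(NA, 1e-5))
  expect_warning(lab <- classify_de(de, 0.001), "skipped 1")
  expect_equal(lab$gene_id, "b")
})

test_that("gene association matches the quadratic center-distance oracle", {
  # TSS at the region center associates at distance 0; the 100 kb
  # boundary is inclusive
  reg <- se_fixture(0, 10000)
  genes <- make_genes("chr1", tss = c(5000, 105000, 105001))
  got <- associate_genes(reg, genes, 100000)$associations
  expect_equal(got$gene_id, c("g001", "g002"))
  expect_equal(got$distance, c(0, 100000))

  set.seed(31)
  for (rep in 1:10) {
    rs <- sample(seq(0, 2e6, 1e4), 5)
    regions <- se_fixture(starts = rs, ends = rs + 8000)
    regions$chrom <- sample(c("chr1", "chr2"), 5, replace = TRUE)
    regions$center <- floor((regions$start + regions$end) / 2)
    genes <- make_genes(sample(c("chr1", "chr2"), 20, replace = TRUE),
                        tss = sample(2e6, 20))
    got <- associate_genes(regions, genes, 100000)$associations
    want <- oracle_associate(regions, genes, 100000)
    o1 <- order(got$region_id, got$gene_id)
    o2 <- order(want$region_id, want$gene_id)
    expect_equal(got[o1, ], want[o2, ], ignore_attr = TRUE)
  }
})

test_that("nearest gene per region breaks distance ties lexicographically", {
  reg <- se_fixture(0, 10000) # center 5000
  genes <- make_genes("chr1", tss = c(4000, 6000), gene_id = c("zzz", "aaa"))
  near <- associate_genes(reg, genes)$nearest
  expect_equal(near$gene_id, "aaa")
  expect_equal(near$distance, 1000)
})

test_that("binding bias reproduces a hand tally and handles empty classes", {
  # 10 genes: 4 down (2 bound), 3 up (0 bound), 3 unchanged
  genes <- make_genes("chr1", tss = seq(1e6, 10e6, by = 1e6),
                      gene_id = sprintf("g%02d", 1:10))
  lab <- data.frame(gene_id = genes$gene_id,
                    label = factor(rep(c("down", "up", "unchanged"),
                                       c(4, 3, 3)),
                                   levels = c("down", "up", "unchanged")))
  sites <- genomic_intervals("chr1", c(1e6 + 5e4, 2e6 - 5e4), c(1e6 + 5.1e4, 2e6 - 4.9e4))
  bias <- binding_bias_summary(lab, sites, genes)
  tab <- bias$table
  expect_equal(tab$n_bound[tab$label == "down"], 2L)
  expect_equal(tab$pct_bound[tab$label == "down"], 50.0)
  expect_equal(tab$pct_bound[tab$label == "up"], 0.0)
  expect_true(all(tab$pct_bound >= 0 & tab$pct_bound <= 100, na.rm = TRUE))
  expect_true(is.finite(bias$fisher_p))

  # empty class reports NA
  lab2 <- lab[lab$label != "up", ]
  lab2$label <- factor(as.character(lab2$label),
                       levels = c("down", "up", "unchanged"))
  bias2 <- binding_bias_summary(lab2, sites, genes)
  expect_true(is.na(bias2$table$pct_bound[bias2$table$label == "up"]))
})

test_that("biotype breakdown conserves totals", {
  genes <- make_genes("chr1", tss = 1:10 * 1000,
                      biotype = rep(c("antisense", "lincRNA", "snoRNA"),
                                    c(5, 3, 2)))
  assoc <- data.frame(gene_id = genes$gene_id[c(1, 2, 2, 6, 9, 10)])
  bk <- biotype_breakdown(assoc, genes)
  expect_equal(bk$total, 5L) # distinct genes
  expect_equal(sum(bk$table$n), bk$total)
  expect_equal(bk$table$n[bk$table$biotype == "antisense"], 2L)
  empty <- biotype_breakdown(data.frame(gene_id = character()), genes)
  expect_equal(empty$total, 0L)
})

test_that("siRNA x E2 crosstab counts cells and unmeasured margins exactly", {
  s <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                  label = factor(c("down", "down", "up", "unchanged", "up"),
                                 levels = c("down", "up", "unchanged")))
  t <- data.frame(gene_id = c("a", "b", "c", "d", "f"),
                  label = factor(c("up", "unchanged", "down", "unchanged", "down"),
                                 levels = c("down", "up", "unchanged")))
  ct <- crosstab_sirna_e2(s, t)
  expect_equal(ct$matrix["down", "up"], 1L)
  expect_equal(ct$matrix["down", "unchanged"], 1L)
  expect_equal(ct$matrix["up", "down"], 1L)
  expect_equal(ct$matrix["unchanged", "unchanged"], 1L)
  # conservation: cells + unmeasured margins = |universe|
  expect_equal(sum(ct$matrix) + ct$unmeasured_sirna +
                 ct$unmeasured_timecourse, length(ct$universe))

  # disjoint universes: everything lands in unmeasured margins
  t2 <- data.frame(gene_id = c("x", "y"),
                   label = factor(c("down", "up"),
                                  levels = c("down", "up", "unchanged")))
  ct2 <- crosstab_sirna_e2(s, t2)
  expect_equal(sum(ct2$matrix), 0L)
  expect_equal(ct2$unmeasured_sirna + ct2$unmeasured_timecourse,
               length(ct2$universe))

  # all genes unchanged in both: single nonzero cell
  u <- data.frame(gene_id = c("a", "b"),
                  label = factor(c("unchanged", "unchanged"),
                                 levels = c("down", "up", "unchanged")))
  ct3 <- crosstab_sirna_e2(u, u)
  expect_equal(ct3$matrix["unchanged", "unchanged"], 2L)
  expect_equal(sum(ct3$matrix), 2L)
})

test_that("FPKM follows the longest-isoform formula", {
  expect_equal(fpkm_from_counts(0, 1000, 10), 0)
  expect_equal(fpkm_from_counts(1000, 2000, 10), 50)
  # doubling the length halves the FPKM
  expect_equal(fpkm_from_counts(1000, 4000, 10),
               fpkm_from_counts(1000, 2000, 10) / 2)
  expect_error(fpkm_from_counts(10, 0, 10), "longest_isoform_length")
  expect_error(fpkm_from_counts(10, 1000, 0), "millions")
})
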