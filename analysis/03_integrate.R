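#!/usr/bin/env Rscript
# Regulatory integration: select SEs overlapping ERalpha binding sites
# (SE-aERBS), associate them with gene TSSs within 100 kb of the SE
# center, classify the silencing and estrogen time-course DE tables, and
# compute the summary statistics: binding bias by DE class, lncRNA
# biotype breakdown of SE-associated genes, and the silencing x estrogen
# cross-tabulation.

suppressPackageStartupMessages(library(aposenet))

sim <- "results/sim"
se <- read_se_table("results/se_table.tsv")
sites <- read_bed(file.path(sim, "aerbs.bed"))
genes <- read_genes_gtf(file.path(sim, "genes.gtf"))
de_sirna <- read_de_table(file.path(sim, "de_sirna.tsv"))
de_e2 <- read_de_table(file.path(sim, "de_e2.tsv"))

sup <- se[se$is_super, , drop = FALSE]
sel <- select_se_aerbs(sup, sites)
write_se_table(sel, "results/se_aerbs.tsv")
cat(nrow(sel), "of", nrow(sup), "super-enhancers overlap a binding site (SE-aERBS)\n")

assoc <- associate_genes(sel, genes, 100000)
write_tsv(assoc$associations, "results/associations.tsv")
write_tsv(assoc$nearest, "results/nearest_gene.tsv")
cat(nrow(assoc$associations), "SE-gene associations within 100 kb;",
    length(unique(assoc$associations$gene_id)), "distinct genes\n")

lab_sirna <- classify_de(de_sirna, 0.001)
lab_e2 <- classify_de(de_e2, 0.05)
cat("silencing DE classes:", sum(lab_sirna$label == "down"), "down,",
    sum(lab_sirna$label == "up"), "up,",
    sum(lab_sirna$label == "unchanged"), "unchanged\n")

bias <- binding_bias_summary(lab_sirna, sites, genes, 100000)
write_tsv(bias$table, "results/bias_summary.tsv")
cat("binding bias by class (", "% of class with a site within 100 kb of TSS):\n")
print(bias$table, row.names = FALSE)
cat("Fisher exact p (down/up x bound):", format(bias$fisher_p, digits = 3), "\n")

assoc_ids <- unique(assoc$associations$gene_id)
de_assoc <- lab_sirna[lab_sirna$gene_id %in% assoc_ids &
                        lab_sirna$label != "unchanged", ]
cat(nrow(de_assoc), "SE-aERBS-associated DE genes;",
    sprintf("%.1f%%", 100 * mean(de_assoc$label == "down")),
    "of them down-regulated\n")

lnc <- assoc$associations[
  is_lncrna(genes$biotype[match(assoc$associations$gene_id,
                                genes$gene_id)]) &
    assoc$associations$gene_id %in% de_assoc$gene_id, ]
bk <- biotype_breakdown(lnc, genes)
write_tsv(bk$table, "results/biotype_breakdown.tsv")
cat("associated DE lncRNAs by biotype (total", bk$total, "):\n")
print(bk$table, row.names = FALSE)

ct <- crosstab_sirna_e2(lab_sirna, lab_e2, assoc_ids)
ct_df <- as.data.frame.table(ct$matrix, stringsAsFactors = FALSE)
names(ct_df) <- c("sirna", "e2", "n")
write_tsv(ct_df, "results/crosstab.tsv")
cat("silencing x estrogen cross-tabulation of SE-associated genes:\n")
print(ct$matrix)
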