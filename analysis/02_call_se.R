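#!/usr/bin/env Rscript
# Call super-enhancers from the simulated peaks and signal tracks:
# ROSE-style stitching (12.5 kb), input-subtracted total-signal ranking,
# and the tangent-slope cutoff on the ranked curve. Scores the calls
# against the planted truth.

suppressPackageStartupMessages(library(aposenet))

sim <- "results/sim"
peaks <- read_bed(file.path(sim, "peaks.bed"))
chip <- read_bedgraph(file.path(sim, "chip.bedgraph"))
input <- read_bedgraph(file.path(sim, "input.bedgraph"))
truth <- utils::read.delim(file.path(sim, "truth_se.tsv"))

se <- call_super_enhancers(peaks, chip, input)
write_se_table(se, "results/se_table.tsv")

sup <- se[se$is_super, , drop = FALSE]
cat(nrow(se), "stitched regions;", nrow(sup), "called super-enhancers\n")
cat("top regions by net signal:\n")
print(utils::head(se[, c("chrom", "start", "end", "n_constituents",
                         "net_signal", "rank", "is_super")], 5),
      row.names = FALSE)

jacc <- vapply(seq_len(nrow(truth)), function(i) {
  if (nrow(sup) == 0) return(0)
  max(vapply(seq_len(nrow(sup)), function(j) {
    interval_jaccard(sup[j, ], truth[i, ])
  }, 0))
}, 0)
cat("per-planted-SE best Jaccard vs called SEs:",
    paste(sprintf("%.3f", jacc), collapse = " "), "\n")
cat("mean:", sprintf("%.3f", mean(jacc)), "\n")
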