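# Independent brute-force oracles used to check the fast implementations.
# These are deliberately naive (quadratic loops, per-base sums) and share
# no code with the functions they verify.

# transitive merge of peaks by repeated pairwise joining: two peaks join
# when same chromosome and gap <= stitch
oracle_stitch <- function(peaks, stitch) {
  n <- nrow(peaks)
  if (n == 0L) return(peaks[, c("chrom", "start", "end")])
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (peaks$chrom[i] == peaks$chrom[j] &&
            max(peaks$start[i], peaks$start[j]) -
            min(peaks$end[i], peaks$end[j]) <= stitch &&
            group[i] != group[j]) {
          group[group == group[j]] <- group[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(group), function(g) {
    sel <- peaks[group == g, , drop = FALSE]
    data.frame(chrom = sel$chrom[1], start = min(sel$start),
               end = max(sel$end), n = nrow(sel))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# exhaustive tangent search: for every candidate index, count points
# strictly above the line of chord slope through it; max count wins,
# ties to the largest index
oracle_cutoff <- function(net) {
  s <- sort(net)
  n <- length(s)
  m <- (s[n] - s[1]) / (n - 1)
  best_count <- -1
  best_i <- NA
  for (i in seq_len(n)) {
    count <- 0
    for (j in seq_len(n)) {
      if (s[j] > s[i] + m * (j - i) + 1e-9) count <- count + 1
    }
    if (count > best_count || (count == best_count && i > best_i)) {
      best_count <- count
      best_i <- i
    }
  }
  s[best_i]
}

# per-base signal sum over a region
oracle_region_signal <- function(track, region) {
  total <- 0
  for (k in seq_len(nrow(track))) {
    if (track$chrom[k] != region$chrom) next
    for (b in seq(track$start[k], track$end[k] - 1)) {
      if (b >= region$start && b < region$end) total <- total + track$value[k]
    }
  }
  total
}

# all-pairs center-to-TSS distance filter
oracle_associate <- function(regions, genes, max_distance) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] != genes$chrom[j]) next
      d <- abs(genes$tss[j] - regions$center[i])
      if (d <= max_distance) {
        out[[length(out) + 1]] <- data.frame(
          region_id = regions$region_id[i], gene_id = genes$gene_id[j],
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(region_id = character(), gene_id = character(),
               distance = numeric())
  }
}

# random peak set on a couple of chromosomes
random_peaks <- function(n, max_pos = 100000, width_max = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
             start = start,
             end = start + sample.int(width_max, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# minimal gene table builder
make_genes <- function(chrom, tss, strand = "+", gene_id = NULL,
                       biotype = "protein_coding", body = 1000) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "-", tss - body + 1, tss)
  data.frame(gene_id = if (is.null(gene_id)) sprintf("g%03d", seq_len(n)) else gene_id,
             gene_name = if (is.null(gene_id)) sprintf("g%03d", seq_len(n)) else gene_id,
             chrom = rep_len(chrom, n), start = start, end = start + body,
             strand = strand, biotype = rep_len(biotype, n),
             longest_isoform_length = body, tss = tss,
             stringsAsFactors = FALSE)
}
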