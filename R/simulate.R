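#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generator. Defaults emulate the
#' structure the analysis assumes: a small three-chromosome genome,
#' clustered high-signal peak groups (planted super-enhancers) against
#' isolated constant-signal background peaks over a uniform input track,
#' binding sites inside a subset of planted SEs, a down-regulation bias
#' for genes near bound SEs, and ChIA-PET loops linking bound SEs to their
#' target promoters plus uniform noise pairs.
#'
#' @param seed master seed; each generator derives its own stream by a
#'   fixed offset so adding one generator never perturbs another.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_genes number of non-overlapping gene bodies.
#' @param n_background_peaks isolated background H3K27ac peaks (> 12.5 kb
#'   from any other peak, so they never stitch).
#' @param n_planted_se planted super-enhancers.
#' @param peaks_per_se constituent peaks per planted SE (800 bp peaks,
#'   1.5 kb gaps — a ~10 kb cluster, well under the stitch distance).
#' @param se_signal_ratio planted/background ChIP signal density ratio.
#' @param aerbs_fraction_of_se fraction of planted SEs receiving 1-3
#'   binding sites.
#' @param p_down_given_bound_se probability that a gene within 100 kb of a
#'   bound SE center is down-regulated upon receptor silencing.
#' @param p_down_background same probability for all other genes. The
#'   remaining mass is split equally between up and unchanged in both
#'   classes.
#' @param pairs_per_planted_loop ChIA-PET pairs per planted SE-promoter
#'   loop.
#' @param n_noise_pairs uniformly placed noise pairs.
#' @param e2_nonresponsive_fraction fraction of SE-associated genes left
#'   unchanged in the estrogen time-course table.
#' @param background_cpm,input_cpm,peak_width background peak signal
#'   density, uniform input density (CPM) and peak width (bp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chr1 = 12e6, chr2 = 10e6, chr3 = 8e6),
                       n_genes = 500,
                       n_background_peaks = 50,
                       n_planted_se = 3,
                       peaks_per_se = 5,
                       se_signal_ratio = 5,
                       aerbs_fraction_of_se = 2 / 3,
                       p_down_given_bound_se = 0.75,
                       p_down_background = 0.4,
                       pairs_per_planted_loop = 5,
                       n_noise_pairs = 5,
                       e2_nonresponsive_fraction = 0.6,
                       background_cpm = 1.0,
                       input_cpm = 0.1,
                       peak_width = 800) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$chrom_sizes) > 0, !is.null(names(cfg$chrom_sizes)),
            cfg$n_genes >= 0, cfg$n_background_peaks >= 0,
            cfg$n_planted_se >= 0, cfg$peaks_per_se >= 1,
            cfg$se_signal_ratio > 0,
            cfg$aerbs_fraction_of_se >= 0, cfg$aerbs_fraction_of_se <= 1,
            cfg$p_down_given_bound_se >= 0, cfg$p_down_given_bound_se <= 1,
            cfg$p_down_background >= 0, cfg$p_down_background <= 1,
            cfg$seed == floor(cfg$seed))
  structure(cfg, class = "sim_config")
}

# biotype sampling weights (Gencode-flavoured vocabulary)
BIOTYPE_WEIGHTS <- c(protein_coding = 0.55, antisense = 0.15,
                     lincRNA = 0.12, processed_pseudogene = 0.08,
                     snoRNA = 0.05, TEC = 0.05)

#' Generate non-overlapping gene models
#'
#' Allocates genes to chromosomes proportionally to length, slots each
#' chromosome into equal bins and places one 2-20 kb gene body uniformly
#' inside its bin — guaranteeing pairwise non-overlap. Strand is random,
#' biotype drawn from a Gencode-flavoured weight table, and the longest
#' isoform spans 30-90% of the body.
#'
#' @param config [sim_config()].
#' @return gene table (as from [read_genes_gtf()]).
#' @export
generate_genes <- function(config) {
  set.seed(config$seed + 101L)
  sizes <- config$chrom_sizes
  n <- config$n_genes
  empty <- data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      biotype = character(),
                      longest_isoform_length = numeric(), tss = numeric())
  if (n == 0L) return(empty)
  alloc <- floor(n * sizes / sum(sizes))
  rem <- n - sum(alloc)
  if (rem > 0) {
    frac <- n * sizes / sum(sizes) - alloc
    alloc[order(-frac)[seq_len(rem)]] <- alloc[order(-frac)[seq_len(rem)]] + 1
  }
  rows <- list()
  for (chrom in names(sizes)) {
    k <- alloc[[chrom]]
    if (k == 0L) next
    bin <- floor(sizes[[chrom]] / k)
    len <- sample(2000:20000, k, replace = TRUE)
    if (any(len >= bin)) stop("genome too small to place genes")
    start <- (seq_len(k) - 1) * bin +
      vapply(bin - len, function(s) sample.int(s, 1) - 1L, 0L)
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = start, end = start + len,
      strand = sample(c("+", "-"), k, replace = TRUE),
      biotype = sample(names(BIOTYPE_WEIGHTS), k, replace = TRUE,
                       prob = BIOTYPE_WEIGHTS),
      longest_isoform_length = pmax(200, round(len * stats::runif(k, 0.3, 0.9))),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(match(genes$chrom, names(sizes)), genes$start), ]
  genes <- cbind(gene_id = sprintf("G%04d", seq_len(nrow(genes))), genes,
                 stringsAsFactors = FALSE)
  genes$gene_name <- genes$gene_id
  genes$tss <- tss_position(genes)
  rownames(genes) <- NULL
  genes[, names(empty)]
}

# minimum distance kept between any two peaks that must not stitch
MIN_PEAK_ISOLATION <- 13000

#' Generate the enhancer landscape
#'
#' Plants `n_planted_se` clusters of `peaks_per_se` peaks (800 bp wide,
#' 1.5 kb gaps) at `se_signal_ratio` times the background ChIP density,
#' each centered 15-90 kb from a randomly chosen gene TSS; scatters
#' isolated constant-density background peaks more than 12.5 kb from any
#' other peak; lays a uniform input track. Background peaks share one
#' density and width, so the background rank curve is flat and the
#' tangent cutoff has no spurious elbow (see the methods vignette for
#' what this idealization does and does not test).
#'
#' @param config [sim_config()].
#' @param genes gene table from [generate_genes()].
#' @return list: `peaks` (intervals + name), `chip`, `input` (signal
#'   tracks), `truth` (se_id, chrom, start, end, center, target_gene).
#' @export
generate_enhancer_landscape <- function(config, genes) {
  set.seed(config$seed + 211L)
  sizes <- config$chrom_sizes
  w <- config$peak_width
  gap <- 1500
  span <- config$peaks_per_se * w + (config$peaks_per_se - 1) * gap
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  too_close <- function(chrom, start, end) {
    p <- placed[placed$chrom == chrom, , drop = FALSE]
    nrow(p) > 0 && any(start - p$end < MIN_PEAK_ISOLATION &
                         p$start - end < MIN_PEAK_ISOLATION)
  }
  se_peaks <- list()
  truth <- list()
  if (config$n_planted_se > 0) {
    if (nrow(genes) == 0L) stop("planting SEs requires genes")
    targets <- genes[sample.int(nrow(genes),
                                min(config$n_planted_se, nrow(genes))), ]
    for (i in seq_len(nrow(targets))) {
      g <- targets[i, ]
      ok <- FALSE
      for (try in 1:200) {
        offset <- sample(c(-1, 1), 1) * sample(15000:90000, 1)
        center <- g$tss + offset
        start <- round(center - span / 2)
        if (start < 0 || start + span > sizes[[g$chrom]]) next
        if (too_close(g$chrom, start, start + span)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place planted SE near ", g$gene_id)
      starts <- start + (seq_len(config$peaks_per_se) - 1) * (w + gap)
      se_peaks[[i]] <- data.frame(chrom = g$chrom, start = starts,
                                  end = starts + w,
                                  name = sprintf("planted_%02d", i),
                                  stringsAsFactors = FALSE)
      placed <- rbind(placed, data.frame(chrom = g$chrom, start = start,
                                         end = start + span))
      truth[[i]] <- data.frame(se_id = sprintf("planted_%02d", i),
                               chrom = g$chrom, start = start,
                               end = start + span,
                               center = floor(start + span / 2),
                               target_gene = g$gene_id,
                               stringsAsFactors = FALSE)
    }
  }
  bg <- list()
  if (config$n_background_peaks > 0) {
    for (i in seq_len(config$n_background_peaks)) {
      ok <- FALSE
      for (try in 1:1000) {
        chrom <- sample(names(sizes), 1, prob = sizes / sum(sizes))
        start <- sample.int(sizes[[chrom]] - w, 1)
        if (too_close(chrom, start, start + w)) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place background peak ", i)
      bg[[i]] <- data.frame(chrom = chrom, start = start, end = start + w,
                            name = sprintf("bg_%03d", i),
                            stringsAsFactors = FALSE)
      placed <- rbind(placed,
                      data.frame(chrom = chrom, start = start, end = start + w))
    }
  }
  peaks <- rbind(do.call(rbind, c(se_peaks, list(NULL))),
                 do.call(rbind, c(bg, list(NULL))))
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character())
  }
  peaks$strand <- "."
  o <- order(match(peaks$chrom, names(sizes)), peaks$start)
  peaks <- peaks[o, , drop = FALSE]
  rownames(peaks) <- NULL
  chip <- data.frame(chrom = peaks$chrom, start = peaks$start,
                     end = peaks$end,
                     value = ifelse(startsWith(peaks$name, "planted"),
                                    config$se_signal_ratio * config$background_cpm,
                                    config$background_cpm),
                     stringsAsFactors = FALSE)
  truth_df <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(se_id = character(), chrom = character(), start = numeric(),
               end = numeric(), center = numeric(), target_gene = character())
  }
  list(peaks = peaks, chip = chip,
       input = uniform_track(sizes, config$input_cpm), truth = truth_df)
}

#' Generate binding sites and differential-expression tables
#'
#' A configured fraction of planted SEs receive 1-3 binding sites (400 bp,
#' inside the SE span, labeled with an epigenetic class). Genes within
#' 100 kb of a bound-SE center are down-regulated upon silencing with
#' probability `p_down_given_bound_se`, all others with
#' `p_down_background`; the remainder splits equally between up and
#' unchanged. Labels are realized as (log2fc, adj_p) pairs matching the
#' shape of a differential-expression fit: down -> log2fc = -|N(1.5,
#' 0.5)|, adj_p ~ U(0, 0.0005); up symmetric; unchanged -> log2fc ~ N(0,
#' 0.2), adj_p ~ U(0.1, 1). The estrogen time-course table is drawn
#' independently: SE-associated genes are non-responsive (unchanged) with
#' probability `e2_nonresponsive_fraction`, otherwise up/down equally;
#' background genes respond with probability 0.2; significant rows get
#' adj_p ~ U(0, 0.04) against the 0.05 threshold.
#'
#' @param config [sim_config()].
#' @param truth planted-SE truth table from [generate_enhancer_landscape()].
#' @param genes gene table.
#' @return list: `sites` (interval table with name, epigenetic_class,
#'   se_id), `truth` (input truth + `bound` flag), `de_sirna`, `de_e2`
#'   (gene_id, log2fc, adj_p), `site_classes` (node_id, epigenetic_class).
#' @export
generate_aerbs_and_de <- function(config, truth, genes) {
  set.seed(config$seed + 307L)
  n_se <- nrow(truth)
  n_bound <- round(config$aerbs_fraction_of_se * n_se)
  bound_idx <- if (n_bound > 0) sort(sample.int(n_se, n_bound)) else integer()
  truth$bound <- seq_len(max(n_se, 0)) %in% bound_idx
  classes <- c("EnhT", "EnhP", "EnhWk")
  sites <- list()
  for (i in bound_idx) {
    k <- sample(1:3, 1)
    start <- truth$start[i] +
      vapply(seq_len(k), function(j) sample.int(truth$end[i] - truth$start[i] - 400L, 1), 0L)
    sites[[length(sites) + 1]] <- data.frame(
      chrom = truth$chrom[i], start = start, end = start + 400,
      name = sprintf("%s_site%d", truth$se_id[i], seq_len(k)),
      epigenetic_class = sample(classes, k, replace = TRUE,
                                prob = c(0.6, 0.25, 0.15)),
      se_id = truth$se_id[i], stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), epigenetic_class = character(),
               se_id = character())
  }
  rownames(sites) <- NULL
  near_center <- function(centers_df) {
    if (nrow(genes) == 0L || nrow(centers_df) == 0L) {
      return(rep(FALSE, nrow(genes)))
    }
    vapply(seq_len(nrow(genes)), function(i) {
      any(centers_df$chrom == genes$chrom[i] &
            abs(centers_df$center - genes$tss[i]) <= 100000)
    }, TRUE)
  }
  bound_gene <- near_center(truth[truth$bound, , drop = FALSE])
  se_assoc_gene <- near_center(truth)
  n <- nrow(genes)
  p_down <- ifelse(bound_gene, config$p_down_given_bound_se,
                   config$p_down_background)
  u <- stats::runif(n)
  label <- ifelse(u < p_down, "down",
                  ifelse(u < p_down + (1 - p_down) / 2, "up", "unchanged"))
  realize <- function(label, alpha_scale) {
    n <- length(label)
    lfc <- stats::rnorm(n, 0, 0.2)
    sig <- label != "unchanged"
    lfc[sig] <- abs(stats::rnorm(sum(sig), 1.5, 0.5)) *
      ifelse(label[sig] == "down", -1, 1)
    adj_p <- stats::runif(n, 0.1, 1)
    adj_p[sig] <- stats::runif(sum(sig), 0, alpha_scale)
    data.frame(gene_id = genes$gene_id, log2fc = lfc, adj_p = adj_p,
               stringsAsFactors = FALSE)
  }
  de_sirna <- realize(label, 0.0005)
  p_resp <- ifelse(se_assoc_gene, 1 - config$e2_nonresponsive_fraction, 0.2)
  u2 <- stats::runif(n)
  label_e2 <- ifelse(u2 < p_resp / 2, "down",
                     ifelse(u2 < p_resp, "up", "unchanged"))
  de_e2 <- realize(label_e2, 0.04)
  site_classes <- if (nrow(sites)) {
    data.frame(node_id = sprintf("aerbs:%s:%d-%d", sites$chrom,
                                 as.integer(sites$start),
                                 as.integer(sites$end)),
               epigenetic_class = sites$epigenetic_class,
               stringsAsFactors = FALSE)
  } else {
    data.frame(node_id = character(), epigenetic_class = character())
  }
  list(sites = sites, truth = truth, de_sirna = de_sirna, de_e2 = de_e2,
       site_classes = site_classes)
}

#' Generate ChIA-PET anchor pairs
#'
#' For each bound planted SE, `pairs_per_planted_loop` pairs anchor the
#' SE's first binding site (anchor1 within site +/- 500 bp, so it falls in
#' the extended site footprint) to the target gene's promoter footprint
#' (anchor2 inside it). `n_noise_pairs` pairs get uniformly random
#' anchors. All anchors are 1 kb; counts are 1 + Poisson(1); one
#' experiment ("sim1").
#'
#' @param config [sim_config()].
#' @param truth bound-annotated truth table from [generate_aerbs_and_de()].
#' @param sites binding-site table from the same.
#' @param genes gene table.
#' @return BEDPE data.frame (see [read_bedpe()]).
#' @export
generate_chiapet <- function(config, truth, sites, genes) {
  set.seed(config$seed + 401L)
  sizes <- config$chrom_sizes
  aw <- 1000
  rows <- list()
  proms <- build_promoter_footprints(genes)
  bound <- truth[truth$bound, , drop = FALSE]
  for (i in seq_len(nrow(bound))) {
    site <- sites[sites$se_id == bound$se_id[i], , drop = FALSE][1, ]
    prom <- proms[proms$gene_id == bound$target_gene[i], , drop = FALSE]
    lo1 <- site$start - 500
    hi1 <- site$end + 500 - aw
    lo2 <- prom$start
    hi2 <- prom$end - aw
    for (p in seq_len(config$pairs_per_planted_loop)) {
      s1 <- if (hi1 > lo1) sample(lo1:hi1, 1) else lo1
      s2 <- if (hi2 > lo2) sample(lo2:hi2, 1) else lo2
      rows[[length(rows) + 1]] <- data.frame(
        chrom1 = site$chrom, start1 = max(s1, 0), end1 = max(s1, 0) + aw,
        chrom2 = prom$chrom, start2 = max(s2, 0), end2 = max(s2, 0) + aw,
        experiment_id = "sim1", count = 1 + stats::rpois(1, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (config$n_noise_pairs > 0) {
    rand_anchor <- function() {
      chrom <- sample(names(sizes), 1, prob = sizes / sum(sizes))
      start <- sample.int(sizes[[chrom]] - aw, 1)
      list(chrom = chrom, start = start)
    }
    for (p in seq_len(config$n_noise_pairs)) {
      a <- rand_anchor()
      b <- rand_anchor()
      rows[[length(rows) + 1]] <- data.frame(
        chrom1 = a$chrom, start1 = a$start, end1 = a$start + aw,
        chrom2 = b$chrom, start2 = b$start, end2 = b$start + aw,
        experiment_id = "sim1", count = 1 + stats::rpois(1, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      experiment_id = character(), count = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and write the full synthetic input bundle
#'
#' Runs all generators off one master seed and, when `out_dir` is given,
#' writes genes.gtf, peaks.bed, chip.bedgraph, input.bedgraph, aerbs.bed,
#' aerbs_classes.tsv, de_sirna.tsv, de_e2.tsv, pairs.bedpe and
#' truth_se.tsv with deterministic formatting (fixed seed implies
#' byte-identical files).
#'
#' @param config [sim_config()].
#' @param out_dir output directory (created if missing); NULL keeps
#'   everything in memory.
#' @return list with genes, peaks, chip, input, sites, site_classes,
#'   truth, de_sirna, de_e2, pairs and, when written, `paths`.
#' @export
simulate_bundle <- function(config = sim_config(), out_dir = NULL) {
  genes <- generate_genes(config)
  land <- generate_enhancer_landscape(config, genes)
  ade <- generate_aerbs_and_de(config, land$truth, genes)
  pairs <- generate_chiapet(config, ade$truth, ade$sites, genes)
  bundle <- list(config = config, genes = genes, peaks = land$peaks,
                 chip = land$chip, input = land$input, sites = ade$sites,
                 site_classes = ade$site_classes, truth = ade$truth,
                 de_sirna = ade$de_sirna, de_e2 = ade$de_e2, pairs = pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genes = file.path(out_dir, "genes.gtf"),
      peaks = file.path(out_dir, "peaks.bed"),
      chip = file.path(out_dir, "chip.bedgraph"),
      input = file.path(out_dir, "input.bedgraph"),
      aerbs = file.path(out_dir, "aerbs.bed"),
      aerbs_classes = file.path(out_dir, "aerbs_classes.tsv"),
      de_sirna = file.path(out_dir, "de_sirna.tsv"),
      de_e2 = file.path(out_dir, "de_e2.tsv"),
      pairs = file.path(out_dir, "pairs.bedpe"),
      truth = file.path(out_dir, "truth_se.tsv"))
    write_genes_gtf(genes, paths$genes)
    write_bed(land$peaks, paths$peaks)
    write_bedgraph(land$chip, paths$chip)
    write_bedgraph(land$input, paths$input)
    write_bed(ade$sites[, c("chrom", "start", "end", "name")], paths$aerbs)
    write_tsv(ade$site_classes, paths$aerbs_classes)
    write_tsv(ade$de_sirna, paths$de_sirna)
    write_tsv(ade$de_e2, paths$de_e2)
    write_bedpe(pairs, paths$pairs)
    write_tsv(ade$truth, paths$truth)
    bundle$paths <- paths
  }
  bundle
}
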