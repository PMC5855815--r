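#' Super-enhancer calling parameters
#'
#' Defaults follow the published ROSE defaults: peaks within 12.5 kb of
#' each other are stitched into one candidate region, and no TSS-proximal
#' exclusion is applied (window 0 disables it).
#'
#' @param stitch_distance maximum gap (bp) between consecutive peaks that
#'   still get merged; >= 0.
#' @param tss_exclusion_window half-width (bp) of the window around gene
#'   TSSs whose peaks are dropped before stitching; 0 disables.
#' @return list of class `se_params`.
#' @export
se_params <- function(stitch_distance = 12500, tss_exclusion_window = 0) {
  stopifnot(stitch_distance >= 0, tss_exclusion_window >= 0)
  structure(list(stitch_distance = stitch_distance,
                 tss_exclusion_window = tss_exclusion_window),
            class = "se_params")
}

#' Stitch peaks into candidate enhancer regions
#'
#' Per chromosome, peaks sorted by start are merged transitively whenever
#' the gap between them is at most `stitch_distance`; the stitched interval
#' spans min start to max end of its constituents. Output regions are
#' disjoint, sorted by (chrom, start), and consecutive regions on a
#' chromosome are separated by more than `stitch_distance`. Stitching is
#' idempotent and invariant to input order.
#'
#' @param peaks interval data.frame of H3K27ac peaks.
#' @param params [se_params()].
#' @return data.frame of stitched regions: region_id, chrom, start, end,
#'   n_constituents, plus a list-column `constituents` of row indices into
#'   the (sorted) peak table.
#' @export
stitch_peaks <- function(peaks, params = se_params()) {
  if (nrow(peaks) == 0L) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_constituents = integer()))
  }
  validate_intervals(peaks, "peak")
  gr <- as_granges(peaks)
  # reduce() merges ranges whose gap < min.gapwidth, so gap <= stitch
  # requires min.gapwidth = stitch + 1
  red <- GenomicRanges::reduce(gr, min.gapwidth = params$stitch_distance + 1,
                               ignore.strand = TRUE, with.revmap = TRUE)
  df <- from_granges(red)
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  revmap <- as.list(S4Vectors::mcols(red)$revmap)[o]
  out <- data.frame(
    region_id = sprintf("region_%04d", seq_len(nrow(df))),
    chrom = df$chrom, start = df$start, end = df$end,
    n_constituents = lengths(revmap),
    stringsAsFactors = FALSE
  )
  out$constituents <- revmap
  out
}

#' Rank stitched regions by input-subtracted signal
#'
#' Annotates each region with its total ChIP and input signal (CPM x bp)
#' and the net signal `max(chip - input, 0)` — the floor at zero keeps
#' noise regions where input exceeds ChIP from breaking the cutoff
#' geometry. Regions are sorted by decreasing net signal, ties broken by
#' (chrom, start) ascending, and ranked 1..n.
#'
#' @param regions stitched regions from [stitch_peaks()].
#' @param chip,input signal tracks (CPM).
#' @return `regions` with chip_signal, input_signal, net_signal, rank,
#'   sorted by rank.
#' @export
rank_regions <- function(regions, chip, input) {
  regions$chip_signal <- region_signal(chip, regions)
  regions$input_signal <- region_signal(input, regions)
  regions$net_signal <- pmax(regions$chip_signal - regions$input_signal, 0)
  o <- order(-regions$net_signal, regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  regions
}

#' Tangent-slope cutoff on the ranked signal curve
#'
#' Sorting net signals ascending gives the classic hockey-stick curve;
#' super-enhancers are the points past the elbow, where the curve rises
#' faster than the whole-curve trend. With chord slope
#' `m = (s_n - s_1)/(n - 1)`, the elbow is the tangent point of the lowest
#' line of slope m touching the curve: the index minimizing `s_i - m*i`,
#' equivalently maximizing the number of points strictly above the line
#' through `(i, s_i)`. Ties pick the largest index, so structureless
#' (linear or flat) curves degenerate to threshold `s_n` and an empty SE
#' set. Regions with net signal strictly greater than the returned
#' threshold are super-enhancers; the tangent point itself never is.
#'
#' @param net_signals numeric vector of net signals (any order; sorted
#'   internally).
#' @return the signal threshold (numeric scalar).
#' @export
call_cutoff <- function(net_signals) {
  n <- length(net_signals)
  if (n < 2L) stop("insufficient regions: need at least 2 signal values")
  s <- sort(net_signals)
  m <- (s[n] - s[1]) / (n - 1)
  t <- s - m * seq_len(n)
  i_star <- max(which(t <= min(t) + 1e-12 * max(abs(t), 1)))
  s[i_star]
}

#' Call super-enhancers from peaks and signal tracks
#'
#' The full ROSE-style composition: (optional TSS-proximal peak exclusion)
#' -> stitch -> rank by net signal -> tangent cutoff. Regions whose net
#' signal exceeds the cutoff are flagged `is_super`; every region gets a
#' `center` (floor midpoint of the stitched interval), the reference point
#' for gene association. With fewer than 2 stitched regions no cutoff
#' exists and no region is called super.
#'
#' @param peaks H3K27ac peak intervals.
#' @param chip,input signal tracks (CPM).
#' @param params [se_params()].
#' @param genes optional gene table; needed only when
#'   `tss_exclusion_window > 0`.
#' @return region table sorted by rank with columns region_id, chrom,
#'   start, end, n_constituents, chip_signal, input_signal, net_signal,
#'   rank, is_super, center.
#' @export
call_super_enhancers <- function(peaks, chip, input, params = se_params(),
                                 genes = NULL) {
  if (params$tss_exclusion_window > 0) {
    if (is.null(genes)) stop("tss_exclusion_window > 0 requires gene models")
    w <- params$tss_exclusion_window
    tss_win <- genomic_intervals(genes$chrom, pmax(genes$tss - w, 0),
                                 genes$tss + w)
    if (nrow(peaks) > 0L) {
      hit <- unique(overlap_pairs(peaks, tss_win)$query)
      if (length(hit)) peaks <- peaks[-hit, , drop = FALSE]
    }
  }
  regions <- stitch_peaks(peaks, params)
  if (nrow(regions) == 0L) {
    regions$chip_signal <- numeric()
    regions$input_signal <- numeric()
    regions$net_signal <- numeric()
    regions$rank <- integer()
    regions$is_super <- logical()
    regions$center <- numeric()
    return(regions)
  }
  regions <- rank_regions(regions, chip, input)
  if (nrow(regions) >= 2L) {
    threshold <- call_cutoff(regions$net_signal)
    regions$is_super <- regions$net_signal > threshold
  } else {
    regions$is_super <- FALSE
  }
  regions$center <- floor((regions$start + regions$end) / 2)
  regions
}

#' Write a super-enhancer table as TSV
#'
#' Drops the list-column of constituent indices; column order matches the
#' documented output contract.
#'
#' @param regions output of [call_super_enhancers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_se_table <- function(regions, path) {
  cols <- c("region_id", "chrom", "start", "end", "n_constituents",
            "chip_signal", "input_signal", "net_signal", "rank",
            "is_super", "center")
  write_tsv(regions[, intersect(cols, names(regions)), drop = FALSE], path)
}

#' Read a super-enhancer table written by [write_se_table()]
#' @param path path to the TSV.
#' @return region data.frame.
#' @export
read_se_table <- function(path) {
  if (!file.exists(path)) stop("SE table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("is_super" %in% names(df)) df$is_super <- as.logical(df$is_super)
  df
}
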