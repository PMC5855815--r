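#' Read a BED3/4/5/6 file
#'
#' Thin validating reader: tab-separated, 0-based half-open coordinates,
#' optional `name`, `score` and `strand` columns. Malformed lines
#' (non-integer coordinates, `start >= end`, fewer than 3 columns) raise a
#' parse error naming the offending line number. Records are returned in
#' file order; strand is `"."` when column 6 is absent.
#'
#' @param path path to an existing BED file.
#' @return interval data.frame with columns chrom, start, end, strand and,
#'   when present in the file, name and score.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3L)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 which(n_col < 3L)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: start >= end (empty interval)",
                 bad[1]))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(n_col >= 4L)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(n_col >= 5L)) {
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  df$strand <- if (all(n_col >= 6L)) vapply(fields, `[[`, "", 6L) else "."
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop(sprintf("BED parse error at line %d: bad strand code",
                 which(!(df$strand %in% c("+", "-", ".")))[1]))
  }
  validate_intervals(df, "BED record")
  df
}

#' Write intervals as BED
#'
#' Emits chrom/start/end plus name, score and strand when present.
#' Round-trips with [read_bed()] on canonical records.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "BED record")
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  if ("name" %in% names(df)) {
    cols <- c(cols, list(df$name))
    if ("score" %in% names(df)) {
      cols <- c(cols, list(as.character(df$score)))
      if ("strand" %in% names(df) && any(df$strand != ".")) {
        cols <- c(cols, list(df$strand))
      }
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# fixed integer formatting (no scientific notation) for coordinate output
format_coord <- function(x) sprintf("%d", as.integer(x))

#' Read a bedGraph signal track
#'
#' Four tab-separated columns: chrom, start, end, value (counts-per-million
#' per base). Steps within a chromosome must not overlap; values must be
#' non-negative. Errors name the offending line.
#'
#' @param path path to a bedGraph file.
#' @return signal-track data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop(sprintf("bedGraph parse error at line %d: fewer than 4 columns",
                 which(lengths(fields) < 4L)[1]))
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, "bedGraph step")
  if (any(is.na(df$value) | df$value < 0)) {
    stop(sprintf("bedGraph parse error at line %d: negative or missing value",
                 which(is.na(df$value) | df$value < 0)[1]))
  }
  validate_signal_track(df)
  df
}

# steps within a chromosome must be non-overlapping
validate_signal_track <- function(track) {
  if (nrow(track) < 2L) return(invisible(track))
  o <- order(track$chrom, track$start)
  s <- track[o, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (any(same & s$start[-1] < s$end[-nrow(s)])) {
    stop("signal track has overlapping steps within a chromosome")
  }
  invisible(track)
}

#' Write a signal track as bedGraph
#' @param track signal-track data.frame (chrom, start, end, value).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(paste(track$chrom, format_coord(track$start),
                   format_coord(track$end),
                   formatC(track$value, format = "fg", digits = 6),
                   sep = "\t"), path)
  invisible(path)
}

#' Read ChIA-PET anchor pairs from BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score.
#' `score` is the pair multiplicity (count, >= 1; defaults to 1 when the
#' column is absent); `name` carries the experiment id (defaults to
#' `experiment_id`).
#'
#' @param path path to a BEDPE file.
#' @param experiment_id experiment label used when the name column is absent.
#' @return data.frame with columns chrom1, start1, end1, chrom2, start2,
#'   end2, experiment_id, count.
#' @export
read_bedpe <- function(path, experiment_id = "exp1") {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      experiment_id = character(), count = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) {
    stop(sprintf("BEDPE parse error at line %d: fewer than 6 columns",
                 which(lengths(fields) < 6L)[1]))
  }
  getn <- function(i) as.numeric(vapply(fields, `[[`, "", i))
  df <- data.frame(
    chrom1 = vapply(fields, `[[`, "", 1L), start1 = getn(2L), end1 = getn(3L),
    chrom2 = vapply(fields, `[[`, "", 4L), start2 = getn(5L), end2 = getn(6L),
    stringsAsFactors = FALSE
  )
  nc <- lengths(fields)
  df$experiment_id <- if (all(nc >= 7L)) vapply(fields, `[[`, "", 7L) else experiment_id
  df$count <- if (all(nc >= 8L)) getn(8L) else 1
  if (any(is.na(df$count) | df$count < 1)) {
    stop(sprintf("BEDPE parse error at line %d: count must be >= 1",
                 which(is.na(df$count) | df$count < 1)[1]))
  }
  a1 <- df[, c("chrom1", "start1", "end1")]
  names(a1) <- c("chrom", "start", "end")
  validate_intervals(a1, "BEDPE anchor1")
  a2 <- df[, c("chrom2", "start2", "end2")]
  names(a2) <- c("chrom", "start", "end")
  validate_intervals(a2, "BEDPE anchor2")
  df
}

#' Write anchor pairs as BEDPE
#' @param pairs data.frame as returned by [read_bedpe()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pairs, path) {
  writeLines(paste(pairs$chrom1, format_coord(pairs$start1),
                   format_coord(pairs$end1), pairs$chrom2,
                   format_coord(pairs$start2), format_coord(pairs$end2),
                   pairs$experiment_id, format_coord(pairs$count),
                   sep = "\t"), path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports gene-level records (1-based inclusive GTF coordinates converted
#' to the internal 0-based half-open convention) and resolves the TSS from
#' the strand: interval start for `+` genes, `end - 1` for `-` genes.
#' Expects `gene_id` and `gene_biotype` attributes; `gene_name` defaults to
#' the id and `longest_isoform_length` to the gene-body length when absent.
#'
#' @param path path to a GTF file.
#' @return gene table: gene_id, gene_name, chrom, start, end, strand,
#'   biotype, longest_isoform_length, tss.
#' @export
read_genes_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  df <- from_granges(gr)
  m <- S4Vectors::mcols(gr)
  genes <- data.frame(
    gene_id = as.character(m$gene_id),
    gene_name = if ("gene_name" %in% names(m)) as.character(m$gene_name) else as.character(m$gene_id),
    chrom = df$chrom, start = df$start, end = df$end, strand = df$strand,
    biotype = if ("gene_biotype" %in% names(m)) as.character(m$gene_biotype) else "protein_coding",
    longest_isoform_length = if ("longest_isoform_length" %in% names(m)) {
      as.numeric(as.character(m$longest_isoform_length))
    } else df$end - df$start,
    stringsAsFactors = FALSE
  )
  genes$longest_isoform_length[is.na(genes$longest_isoform_length)] <-
    (genes$end - genes$start)[is.na(genes$longest_isoform_length)]
  genes$tss <- tss_position(genes)
  validate_intervals(genes, "gene")
  genes
}

#' Strand-resolved TSS position
#'
#' `start` for `+` (and unstranded) genes, `end - 1` for `-` genes — the
#' first transcribed base in 0-based coordinates.
#'
#' @param genes gene table with start, end, strand.
#' @return numeric vector of TSS positions.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1, genes$start)
}

#' Write gene models as GTF
#'
#' One `gene` feature per record with gene_id, gene_name, gene_biotype and
#' longest_isoform_length attributes; converts internal 0-based half-open
#' back to GTF 1-based inclusive.
#'
#' @param genes gene table as from [read_genes_gtf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  attr_str <- sprintf(
    'gene_id "%s"; gene_name "%s"; gene_biotype "%s"; longest_isoform_length "%d";',
    genes$gene_id, genes$gene_name, genes$biotype,
    as.integer(genes$longest_isoform_length)
  )
  writeLines(paste(genes$chrom, "aposenet", "gene",
                   format_coord(genes$start + 1), format_coord(genes$end),
                   ".", genes$strand, ".", attr_str, sep = "\t"), path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with header; requires columns `gene_id`, `log2fc`,
#' `adj_p`. Rows with missing `adj_p` are kept (they are skipped, with a
#' warning count, at classification time).
#'
#' @param path path to the TSV.
#' @return data.frame with gene_id, log2fc, adj_p.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "adj_p")
  if (!all(need %in% names(df))) {
    stop("DE table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.na(df$adj_p) & (df$adj_p < 0 | df$adj_p > 1))) {
    stop("DE table ", path, ": adj_p outside [0, 1]")
  }
  df[, need]
}

#' Write a data.frame as a deterministic TSV
#'
#' Tab-separated, header, no quoting or row names, fixed 15-significant-digit
#' numeric formatting so identical inputs yield byte-identical files.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], format = "g", digits = 15))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
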