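#' Read a peak file (MACS tab-separated dialect or BED)
#'
#' The MACS dialect is the tab-separated "xls" output of classic MACS
#' (<= v1.4): comment lines start with `#`, an optional header line precedes
#' the data, and the default column map is chrom, start, end, length,
#' summit offset, tag count, -10*log10(p) score. The summit offset is
#' converted to an absolute position (`start + offset`). BED files use the
#' interval midpoint as the summit unless a summit-offset column is named.
#'
#' @param path file path
#' @param dialect `"auto"` (sniffed from the first data line), `"macs"` or
#'   `"bed"`
#' @param macs_columns column map for the MACS dialect (1-based indices:
#'   `chrom`, `start`, `end`, `summit`, `score`); the default matches MACS
#'   <= 1.4. Configurable because column layout drifts across MACS releases.
#' @param one_based whether MACS start coordinates are 1-based inclusive
#'   (converted to the internal 0-based half-open frame on read)
#' @param bed_summit_col optional 1-based column index holding a summit offset
#'   in BED input; default uses the interval midpoint
#' @return data.table of peaks: `chrom`, `start`, `end`, `summit` (absolute),
#'   `score`, satisfying `start <= summit < end` and `score >= 0`.
#' @export
read_peaks <- function(path, dialect = c("auto", "macs", "bed"),
                       macs_columns = list(chrom = 1, start = 2, end = 3,
                                           summit = 5, score = 7),
                       one_based = FALSE, bed_summit_col = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                "peakodds_io_error")
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  line_no <- which(keep)
  if (length(body) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), score = numeric()))
  first <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  is_header <- suppressWarnings(is.na(as.numeric(first[2])))
  if (is_header) { body <- body[-1]; line_no <- line_no[-1] }
  if (dialect == "auto")
    dialect <- if (length(first) >= 7) "macs" else "bed"

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "macs") max(unlist(macs_columns)) else 3L
  if (any(nf < need))
    abort(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                  line_no[which(nf < need)[1]], path, need, min(nf)),
          "peakodds_io_error")

  getnum <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", i)))
    if (anyNA(v))
      abort(sprintf("malformed line %d in %s: non-numeric field %d",
                    line_no[which(is.na(v))[1]], path, i),
            "peakodds_io_error")
    v
  }

  if (dialect == "macs") {
    start <- as.integer(getnum(macs_columns$start)) - if (one_based) 1L else 0L
    end <- as.integer(getnum(macs_columns$end))
    offs <- as.integer(getnum(macs_columns$summit))
    pk <- data.table(chrom = vapply(fields, `[`, "", macs_columns$chrom),
                     start = start, end = end, summit = start + offs,
                     score = getnum(macs_columns$score))
  } else {
    start <- as.integer(getnum(2))
    end <- as.integer(getnum(3))
    summit <- if (!is.null(bed_summit_col)) start + as.integer(getnum(bed_summit_col))
              else as.integer(floor((start + end) / 2))
    score <- if (is.null(bed_summit_col) && all(nf >= 5))
      suppressWarnings(as.numeric(vapply(fields, `[`, "", 5))) else NA_real_
    score[is.na(score)] <- 0
    if (length(score) == 1L && length(start) > 1L) score <- rep(score, length(start))
    pk <- data.table(chrom = vapply(fields, `[`, "", 1),
                     start = start, end = end, summit = summit, score = score)
  }
  bad <- pk$summit < pk$start | pk$summit >= pk$end
  if (any(bad))
    abort(sprintf("line %d in %s: summit outside [start, end)",
                  line_no[which(bad)[1]], path), "peakodds_io_error")
  if (any(pk$score < 0))
    abort("negative peak score", "peakodds_io_error")
  pk[]
}

#' Write peaks in the MACS tab-separated dialect
#'
#' @param peaks data.table of peaks (as from [read_peaks()])
#' @param path output path
#' @param comments optional character vector written as leading `#` lines
#' @export
write_peaks_macs <- function(peaks, path, comments = NULL) {
  peaks <- as.data.table(peaks)
  hdr <- c(paste0("# ", comments %||% "MACS-dialect peak calls"),
           paste("chr", "start", "end", "length", "summit", "tags",
                 "-10*LOG10(pvalue)", sep = "\t"))
  rows <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%.4f",
                  peaks$chrom, peaks$start, peaks$end,
                  peaks$end - peaks$start, peaks$summit - peaks$start,
                  0L, peaks$score)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a GTF/GFF gene annotation
#'
#' Builds a [genome_annotation()] from GENCODE-style GTF: one TSS per
#' transcript (5' end, strand-aware), exon structure, 1-based inclusive
#' coordinates converted to 0-based half-open. Chromosome lengths are taken
#' from `chrom_lengths`, then from `##sequence-region` header comments, then
#' inferred from the rightmost feature.
#'
#' @param path GTF/GFF file
#' @param chrom_lengths optional named vector of chromosome lengths
#' @return a [genome_annotation()]
#' @export
read_annotation <- function(path, chrom_lengths = NULL) {
  raw <- readLines(path)
  seq_region <- NULL
  hdr <- grep("^##sequence-region", raw, value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr), "\\s+")
    seq_region <- setNames(vapply(parts, function(p) as.numeric(p[4]), 0),
                           vapply(parts, `[`, "", 2))
  }
  empty_ann <- function(lens)
    genome_annotation(lens %||% setNames(numeric(), character()),
                      data.frame(gene_id = character(), chrom = character(),
                                 strand = character()),
                      data.frame(gene_id = character(),
                                 transcript_id = character(),
                                 start = integer(), end = integer()))
  if (!any(nzchar(raw) & !grepl("^#", raw)))
    return(empty_ann(chrom_lengths %||% seq_region))
  gr <- rtracklayer::import(path)
  md <- as.data.table(as.data.frame(gr))
  if (nrow(md) == 0L) return(empty_ann(chrom_lengths %||% seq_region))
  md[, chrom := as.character(seqnames)]
  md[, strand := as.character(strand)]
  md[, start0 := start - 1L]

  unk <- md$type %in% c("gene", "transcript") & !md$strand %in% c("+", "-")
  if (any(unk)) {
    warning(sum(unk), " feature(s) with unknown strand skipped")
    bad_genes <- unique(md$gene_id[unk])
    md <- md[!md$gene_id %in% bad_genes]
  }

  tx <- md[md$type == "transcript",
           .(gene_id, transcript_id, chrom, strand, start = start0, end = end)]
  ex <- md[md$type == "exon", .(transcript_id, start = start0, end = end)]
  if (nrow(tx) == 0L && nrow(ex))
    abort("GTF has exons but no transcript features", "peakodds_io_error")

  gchrom <- unique(tx[, .(gene_id, chrom)])
  if (anyDuplicated(gchrom$gene_id))
    abort("gene spans multiple chromosomes", "peakodds_io_error")
  genes <- unique(tx[, .(gene_id, chrom, strand)])

  no_exon <- setdiff(tx$transcript_id, ex$transcript_id)
  if (length(no_exon)) {
    warning(length(no_exon),
            " transcript(s) without exons; using transcript bounds")
    ex <- rbind(ex, tx[tx$transcript_id %in% no_exon,
                       .(transcript_id, start, end)])
  }

  lens <- chrom_lengths %||% seq_region
  if (is.null(lens)) {
    mx <- md[, .(len = max(end)), by = chrom]
    lens <- setNames(mx$len, mx$chrom)
  }
  genome_annotation(lens, as.data.frame(genes),
                    as.data.frame(tx[, .(gene_id, transcript_id, start, end)]),
                    as.data.frame(ex))
}

#' Write a genome annotation as GTF
#'
#' Emits gene/transcript/exon features with `gene_id`/`transcript_id`
#' attributes, converting back to 1-based inclusive coordinates, plus
#' `##sequence-region` headers carrying the chromosome lengths so that
#' write/read round-trips losslessly.
#'
#' @param annotation a [genome_annotation()]
#' @param path output path
#' @export
write_gtf <- function(annotation, path) {
  hdr <- sprintf("##sequence-region %s 1 %d",
                 names(annotation$chromosomes),
                 as.integer(annotation$chromosomes))
  tx <- annotation$transcripts
  ex <- merge(annotation$exons,
              tx[, .(transcript_id, gene_id, chrom, strand)],
              by = "transcript_id", sort = FALSE)
  fmt <- function(chrom, type, s0, e, strand, attr)
    sprintf("%s\tpeakodds\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s0 + 1L, e, strand, attr)
  lines <- hdr
  if (nrow(tx)) {
    gl <- tx[, .(start = min(start), end = max(end)),
             by = .(gene_id, chrom, strand)]
    lines <- c(
      lines,
      fmt(gl$chrom, "gene", gl$start, gl$end, gl$strand,
          sprintf('gene_id "%s";', gl$gene_id)),
      fmt(tx$chrom, "transcript", tx$start, tx$end, tx$strand,
          sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id,
                  tx$transcript_id)),
      fmt(ex$chrom, "exon", ex$start, ex$end, ex$strand,
          sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id,
                  ex$transcript_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read position weight matrices
#'
#' Supports the MEME minimal text format (possibly several `MOTIF` blocks per
#' file) and a plain probability-matrix TSV (columns A, C, G, T, one row per
#' motif position; motif name from a leading `# name` comment or the file
#' name). Each column must sum to 1 within `1e-6`; a pseudocount is then
#' added and the columns renormalised, so downstream log-ratio scores are
#' finite.
#'
#' @param path file path
#' @param format `"auto"`, `"meme"` or `"tsv"`
#' @param pseudocount added to every probability before renormalisation
#' @return list of `pwm_record` objects (see [pwm_record()])
#' @export
read_pwm <- function(path, format = c("auto", "meme", "tsv"),
                     pseudocount = 1e-3) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (any(grepl("^MOTIF", lines))) "meme" else "tsv"
  if (format == "meme") {
    bkg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    bline <- grep("^Background letter frequencies", lines)
    if (length(bline) && bline[1] < length(lines)) {
      toks <- strsplit(trimws(lines[bline[1] + 1L]), "\\s+")[[1]]
      if (length(toks) >= 8)
        bkg <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
    }
    starts <- grep("^MOTIF", lines)
    out <- lapply(seq_along(starts), function(i) {
      name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
      stop_at <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
      block <- lines[starts[i]:stop_at]
      hdr <- grep("letter-probability matrix", block)[1]
      if (is.na(hdr)) abort("MEME motif block without probability matrix",
                            "peakodds_io_error")
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr]))
      rows <- block[(hdr + 1L):(hdr + w)]
      mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                      function(x) as.numeric(x[1:4]), numeric(4)))
      pwm_record(name, t(mat), bkg, pseudocount = pseudocount)
    })
    out
  } else {
    name_line <- grep("^#", lines, value = TRUE)
    name <- if (length(name_line)) trimws(sub("^#+", "", name_line[1]))
            else tools::file_path_sans_ext(basename(path))
    tab <- fread(text = lines[!grepl("^#", lines)], header = TRUE)
    if (!all(c("A", "C", "G", "T") %in% names(tab)))
      abort("matrix TSV needs A, C, G, T columns", "peakodds_io_error")
    mat <- t(as.matrix(tab[, c("A", "C", "G", "T"), with = FALSE]))
    list(pwm_record(name, mat, pseudocount = pseudocount))
  }
}

#' Read a BED feature track as merged disjoint intervals
#'
#' Overlapping or adjacent intervals are merged on read (nucleotide-proportion
#' statistics require disjointness).
#'
#' @param path BED file
#' @return sorted, disjoint `GRanges`
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' @rdname read_features
#' @export
read_mask <- read_features

#' Read a FASTA genome
#'
#' @param path FASTA file
#' @return `DNAStringSet` with names truncated at the first whitespace
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write / read a regulation-odds table as TSV
#'
#' The layout mirrors the learned model: one row per category (`bin`,
#' `context`, `mean_odds`, `sd_odds`), with `N/A` marking unestimable
#' categories. Write-then-read round-trips within 1e-9.
#'
#' @param odds an [odds_table()]
#' @param path file path
#' @param comments optional `#` header lines
#' @export
write_odds_table <- function(odds, path, comments = NULL) {
  stopifnot(inherits(odds, "odds_table"))
  fmt <- function(x) ifelse(is.na(x), "N/A", sprintf("%.10g", x))
  lines <- c(if (!is.null(comments)) paste0("# ", comments),
             paste("bin", "context", "mean_odds", "sd_odds", sep = "\t"),
             paste(odds$bin, odds$context, fmt(odds$mean_odds),
                   fmt(odds$sd_odds), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_odds_table
#' @export
read_odds_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tab <- fread(text = lines, header = TRUE, sep = "\t", na.strings = "N/A",
               colClasses = list(character = c("bin", "context")))
  odds_table(tab)
}

#' Write ranked gene scores as TSV
#'
#' @param scores output of [score_genes()] or [traditional_assign()]
#' @param path file path
#' @param comments optional `#` header lines (used by the CLI to stamp seed,
#'   version and parameters into every output)
#' @export
write_gene_scores <- function(scores, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
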