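#' Construct a genome annotation
#'
#' The coordinate frame for all classification. Internal coordinates are
#' 0-based half-open throughout the package; GTF input (1-based inclusive) is
#' converted on read.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp)
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`)
#' @param transcripts data.frame with columns `gene_id`, `transcript_id`,
#'   `start`, `end` (0-based half-open genomic extent)
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open), non-overlapping within a transcript
#' @return object of class `genome_annotation`: the three tables (as
#'   data.tables, transcripts gaining a strand-aware `tss` column) plus the
#'   chromosome lengths.
#' @export
genome_annotation <- function(chromosomes, genes, transcripts, exons = NULL) {
  genes <- as.data.table(genes)
  transcripts <- as.data.table(transcripts)
  exons <- if (is.null(exons) || nrow(exons) == 0L) {
    data.table(transcript_id = character(), start = integer(), end = integer())
  } else as.data.table(exons)

  if (anyDuplicated(genes$gene_id))
    abort("duplicate gene IDs in annotation", "peakodds_invalid_annotation")
  if (nrow(transcripts) && !all(transcripts$gene_id %in% genes$gene_id))
    abort("transcript references unknown gene", "peakodds_invalid_annotation")
  if (nrow(genes) && !all(genes$strand %in% c("+", "-")))
    abort("gene strand must be '+' or '-'", "peakodds_invalid_annotation")
  if (nrow(genes) && !all(genes$chrom %in% names(chromosomes)))
    abort("gene on chromosome absent from chromosome lengths",
          "peakodds_invalid_annotation")

  tx <- merge(transcripts, genes[, .(gene_id, chrom, strand)], by = "gene_id",
              sort = FALSE)
  if (nrow(tx)) {
    len <- chromosomes[tx$chrom]
    if (any(tx$start < 0 | tx$end > len | tx$start >= tx$end))
      abort("transcript coordinates outside chromosome bounds",
            "peakodds_invalid_annotation")
    tx[, tss := ifelse(strand == "+", start, end - 1L)]
  } else {
    tx[, `:=`(chrom = character(), strand = character(), tss = integer())]
  }

  if (nrow(exons)) {
    ex <- merge(exons, tx[, .(transcript_id, t_start = start, t_end = end)],
                by = "transcript_id", sort = FALSE)
    if (any(ex$start < ex$t_start | ex$end > ex$t_end | ex$start >= ex$end))
      abort("exon outside its transcript", "peakodds_invalid_annotation")
    setorder(ex, transcript_id, start)
    ov <- ex[, any(start[-1] < end[-.N]), by = transcript_id]
    if (nrow(ov) && any(ov$V1))
      abort("overlapping exons within a transcript",
            "peakodds_invalid_annotation")
  }

  structure(list(chromosomes = chromosomes, genes = genes,
                 transcripts = tx, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s) (%.2f Mb), %d gene(s), %d transcript(s)\n",
              length(x$chromosomes), sum(x$chromosomes) / 1e6,
              nrow(x$genes), nrow(x$transcripts)))
  invisible(x)
}

#' Signed distance from a peak summit to a TSS
#'
#' Positive when the summit lies upstream of the TSS in the gene's
#' transcription orientation, negative when downstream; the magnitude is the
#' absolute genomic distance. Vectorised over all arguments.
#'
#' @param summit summit position(s), 0-based
#' @param tss TSS position(s), 0-based
#' @param strand gene strand, `"+"` or `"-"`
#' @param summit_chrom,gene_chrom optional chromosome names; if both given
#'   they must agree, otherwise an error is raised (coordinates on different
#'   chromosomes are incomparable)
#' @return signed distance(s) in bp
#' @export
signed_tss_distance <- function(summit, tss, strand,
                                summit_chrom = NULL, gene_chrom = NULL) {
  if (!is.null(summit_chrom) && !is.null(gene_chrom) &&
      any(summit_chrom != gene_chrom))
    abort("summit and TSS lie on different chromosomes; distance undefined",
          "peakodds_chromosome_mismatch")
  ifelse(strand == "+", tss - summit, summit - tss)
}

# All candidate (summit, gene, TSS) classifications for a set of summits.
# Returns one row per summit x transcript pair on the same chromosome, with the
# signed distance, distance bin and structural context already resolved.
candidate_table <- function(summits, annotation) {
  stopifnot(is.data.frame(summits))
  s <- as.data.table(summits)[, .(sid = seq_len(.N), chrom, pos = summit)]
  tx <- annotation$transcripts
  if (nrow(tx) == 0L || nrow(s) == 0L) {
    out <- data.table(sid = integer(), chrom = character(), pos = integer(),
                      gene_id = character(), transcript_id = character(),
                      gene_strand = character(), tss = integer(), d = integer(),
                      bin = character(), context = character())
    out[, key := character(0)]
    return(out)
  }
  cand <- tx[, .(chrom, gene_id, transcript_id, gene_strand = strand, tss,
                 t_start = start, t_end = end)][s, on = "chrom",
                                                allow.cartesian = TRUE, nomatch = 0L]
  if (nrow(cand) == 0L) return(cand[, `:=`(d = integer(), bin = character(),
                                           context = character(), key = character())])
  cand[, d := ifelse(gene_strand == "+", tss - pos, pos - tss)]
  cand[, bin := distance_bin(d)]
  cand[, inside := d < 0 & pos >= t_start & pos < t_end]
  cand[, exonic := FALSE]
  if (any(cand$inside) && nrow(annotation$exons)) {
    ex <- annotation$exons
    sub <- cbind(row_id = which(cand$inside),
                 cand[inside == TRUE, .(transcript_id, pos, pos2 = pos)])
    hits <- ex[sub, on = .(transcript_id, start <= pos, end > pos2),
               nomatch = 0L, .(row_id)]
    if (nrow(hits)) cand[unique(hits$row_id), exonic := TRUE]
  }
  cand[, context := ifelse(d >= 0, "upstream",
                    ifelse(!inside, "downstream_outside_transcript",
                    ifelse(exonic, "exon", "intron")))]
  cand[, key := category_key(bin, context)]
  cand[, c("inside", "exonic", "t_start", "t_end") := NULL]
  cand
}

# Pick, per summit, the best candidate under an odds table (NULL = uniform).
# Ties: smaller |d|, then lexicographic gene id, then transcript id.
best_candidates <- function(cand, odds = NULL) {
  if (nrow(cand) == 0L) return(cand)
  cand <- copy(cand)
  if (is.null(odds)) {
    cand[, odds := 1]
  } else {
    ov <- odds_vector(odds)
    cand[, odds := ov[key]]
    cand[is.na(odds), odds := 0]
  }
  cand[, absd := abs(d)]
  setorder(cand, sid, -odds, absd, gene_id, transcript_id)
  out <- cand[!duplicated(sid)]
  out[, absd := NULL]
  out
}

#' Classify a peak summit against one gene
#'
#' Classification is total: every summit on the gene's chromosome receives a
#' category. When the gene has multiple TSSs (one per transcript), the TSS
#' yielding the highest-odds category is chosen; with no odds table, or on
#' ties, the TSS at the smallest absolute distance wins.
#'
#' @param annotation a [genome_annotation()]
#' @param chrom chromosome of the summit
#' @param summit summit position (0-based)
#' @param gene_id gene to classify against
#' @param odds optional [odds_table()] guiding TSS choice
#' @return list with `bin`, `context`, `key`, `tss`, `transcript_id`,
#'   `distance`
#' @export
classify_location <- function(annotation, chrom, summit, gene_id, odds = NULL) {
  .gid <- gene_id
  g <- as.data.frame(annotation$genes)[annotation$genes$gene_id == .gid, ]
  if (nrow(g) == 0L) abort("unknown gene", "peakodds_unknown_gene")
  if (g$chrom != chrom)
    abort("summit and gene lie on different chromosomes",
          "peakodds_chromosome_mismatch")
  sub_ann <- annotation
  sub_ann$transcripts <- annotation$transcripts[annotation$transcripts$gene_id == g$gene_id]
  cand <- candidate_table(data.frame(chrom = chrom, summit = summit), sub_ann)
  best <- best_candidates(cand, odds)
  list(bin = best$bin, context = best$context, key = best$key,
       tss = best$tss, transcript_id = best$transcript_id, distance = best$d)
}

#' Classify many peak summits at once
#'
#' For each summit, considers every (gene, TSS) pair on its chromosome (no
#' distance cutoff) and keeps the candidate whose category has maximal mean
#' odds (uniform odds when `odds` is NULL, which reduces to nearest-TSS
#' choice). Ties break by smaller |distance|, then gene id.
#'
#' @param peaks data.frame of peaks (needs `chrom`, `summit`)
#' @param annotation a [genome_annotation()]
#' @param odds optional [odds_table()]
#' @return data.table, one row per peak (`sid` = input row), with the chosen
#'   gene, category and signed distance; peaks on chromosomes without genes
#'   are absent.
#' @export
classify_peaks <- function(peaks, annotation, odds = NULL) {
  best_candidates(candidate_table(peaks, annotation), odds)
}

#' Build a TSS index for nearest-TSS and containment queries
#'
#' Per-chromosome sorted TSS tables supporting nearest-k queries and
#' transcript-containment queries; results are identical to a naive linear
#' scan (property-tested).
#'
#' @param annotation a [genome_annotation()]
#' @return object of class `tss_index`
#' @export
build_tss_index <- function(annotation) {
  tx <- copy(annotation$transcripts)
  setorder(tx, chrom, tss, gene_id, transcript_id)
  structure(list(tx = tx, chromosomes = annotation$chromosomes),
            class = "tss_index")
}

#' Nearest TSSs to a position
#'
#' @param index a [build_tss_index()]
#' @param chrom chromosome
#' @param pos query position (0-based)
#' @param k number of nearest TSSs to return
#' @return data.table of the k nearest (gene, transcript, tss) rows, ordered by
#'   |distance| then gene id; fewer rows if the chromosome has fewer TSSs.
#' @export
nearest_tss <- function(index, chrom, pos, k = 1L) {
  .ch <- chrom
  sub <- index$tx[index$tx$chrom == .ch]
  if (nrow(sub) == 0L) return(sub)
  sub <- copy(sub)
  sub[, absd := abs(tss - pos)]
  setorder(sub, absd, gene_id, transcript_id)
  head(sub, k)
}

#' Transcripts containing a position
#'
#' @inheritParams nearest_tss
#' @return data.table of transcripts whose `[start, end)` interval contains
#'   `pos`.
#' @export
transcripts_containing <- function(index, chrom, pos) {
  .ch <- chrom; .pos <- pos
  index$tx[index$tx$chrom == .ch & index$tx$start <= .pos & index$tx$end > .pos]
}
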