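# Small hand-built fixtures shared across test files.

# two genes on one 100 kb chromosome: A (+, exons [10000,10500) and
# [15000,16000)) and B (-, single exon [50000,60000))
toy_annotation <- function() {
  genome_annotation(
    c(chr1 = 100000),
    data.frame(gene_id = c("A", "B"), chrom = "chr1", strand = c("+", "-")),
    data.frame(gene_id = c("A", "B"), transcript_id = c("A.T1", "B.T1"),
               start = c(10000, 50000), end = c(20000, 60000)),
    data.frame(transcript_id = c("A.T1", "A.T1", "B.T1"),
               start = c(10000, 15000, 50000), end = c(10500, 16000, 60000)))
}

# random annotation for property tests: n genes, 1-2 transcripts each,
# random exon structure; all coordinates within [0, len)
random_annotation <- function(n_genes, len = 1e6, seed = 1) {
  withr::with_seed(seed, {
    genes <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                        chrom = "chr1",
                        strand = sample(c("+", "-"), n_genes, replace = TRUE))
    tx <- list(); ex <- list()
    for (i in seq_len(n_genes)) {
      glen <- sample(2000:30000, 1)
      gstart <- sample.int(len - glen, 1) - 1L
      n_tx <- sample(1:2, 1)
      for (t in seq_len(n_tx)) {
        shift <- if (t == 1) 0L else sample.int(glen %/% 2L, 1)
        ts <- if (genes$strand[i] == "+") gstart + shift else gstart
        te <- if (genes$strand[i] == "+") gstart + glen else gstart + glen - shift
        tid <- sprintf("%s.T%d", genes$gene_id[i], t)
        tx[[length(tx) + 1L]] <- data.frame(gene_id = genes$gene_id[i],
                                            transcript_id = tid,
                                            start = ts, end = te)
        k <- sample(1:3, 1)
        if (k == 1L || te - ts < 4L * k + 2L) {
          ex[[length(ex) + 1L]] <- data.frame(transcript_id = tid,
                                              start = ts, end = te)
        } else {
          cuts <- sort(sample((ts + 1L):(te - 1L), 2L * (k - 1L)))
          ex[[length(ex) + 1L]] <- data.frame(
            transcript_id = tid,
            start = c(ts, cuts[seq(2, length(cuts), 2)]),
            end = c(cuts[seq(1, length(cuts), 2)], te))
        }
      }
    }
    genome_annotation(c(chr1 = len), genes, do.call(rbind, tx),
                      do.call(rbind, ex))
  })
}

# brute-force classification of a single summit against a single gene:
# per-transcript scan, best by smallest |distance| (uniform odds)
oracle_classify <- function(annotation, summit, gene_id) {
  tx <- as.data.frame(annotation$transcripts)
  tx <- tx[tx$gene_id == gene_id, ]
  ex <- as.data.frame(annotation$exons)
  best <- NULL
  for (i in seq_len(nrow(tx))) {
    d <- if (tx$strand[i] == "+") tx$tss[i] - summit else summit - tx$tss[i]
    if (d >= 0) {
      context <- "upstream"
    } else if (summit >= tx$start[i] && summit < tx$end[i]) {
      exi <- ex[ex$transcript_id == tx$transcript_id[i], ]
      inexon <- any(exi$start <= summit & summit < exi$end)
      context <- if (inexon) "exon" else "intron"
    } else {
      context <- "downstream_outside_transcript"
    }
    cand <- list(bin = distance_bin(d), context = context, d = d,
                 transcript_id = tx$transcript_id[i])
    if (is.null(best) || abs(d) < abs(best$d) ||
        (abs(d) == abs(best$d) && cand$transcript_id < best$transcript_id))
      best <- cand
  }
  best
}

# reference odds table assembled from the published per-category regulation
# odds for NF-kB/RelA peaks (distance/context categories)
reference_odds <- function() {
  read_odds_table(system.file("extdata", "rela_reference_odds.tsv",
                              package = "peakodds"))
}

# small, fast fixture spec used across test files
small_spec <- function(seed = 9, ...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 1, chrom_length = 1e6, n_genes = 60,
                   n_peaks = 100, seed = seed)
  do.call(fixture_spec, utils::modifyList(defaults, args))
}
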