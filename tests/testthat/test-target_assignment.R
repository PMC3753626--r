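# Odds-guided assignment against a reference odds table with the published
# per-category values; the two scenario tests pit a promoter-proximal
# candidate against intronic/exonic candidates the way the odds rank them.

test_that("assignment picks the maximal-odds candidate gene", {
  odds <- reference_odds()
  # summit 1 kb upstream of A's TSS (odds 6.73) vs 1.5 kb into B's intron
  # (odds 4.37) -> A wins
  ann <- genome_annotation(
    c(chr1 = 100000),
    data.frame(gene_id = c("A", "B"), chrom = "chr1", strand = "+"),
    data.frame(gene_id = c("A", "B"), transcript_id = c("A.T1", "B.T1"),
               start = c(21000, 18000), end = c(31000, 30000)),
    data.frame(transcript_id = c("A.T1", "B.T1", "B.T1"),
               start = c(21000, 18000, 25000), end = c(31000, 18200, 30000)))
  res <- assign_peak(data.frame(chrom = "chr1", summit = 20000), ann, odds)
  expect_equal(res$gene_id, "A")
  expect_equal(res$key, "0-2k|upstream")
  expect_equal(res$probability, 6.73 / 7.73)

  # summit 10 kb upstream of A (1.73) vs 1 kb inside B's exon (2.19) -> B
  ann2 <- genome_annotation(
    c(chr1 = 100000),
    data.frame(gene_id = c("A", "B"), chrom = "chr1", strand = "+"),
    data.frame(gene_id = c("A", "B"), transcript_id = c("A.T1", "B.T1"),
               start = c(30000, 19000), end = c(40000, 29000)),
    data.frame(transcript_id = c("A.T1", "B.T1"),
               start = c(30000, 19000), end = c(40000, 29000)))
  res2 <- assign_peak(data.frame(chrom = "chr1", summit = 20000), ann2, odds)
  expect_equal(res2$gene_id, "B")
  expect_equal(res2$key, "-2k-0|exon")
})

test_that("single-gene genomes assign every peak to that gene", {
  ann <- toy_annotation()
  ann$genes <- ann$genes[gene_id == "A"]
  ann$transcripts <- ann$transcripts[gene_id == "A"]
  odds <- reference_odds()
  for (s in c(0, 30000, 99999))
    expect_equal(assign_peak(data.frame(chrom = "chr1", summit = s),
                             ann, odds)$gene_id, "A")
})

test_that("peaks with no gene on their chromosome are marked unassigned", {
  ann <- toy_annotation()
  odds <- reference_odds()
  res <- assign_peaks(data.frame(chrom = c("chr1", "chrX"),
                                 summit = c(9000, 100)), ann, odds)
  expect_equal(res$gene_id, c("A", NA))
  expect_error(assign_peaks(data.frame(chrom = "chr1", summit = 1),
                            ann, odds_table(data.frame(bin = "0-2k",
                                                       context = "upstream",
                                                       mean_odds = NA_real_))),
               class = "peakodds_invalid_odds")
})

test_that("assignment is deterministic and order invariant", {
  ann <- random_annotation(30, seed = 5)
  odds <- reference_odds()
  peaks <- withr::with_seed(6, data.frame(chrom = "chr1",
                                          summit = sample.int(1e6, 200) - 1L))
  a <- assign_peaks(peaks, ann, odds)
  perm <- withr::with_seed(7, sample.int(nrow(peaks)))
  b <- assign_peaks(peaks[perm, , drop = FALSE], ann, odds)
  expect_equal(a$gene_id[perm], b$gene_id)
  expect_equal(a$key[perm], b$key)
})

test_that("odds learning accepts a mappability mask and validates inputs", {
  ann <- random_annotation(25, seed = 91)
  peaks <- withr::with_seed(92,
    data.frame(chrom = "chr1", summit = sample.int(1e6, 300) - 1L))
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e5))
  odds <- learn_odds(peaks, ann, n_null_replicates = 3, seed = 93,
                     mask = mask)
  expect_s3_class(odds, "odds_table")
  expect_gte(sum(!is.na(odds$mean_odds)), 1L)
  expect_error(learn_odds(peaks, ann, n_null_replicates = 0),
               class = "peakodds_invalid_input")
  expect_error(learn_odds(data.frame(chrom = "chrZ", summit = 1), ann),
               class = "peakodds_unknown_chromosome")
})

test_that("gene scores combine per-peak probabilities by the chosen rule", {
  mk <- function(p, odds = p / (1 - p)) {
    data.table::data.table(peak_id = seq_along(p), gene_id = "G",
                           probability = p, odds = odds)
  }
  expect_equal(score_genes(mk(0.6))$score, 0.6)
  expect_equal(score_genes(mk(c(0.5, 0.5)), mode = "noisy_or")$score, 0.75)
  expect_equal(score_genes(mk(c(0.5, 0.5)), mode = "product")$score, 0.25)
  expect_equal(score_genes(mk(c(0.5, 0.5)), mode = "log_sum")$score, 0)
  expect_equal(nrow(score_genes(mk(numeric(0)))), 0L)
})

test_that("noisy-OR is monotone in added peaks while product is not", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      p <- runif(sample(2:6, 1), 0.05, 0.95)
      base <- data.table::data.table(peak_id = seq_along(p), gene_id = "G",
                                     probability = p, odds = p / (1 - p))
      extra <- rbind(base,
                     data.table::data.table(peak_id = length(p) + 1L,
                                            gene_id = "G", probability = 0.3,
                                            odds = 0.3 / 0.7))
      expect_gt(score_genes(extra)$score, score_genes(base)$score)
      expect_lt(score_genes(extra, mode = "product")$score,
                score_genes(base, mode = "product")$score)
    }
  })
})

test_that("traditional assignment sums scores within the promoter window", {
  ann <- toy_annotation()
  peaks <- data.frame(chrom = "chr1",
                      summit = c(9500, 11000, 62600),
                      score = c(120, 80, 40))
  res <- traditional_assign(peaks, ann, window = 2000)
  # two peaks within 2 kb of A's TSS sum to 200; the third is 2.6 kb from
  # B's TSS and is dropped
  expect_equal(as.data.frame(res),
               data.frame(gene_id = "A", score = 200, n_peaks = 2L))

  # exactly equidistant TSSs break ties lexicographically
  ann2 <- genome_annotation(
    c(chr1 = 100000),
    data.frame(gene_id = c("X", "Y"), chrom = "chr1", strand = "+"),
    data.frame(gene_id = c("X", "Y"), transcript_id = c("X.T1", "Y.T1"),
               start = c(9000, 11000), end = c(10000, 12000)))
  res2 <- traditional_assign(data.frame(chrom = "chr1", summit = 10000,
                                        score = 5), ann2, window = 2000)
  expect_equal(res2$gene_id, "X")
  expect_error(traditional_assign(peaks, ann, window = 0),
               class = "peakodds_invalid_input")
})

test_that("ranked-list overlap handles identical, disjoint and short lists", {
  expect_equal(compare_assignments(letters[1:10], letters[1:10], 5), 1.0)
  expect_equal(compare_assignments(letters[1:5], letters[6:10], 5), 0.0)
  expect_equal(compare_assignments(c("a", "b", "c", "d"),
                                   c("c", "d", "x", "y"), 4), 0.5)
  # a truncated list keeps the requested denominator
  expect_warning(ov <- compare_assignments(letters[1:3], letters[1:3], 10),
                 "full")
  expect_equal(ov, 0.3)
})

test_that("probabilistic and promoter-window lists diverge when planted
           targets sit outside the window", {
  # construct genes whose peaks are planted alternately at 1 kb (inside the
  # +/-2 kb window) and 10 kb (outside) upstream: the traditional method
  # keeps only half the genes, so top-n overlap is ~0.5
  n <- 40
  starts <- seq(50000, by = 25000, length.out = n)
  ann <- genome_annotation(
    c(chr1 = 50000 + 25000 * n + 100000),
    data.frame(gene_id = sprintf("G%02d", 1:n), chrom = "chr1", strand = "+"),
    data.frame(gene_id = sprintf("G%02d", 1:n),
               transcript_id = sprintf("G%02d.T1", 1:n),
               start = starts, end = starts + 5000))
  offset <- rep(c(1000, 10000), length.out = n)
  peaks <- data.frame(chrom = "chr1", summit = starts - offset, score = 50)
  odds <- reference_odds()
  prob <- score_genes(assign_peaks(peaks, ann, odds))
  trad <- traditional_assign(peaks, ann, window = 2000)
  expect_equal(nrow(trad), n / 2)
  expect_warning(ov <- compare_assignments(prob, trad, n), "full")
  expect_equal(ov, 0.5)
})
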