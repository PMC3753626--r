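# Exhaustive/naive oracles for the PWM machinery are defined inline: the
# naive per-position product score, and full enumeration of all 4^w windows
# for the best-site null.

naive_score <- function(window, pwm, bkg) {
  bases <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  prod_motif <- prod(pwm$mat[cbind(bases, seq_along(bases))])
  prod_bkg <- prod(bkg[bases])
  log(prod_motif / prod_bkg)
}

all_kmers <- function(w) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), w),
                              stringsAsFactors = FALSE))
}

test_that("position score equals the naive log product", {
  withr::with_seed(41, {
    for (i in 1:20) {
      w <- sample(4:12, 1)
      m <- matrix(rgamma(4 * w, 1) + 0.01, 4)
      m <- sweep(m, 2, colSums(m), "/")
      pwm <- pwm_record("r", m)
      bkg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
      win <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                   collapse = "")
      expect_equal(position_score(win, pwm, bkg), naive_score(win, pwm, bkg),
                   tolerance = 1e-12)
    }
  })
})

test_that("uniform PWM scores zero and ambiguous bases use the column mean", {
  flat <- pwm_record("flat", matrix(0.25, 4, 5))
  expect_equal(position_score("ACGTN", flat), 0)
  one <- pwm_record("one", matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1))
  expect_equal(position_score("A", one), log(0.97 / 0.25))
  # N contributes the log background-weighted column mean ratio (= 0 for a
  # normalised column under its own background)
  expect_equal(position_score("N", one), 0)
  # zero entries without a pseudocount are rejected with guidance
  zero <- pwm_record("z", matrix(c(1, 0, 0, 0), 4, 1))
  expect_error(position_score("A", zero), "pseudocount")
})

test_that("best-site p-value counts both strands in the Bonferroni factor", {
  pwm <- consensus_pwm(strrep("A", 12))
  frag <- strrep("C", 500)
  r <- best_site_pvalue(frag, pwm)
  expect_equal(r$n_tests, 2L * (500L - 12L + 1L))
  expect_true(r$corrected_p >= r$raw_p)

  flat <- pwm_record("flat", matrix(0.25, 4, 8))
  expect_equal(best_site_pvalue("ACGTACGTACGTACGT", flat)$corrected_p, 1)
  expect_error(best_site_pvalue("ACGT", pwm), class = "peakodds_invalid_input")
})

test_that("best-site p-value matches alphabet-complete enumeration", {
  # every window of length w over the full alphabet, compared to the exact
  # convolution null at 1e-12
  withr::with_seed(42, {
    for (w in c(3, 4, 6)) {
      m <- matrix(rgamma(4 * w, 1) + 0.05, 4)
      m <- sweep(m, 2, colSums(m), "/")
      pwm <- pwm_record(paste0("w", w), m)
      bkg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
      kmers <- all_kmers(w)
      scores <- vapply(kmers, naive_score, 0, pwm = pwm, bkg = bkg)
      null <- pwm_null_distribution(pwm, bkg)
      expect_true(null$exact)
      for (frag in sample(kmers, 25)) {
        r <- best_site_pvalue(frag, pwm, bkg, null)
        # enumeration oracle: mass of windows scoring >= the observed best
        want <- mean(scores >= r$best_score - 1e-9)
        expect_equal(r$raw_p, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("a planted consensus site in a random fragment is significant", {
  withr::with_seed(43, {
    pwm <- consensus_pwm("TGGGACTTTCCA")
    frag <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
    planted <- paste0(substr(frag, 1, 200), "TGGGACTTTCCA",
                      substr(frag, 213, 500))
    r <- best_site_pvalue(planted, pwm)
    expect_lt(r$corrected_p, 1e-3)
    expect_equal(r$best_pos, 200L)
    expect_equal(r$best_strand, "+")
    # and the reverse complement is found on the minus strand
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(planted)))
    r2 <- best_site_pvalue(rc, pwm)
    expect_equal(r2$best_strand, "-")
    expect_equal(r2$best_score, r$best_score)
  })
})

test_that("Bonferroni-corrected p grows with fragment length at fixed raw p", {
  pwm <- consensus_pwm("ACGTAC")
  null <- pwm_null_distribution(pwm)
  base <- strrep("G", 50)
  p_short <- best_site_pvalue(paste0(base, "ACGTAC"), pwm, null = null)
  p_long <- best_site_pvalue(paste0(strrep("G", 400), "ACGTAC"), pwm,
                             null = null)
  expect_equal(p_short$raw_p, p_long$raw_p)
  expect_gt(p_long$corrected_p, p_short$corrected_p)
})

test_that("occurrence counting recovers planted sites and is deterministic", {
  spec <- small_spec(seed = 9)
  g <- make_genome(spec)
  pk <- plant_peaks(spec, g$annotation, n_peaks = 50)
  pm <- plant_motifs(spec, g$genome, pk$peaks)
  pwm <- consensus_pwm(spec$datum_motif, name = "datum")
  half <- 250L
  frags <- data.frame(chrom = pk$peaks$chrom,
                      start = pmax(0L, pk$peaks$summit - half),
                      end = pmin(1e6L, pk$peaks$summit + half))
  occ <- count_occurrences(frags, pm$genome, pwm, alpha = 0.05)
  expect_gte(occ$count, 48L)  # boundary losses allowed
  occ2 <- count_occurrences(frags, pm$genome, pwm, alpha = 0.05)
  expect_identical(occ$hits$best_pos, occ2$hits$best_pos)

  flat <- pwm_record("flat", matrix(0.25, 4, 12))
  expect_equal(count_occurrences(frags, pm$genome, flat, alpha = 0.05)$count,
               0L)
})

test_that("hypergeometric tails match exhaustive draw enumeration", {
  # direct enumeration of all C(N, n) draws for every instance with N <= 12
  enum <- function(k, n, K, N) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)  # items 1..K are the successes
    c(mean(hits >= k), mean(hits <= k))
  }
  for (N in c(5, 9, 12)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, 3, N)) {
        if (n > N) next
        for (k in unique(c(0, 1, min(n, K)))) {
          if (k > min(n, K)) next
          got <- hypergeom_test(k, n, K, N)
          want <- enum(k, n, K, N)
          expect_equal(got$p_enriched, want[1], tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
          expect_equal(got$p_depleted, want[2], tolerance = 1e-12)
        }
      }
    }
  }
  expect_equal(hypergeom_test(4, 4, 5, 10)$p_enriched, 5 / 210,
               tolerance = 1e-12)
  expect_error(hypergeom_test(6, 5, 5, 10), class = "peakodds_invalid_input")
})

test_that("enrichment and depletion p-values share the point mass", {
  withr::with_seed(44, {
    for (i in 1:50) {
      N <- sample(10:200, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
      lo <- max(0, n + K - N); hi <- min(n, K)
      k <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      ht <- hypergeom_test(k, n, K, N)
      expect_gte(ht$p_enriched + ht$p_depleted, 1)
      expect_true(ht$p_enriched > 0 && ht$p_enriched <= 1)
      expect_true(ht$p_depleted > 0 && ht$p_depleted <= 1)
    }
  })
})

test_that("likelihood histograms separate planted peaks from background", {
  spec <- small_spec(seed = 19)
  g <- make_genome(spec)
  pk <- plant_peaks(spec, g$annotation, n_peaks = 60)
  pm <- plant_motifs(spec, g$genome, pk$peaks)
  pwm <- consensus_pwm(spec$datum_motif, name = "datum")
  bkg <- genome_background(pm$genome)
  null <- pwm_null_distribution(pwm, bkg)
  frags <- data.frame(chrom = pk$peaks$chrom,
                      start = pmax(0L, pk$peaks$summit - 250L),
                      end = pmin(1e6L, pk$peaks$summit + 250L))
  pk_scores <- count_occurrences(frags, pm$genome, pwm, background = bkg,
                                 null = null)$hits$best_score
  gen_scores <- count_occurrences(
    data.frame(chrom = "chr1", start = 0L, end = 1e6L),
    pm$genome, pwm, background = bkg, null = null)$hits$best_score
  h <- likelihood_histograms(pk_scores, gen_scores)
  expect_gt(h$separation, 2)
  expect_equal(sum(h$peak_counts), length(pk_scores))
  expect_equal(sum(h$genome_counts), length(gen_scores))
  # degenerate single-fragment histogram carries one mass
  h1 <- likelihood_histograms(pk_scores[1], pk_scores[1])
  expect_equal(sum(h1$peak_counts), 1L)
})

test_that("a motif frequent in the genome but not in peaks is called depleted", {
  # the empirical-frequency correction: a low-complexity motif planted
  # heavily across the genome background but only at background rate inside
  # peaks must come out depleted, not enriched
  spec <- small_spec(seed = 29)
  g <- make_genome(spec)
  pk <- plant_peaks(spec, g$annotation, n_peaks = 60)
  pm <- plant_motifs(spec, g$genome, pk$peaks)  # datum motif in peaks only
  polyA <- strrep("A", 12)
  genome <- pm$genome
  # plant poly-A across the genome, avoiding the peak fragments
  withr::with_seed(30, {
    keepout <- IRanges::IRanges(pmax(1, pk$peaks$summit - 300),
                                pk$peaks$summit + 300)
    spots <- IRanges::IRanges(sort(sample.int(1e6 - 12, 3000)), width = 12)
    spots <- spots[!IRanges::overlapsAny(spots, keepout)]
    spots <- IRanges::reduce(spots)
    spots <- spots[IRanges::width(spots) >= 12]
    genome[["chr1"]] <- Biostrings::replaceAt(
      genome[["chr1"]], IRanges::resize(spots, 12),
      Biostrings::DNAStringSet(rep(polyA, length(spots))))
  })
  res <- motif_validate(pk$peaks, genome,
                        list(consensus_pwm(polyA, name = "polyA"),
                             consensus_pwm(spec$datum_motif, name = "datum")),
                        alpha = 0.05)
  expect_equal(res[res$motif == "polyA", ]$verdict, "depleted")
  expect_equal(res[res$motif == "datum", ]$verdict, "enriched")
})
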