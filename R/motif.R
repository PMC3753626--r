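#' Construct a position weight matrix record
#'
#' @param name motif name
#' @param mat 4 x w matrix of per-position base probabilities, rows A, C, G,
#'   T; each column must sum to 1 within `1e-6`
#' @param bkg background base frequencies (named A/C/G/T, summing to 1)
#' @param pseudocount added to every entry, columns renormalised (keeps
#'   log-ratio scores finite); 0 leaves the matrix untouched
#' @return object of class `pwm_record` with fields `name`, `mat`, `bkg`,
#'   `width`
#' @export
pwm_record <- function(name, mat, bkg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pseudocount = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) abort("PWM must have 4 rows (A, C, G, T)",
                             "peakodds_invalid_pwm")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(mat < 0)) abort("PWM entries must be non-negative",
                          "peakodds_invalid_pwm")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6))
    abort(sprintf("PWM column %d sums to %.8f, not 1 (tolerance 1e-6)",
                  which(abs(cs - 1) > 1e-6)[1], cs[which(abs(cs - 1) > 1e-6)[1]]),
          "peakodds_invalid_pwm")
  if (pseudocount > 0) {
    mat <- mat + pseudocount
    mat <- sweep(mat, 2, colSums(mat), "/")
  }
  bkg <- bkg[c("A", "C", "G", "T")]
  if (abs(sum(bkg) - 1) > 1e-6)
    abort("background frequencies must sum to 1", "peakodds_invalid_pwm")
  structure(list(name = name, mat = mat, bkg = bkg, width = ncol(mat)),
            class = "pwm_record")
}

#' @export
print.pwm_record <- function(x, ...) {
  ic <- sum(2 + colSums(ifelse(x$mat > 0, x$mat * log2(x$mat), 0)))
  cat(sprintf("pwm_record '%s': width %d, information content %.1f bits\n",
              x$name, x$width, ic))
  invisible(x)
}

#' Build a sharply peaked PWM from a consensus sequence
#'
#' @param seq consensus string (A/C/G/T)
#' @param strength probability of the consensus base at each position; the
#'   remainder is spread over the other three bases
#' @param name motif name
#' @return a [pwm_record()]
#' @export
consensus_pwm <- function(seq, strength = 0.97, name = seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    abort("consensus must be A/C/G/T only", "peakodds_invalid_pwm")
  mat <- matrix((1 - strength) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- strength
  pwm_record(name, mat)
}

# A/C/G/T -> 1/2/3/4, anything else NA; fast lookup via utf8 codes
seq_to_codes <- function(s) {
  if (inherits(s, "XString")) s <- as.character(s)
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(s)]
}

# log-likelihood-ratio score matrix (4 x w) and the per-column score used for
# ambiguous bases: the background-weighted mean ratio, log(sum_b bkg_b *
# pwm_bj / bkg_b) = log(sum_b pwm_bj)
score_matrix <- function(pwm, background = NULL) {
  bkg <- background %||% pwm$bkg
  if (any(pwm$mat == 0))
    abort("PWM contains zero entries; re-read with a pseudocount (see read_pwm)",
          "peakodds_invalid_pwm")
  list(M = log(pwm$mat / bkg), n_score = log(colSums(pwm$mat)), bkg = bkg)
}

#' Log likelihood-ratio score of one window
#'
#' `sum_j log(pwm[base_j, j] / background[base_j])`: the log ratio of the
#' likelihood that the window was emitted by the motif versus by the
#' background. An ambiguous base contributes the log of the
#' background-weighted column mean ratio.
#'
#' @param window sequence of length equal to the PWM width
#' @param pwm a [pwm_record()]
#' @param background base frequencies (default: the PWM's own background)
#' @return numeric log likelihood ratio
#' @export
position_score <- function(window, pwm, background = NULL) {
  sm <- score_matrix(pwm, background)
  codes <- seq_to_codes(window)
  if (length(codes) != pwm$width)
    abort("window length must equal PWM width", "peakodds_invalid_input")
  contrib <- sm$M[cbind(codes, seq_len(pwm$width))]
  contrib[is.na(codes)] <- sm$n_score[is.na(codes)]
  sum(contrib)
}

# forward-strand window scores along a code vector; O(L * w) vectorised
scan_codes <- function(codes, sm, w) {
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    v <- sm$M[cbind(cj, j)]
    v[is.na(cj)] <- sm$n_score[j]
    s <- s + v
  }
  s
}

revcomp_codes <- function(codes) rev(5L - codes)

#' Exact null distribution of PWM window scores under the background
#'
#' The distribution of the log likelihood-ratio score of a single background
#' window, computed by column-wise convolution of the per-column score
#' distribution. When the full support is small (width <= `exact_max_width`)
#' the convolution runs over exact score values, so tail probabilities agree
#' with exhaustive window enumeration to machine precision; for wider motifs
#' scores are binned at `bin`.
#'
#' @param pwm a [pwm_record()]
#' @param background base frequencies (default: the PWM's background)
#' @param bin score bin width for the discretised path
#' @param exact_max_width largest width for which the exact path is used
#' @return list with sorted `scores` and `tail` (`P(X >= score)`), plus
#'   `exact` flag
#' @export
pwm_null_distribution <- function(pwm, background = NULL, bin = 1e-3,
                                  exact_max_width = 10) {
  sm <- score_matrix(pwm, background)
  exact <- pwm$width <= exact_max_width
  dist <- data.table(v = sm$M[, 1], p = as.numeric(sm$bkg))
  if (pwm$width > 1) for (j in 2:pwm$width) {
    v <- as.vector(outer(dist$v, sm$M[, j], "+"))
    p <- as.vector(outer(dist$p, as.numeric(sm$bkg), "*"))
    dist <- data.table(v = v, p = p)
    if (!exact) dist[, v := round(v / bin) * bin]
    dist <- dist[, .(p = sum(p)), by = v]
  }
  setorder(dist, v)
  tail_p <- rev(cumsum(rev(dist$p)))
  structure(list(scores = dist$v, tail = pmin(tail_p, 1), exact = exact,
                 bin = if (exact) 0 else bin),
            class = "pwm_null")
}

# P(X >= s) from a pwm_null, vectorised over s; scores within 1e-9 of a
# support point count as attaining it
null_tail_p <- function(null, s) {
  i <- findInterval(s - 1e-9, null$scores)
  # i == length(scores) means the score exceeds the whole support; report the
  # smallest attainable tail mass rather than 0 so corrected p stays in (0, 1]
  null$tail[pmin(i + 1L, length(null$scores))]
}

#' Best motif site in a fragment, with Bonferroni-corrected p-value
#'
#' Scans both strands of the fragment (`m = 2 * (L - w + 1)` tests), takes the
#' highest-scoring window, computes its raw p-value from the exact null score
#' distribution of the background model, and applies the Bonferroni correction
#' `min(1, m * raw)` — under the assumption that a fragment harbours at most
#' one true binding site.
#'
#' @param fragment sequence (character or `DNAString`), length >= PWM width
#' @param pwm a [pwm_record()]
#' @param background base frequencies (default: the PWM's background)
#' @param null optional precomputed [pwm_null_distribution()] (recomputed
#'   otherwise)
#' @param fragment_id carried into the result
#' @return list of class `scan_result`: `fragment_id`, `best_pos` (0-based
#'   forward-strand start of the best window), `best_strand`, `best_score`,
#'   `raw_p`, `corrected_p`, `n_tests`
#' @export
best_site_pvalue <- function(fragment, pwm, background = NULL, null = NULL,
                             fragment_id = NA_character_) {
  codes <- seq_to_codes(fragment)
  L <- length(codes)
  w <- pwm$width
  if (L < w) abort("fragment shorter than the motif", "peakodds_invalid_input")
  sm <- score_matrix(pwm, background)
  if (is.null(null)) null <- pwm_null_distribution(pwm, background)
  fwd <- scan_codes(codes, sm, w)
  rev_ <- scan_codes(revcomp_codes(codes), sm, w)
  m <- 2L * (L - w + 1L)
  bf <- which.max(fwd); br <- which.max(rev_)
  if (fwd[bf] >= rev_[br]) {
    best_score <- fwd[bf]; best_strand <- "+"; best_pos <- bf - 1L
  } else {
    best_score <- rev_[br]; best_strand <- "-"
    best_pos <- L - w + 1L - br  # forward-strand start of the rc window
  }
  raw <- null_tail_p(null, best_score)
  structure(list(fragment_id = fragment_id, best_pos = best_pos,
                 best_strand = best_strand, best_score = best_score,
                 raw_p = raw, corrected_p = min(1, m * raw), n_tests = m),
            class = "scan_result")
}

# best window score per tile, both strands, from one whole-region scan.
# tiles: data.table(tile_id, start, end) 0-based within `codes`.
tile_best_scores <- function(codes, tiles, sm, w) {
  out <- lapply(seq_len(nrow(tiles)), function(i) {
    ts <- tiles$start[i]; te <- tiles$end[i]
    sub <- codes[(ts + 1L):te]
    if (length(sub) < w)
      return(list(best_score = -Inf, best_pos = NA_integer_,
                  best_strand = NA_character_, n_tests = 0L))
    fwd <- scan_codes(sub, sm, w)
    rev_ <- scan_codes(revcomp_codes(sub), sm, w)
    bf <- which.max(fwd); br <- which.max(rev_)
    if (fwd[bf] >= rev_[br])
      list(best_score = fwd[bf], best_pos = ts + bf - 1L, best_strand = "+",
           n_tests = 2L * length(fwd))
    else
      list(best_score = rev_[br], best_pos = ts + length(sub) - w + 1L - br,
           best_strand = "-", n_tests = 2L * length(rev_))
  })
  rbindlist(out)
}

#' Count significant motif occurrences in tiled regions
#'
#' Regions are tiled into `tile_width`-bp fragments (the occurrence unit: at
#' most one best site per tile, matching the one-site-per-fragment
#' assumption); a tile counts as an occurrence when its Bonferroni-corrected
#' best-site p-value is at most `alpha`.
#'
#' @param regions data.frame/`GRanges` of intervals (`chrom`, `start`, `end`,
#'   0-based half-open), within genome bounds
#' @param genome named `DNAStringSet`
#' @param pwm a [pwm_record()]
#' @param alpha corrected-p threshold
#' @param tile_width fragment size in bp
#' @param background base frequencies (default: 0th-order composition of
#'   `genome`)
#' @param null optional precomputed [pwm_null_distribution()]
#' @return list: `count` (tiles with an occurrence), `n_tiles`, `hits`
#'   (data.table of per-tile best sites with corrected p), `alpha`
#' @export
count_occurrences <- function(regions, genome, pwm, alpha = 0.05,
                              tile_width = 500, background = NULL,
                              null = NULL) {
  if (inherits(regions, "GRanges")) {
    regions <- data.table(chrom = as.character(GenomicRanges::seqnames(regions)),
                          start = GenomicRanges::start(regions) - 1L,
                          end = GenomicRanges::end(regions))
  } else regions <- as.data.table(regions)
  background <- background %||% genome_background(genome)
  sm <- score_matrix(pwm, background)
  if (is.null(null)) null <- pwm_null_distribution(pwm, background)
  w <- pwm$width
  res <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(genome))
      abort(paste0("region on unknown chromosome ", chrom), "peakodds_invalid_input")
    s0 <- regions$start[i]; e0 <- regions$end[i]
    if (s0 < 0 || e0 > length(genome[[chrom]]))
      abort("region outside genome bounds", "peakodds_invalid_input")
    codes <- seq_to_codes(Biostrings::subseq(genome[[chrom]], s0 + 1L, e0))
    tile_starts <- seq.int(0L, max(0L, e0 - s0 - 1L), by = tile_width)
    tiles <- data.table(start = tile_starts,
                        end = pmin(tile_starts + tile_width, e0 - s0))
    tb <- tile_best_scores(codes, tiles, sm, w)
    tb[, `:=`(chrom = chrom,
              tile_start = s0 + tiles$start, tile_end = s0 + tiles$end)]
    tb[, best_pos := best_pos + s0]
    res[[i]] <- tb
  }
  hits <- rbindlist(res)
  hits <- hits[n_tests > 0L]
  hits[, raw_p := null_tail_p(null, best_score)]
  hits[, corrected_p := pmin(1, n_tests * raw_p)]
  list(count = sum(hits$corrected_p <= alpha), n_tiles = nrow(hits),
       hits = hits[], alpha = alpha)
}

#' 0th-order base composition of a genome
#'
#' @param genome `DNAStringSet`
#' @return named frequency vector over A/C/G/T (ambiguous bases ignored)
#' @export
genome_background <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                                          drop = FALSE])
  counts / sum(counts)
}

#' Hypergeometric enrichment and depletion p-values
#'
#' For `X ~ Hypergeometric(N, K, n)` (n draws from a population of N with K
#' successes): `p_enriched = P(X >= k)`, `p_depleted = P(X <= k)`. Computed
#' via the stable log-space tail routines of [stats::phyper()].
#'
#' @param k observed successes in the sample
#' @param n sample size
#' @param K successes in the population
#' @param N population size
#' @return list with `p_enriched` and `p_depleted`
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (k < 0 || k > min(n, K) || n > N || K > N)
    abort("hypergeometric bounds violated (need 0 <= k <= min(n, K); n, K <= N)",
          "peakodds_invalid_input")
  p_enr <- exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  p_dep <- exp(phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
  list(p_enriched = min(1, p_enr), p_depleted = min(1, p_dep))
}

#' Motif enrichment report against empirical genome frequency
#'
#' The antidote to inflated theoretical motif E-values: occurrences are
#' counted in peak fragments and in identically tiled genome background, and
#' a hypergeometric test decides enrichment or depletion of the motif in the
#' peaks relative to its actual genome frequency.
#'
#' @param peaks data.frame of peaks (`chrom`, `summit`)
#' @param genome named `DNAStringSet`
#' @param pwms list of [pwm_record()]s
#' @param alpha corrected-p threshold for calling an occurrence, and the
#'   significance level for the verdict
#' @param fragment_width width of the fragment centred on each summit
#' @return data.table: one row per motif with counts `k`, `n`, `K`, `N`,
#'   `p_enriched`, `p_depleted` and `verdict`
#'   (enriched/depleted/neither)
#' @export
motif_validate <- function(peaks, genome, pwms, alpha = 0.05,
                           fragment_width = 500) {
  peaks <- as.data.table(peaks)
  half <- fragment_width %/% 2L
  frag <- data.table(chrom = peaks$chrom,
                     start = pmax(0L, peaks$summit - half))
  lens <- setNames(Biostrings::width(genome), names(genome))
  frag[, end := pmin(start + fragment_width, lens[chrom])]
  frag[, start := pmax(0L, end - fragment_width)]
  genome_tiles <- data.table(chrom = names(genome), start = 0L,
                             end = as.integer(lens))
  bkg <- genome_background(genome)
  out <- lapply(pwms, function(pwm) {
    null <- pwm_null_distribution(pwm, bkg)
    inpk <- count_occurrences(frag, genome, pwm, alpha, fragment_width, bkg, null)
    ingen <- count_occurrences(genome_tiles, genome, pwm, alpha, fragment_width,
                               bkg, null)
    ht <- hypergeom_test(min(inpk$count, ingen$count), inpk$n_tiles,
                         ingen$count, ingen$n_tiles)
    data.table(motif = pwm$name, k = inpk$count, n = inpk$n_tiles,
               K = ingen$count, N = ingen$n_tiles,
               p_enriched = ht$p_enriched, p_depleted = ht$p_depleted,
               verdict = if (ht$p_enriched <= alpha) "enriched"
                         else if (ht$p_depleted <= alpha) "depleted"
                         else "neither")
  })
  rbindlist(out)
}

#' Best-site score histograms for peaks versus genome background
#'
#' The in-silico validation picture: the distribution of per-fragment best
#' likelihood scores among peak fragments against the same distribution over
#' genome tiles, on a common binning, with a separation statistic (difference
#' of means). A genuinely enriched motif shifts the peak histogram to the
#' right.
#'
#' @param peak_scores,genome_scores numeric vectors of per-fragment best-site
#'   scores (e.g. `hits$best_score` from [count_occurrences()])
#' @param n_breaks number of common bins
#' @return list: `breaks`, `peak_counts`, `genome_counts`, `separation`
#' @export
likelihood_histograms <- function(peak_scores, genome_scores, n_breaks = 50) {
  if (length(peak_scores) == 0L || length(genome_scores) == 0L)
    abort("both score sets must be non-empty", "peakodds_invalid_input")
  rng <- range(c(peak_scores, genome_scores))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  list(breaks = breaks,
       peak_counts = hist(peak_scores, breaks = breaks, plot = FALSE)$counts,
       genome_counts = hist(genome_scores, breaks = breaks, plot = FALSE)$counts,
       separation = mean(peak_scores) - mean(genome_scores))
}
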