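#' Construct an empirical enrichment result
#'
#' Output of every permutation test: the observed statistic, a summary of the
#' permutation null, and empirical tail p-values estimated as `max(r, 1) / n`
#' so the smallest reportable p equals `1/n`.
#'
#' @param statistic statistic name
#' @param observed observed value
#' @param null_values numeric vector of null statistics
#' @return object of class `enrichment_result`
#' @keywords internal
enrichment_result <- function(statistic, observed, null_values) {
  n <- length(null_values)
  r_enr <- sum(null_values >= observed - 1e-12)
  r_dep <- sum(null_values <= observed + 1e-12)
  structure(list(statistic = statistic, observed = observed,
                 null_mean = mean(null_values), null_sd = sd(null_values),
                 p_enriched = max(r_enr, 1) / n,
                 p_depleted = max(r_dep, 1) / n,
                 n_permutations = n),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("enrichment_result '%s': observed %.4g, null %.4g +/- %.4g ",
                     "(n = %d)\n  p_enriched = %.3g, p_depleted = %.3g\n"),
              x$statistic, x$observed, x$null_mean, x$null_sd,
              x$n_permutations, x$p_enriched, x$p_depleted))
  invisible(x)
}

# peaks data.frame (0-based half-open) -> GRanges
gr_from_peaks <- function(peaks) {
  if (inherits(peaks, "GRanges")) return(peaks)
  peaks <- as.data.table(peaks)
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

gr_from_lengths <- function(chrom_lengths) {
  GenomicRanges::GRanges(names(chrom_lengths),
                         IRanges::IRanges(1L, as.integer(chrom_lengths)))
}

# disjoint sorted GRanges -> concatenated-coordinate table
concat_space <- function(mask) {
  mask <- GenomicRanges::reduce(GenomicRanges::sort(mask))
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(mask)),
                   start = GenomicRanges::start(mask) - 1L,
                   end = GenomicRanges::end(mask))
  dt[, width := end - start]
  dt[, offset := cumsum(c(0, head(width, -1)))]
  dt
}

# map a GRanges into concatenated mask coordinates (pieces outside the mask
# are dropped); returns dt(start, end) sorted and merged
to_concat <- function(gr, space) {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  a <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr))
  pieces <- space[a, on = .(chrom, start < end, end > start), nomatch = 0L,
                  .(m_start = x.start, m_end = x.end, m_off = offset,
                    q_start = i.start, q_end = i.end)]
  if (nrow(pieces) == 0L) return(data.table(start = numeric(), end = numeric()))
  out <- pieces[, .(start = m_off + pmax(q_start, m_start) - m_start,
                    end = m_off + pmin(q_end, m_end) - m_start)]
  setorder(out, start)
  # merge touching pieces
  gap <- c(TRUE, out$start[-1] > out$end[-nrow(out)])
  grp <- cumsum(gap)
  out[, .(start = min(start), end = max(end)), by = .(grp = grp)][, .(start, end)]
}

# cumulative feature coverage C(x) = feature bp in [0, x); feat sorted disjoint
coverage_lookup <- function(feat) {
  fs <- feat$start; fe <- feat$end
  cum <- cumsum(c(0, head(fe - fs, -1)))
  function(x) {
    i <- findInterval(x, fs)
    out <- numeric(length(x))
    hit <- i > 0L
    out[hit] <- cum[i[hit]] + pmax(0, pmin(x[hit], fe[i[hit]]) - fs[i[hit]])
    out
  }
}

# n replicates of non-overlapping placement of k intervals with the given
# lengths, uniform over [0, total): starts sampled uniformly, draws
# overlapping an earlier placement within the replicate are rejected and
# resampled (cap max_rounds, then error). Returns n x k matrix of starts.
sample_placements <- function(n, lengths, total, max_rounds = 1000) {
  k <- length(lengths)
  if (sum(lengths) > total)
    abort("total interval length exceeds the mappable space",
          "peakodds_invalid_input")
  starts <- matrix(0, nrow = n, ncol = k)
  for (i in seq_len(k)) {
    span <- total - lengths[i] + 1
    if (span <= 0) abort("interval longer than the mappable space",
                         "peakodds_invalid_input")
    cand <- floor(runif(n) * span)
    if (i > 1L) {
      for (round in seq_len(max_rounds)) {
        bad <- rep(FALSE, n)
        for (j in seq_len(i - 1L)) {
          bad <- bad | (cand < starts[, j] + lengths[j] &
                        starts[, j] < cand + lengths[i])
        }
        if (!any(bad)) break
        if (round == max_rounds)
          abort("could not place non-overlapping intervals after 1000 rejections",
                "peakodds_placement_failure")
        cand[bad] <- floor(runif(sum(bad)) * span)
      }
    }
    starts[, i] <- cand
  }
  starts
}

#' Feature enrichment in peaks by mappability-restricted random placement
#'
#' Observed statistic: the fraction of mappable peak nucleotides covered by
#' the feature. Null: `n` random assignments of the peaks to non-overlapping
#' locations of their respective mappable lengths, uniform in the
#' concatenated mappable space; empirical p-values are tail frequencies with
#' floor `1/n`.
#'
#' @param peaks data.frame of peaks or `GRanges`
#' @param feature feature track (`GRanges`, disjoint after read)
#' @param mask mappability mask (`GRanges`); `NULL` means fully mappable
#'   chromosomes given by `chrom_lengths`
#' @param n number of random placements (>= 1)
#' @param seed integer seed
#' @param chrom_lengths named chromosome lengths, required when `mask` is NULL
#' @return an `enrichment_result`
#' @export
feature_enrichment <- function(peaks, feature, mask = NULL, n = 100000,
                               seed = 1, chrom_lengths = NULL) {
  if (n < 1) abort("n must be >= 1", "peakodds_invalid_input")
  if (is.null(mask)) {
    if (is.null(chrom_lengths))
      abort("need a mask or chrom_lengths", "peakodds_invalid_input")
    mask <- gr_from_lengths(chrom_lengths)
  }
  pk <- gr_from_peaks(peaks)
  space <- concat_space(mask)
  total <- sum(space$width)
  pk_cc <- lapply(seq_along(pk), function(i) to_concat(pk[i], space))
  lens <- vapply(pk_cc, function(p) sum(p$end - p$start), 0)
  if (any(lens == 0)) {
    warning(sum(lens == 0), " peak(s) with no mappable bases dropped")
    pk_cc <- pk_cc[lens > 0]
    lens <- lens[lens > 0]
  }
  if (length(lens) == 0L) abort("no mappable peaks", "peakodds_invalid_input")
  feat_cc <- to_concat(feature, space)
  covfun <- coverage_lookup(feat_cc)

  obs_bp <- sum(vapply(pk_cc, function(p) sum(covfun(p$end) - covfun(p$start)), 0))
  observed <- obs_bp / sum(lens)

  null_values <- with_fixed_seed(seed, {
    starts <- sample_placements(n, lens, total)
    ov <- matrix(0, nrow = n, ncol = length(lens))
    for (i in seq_along(lens))
      ov[, i] <- covfun(starts[, i] + lens[i]) - covfun(starts[, i])
    rowSums(ov) / sum(lens)
  })
  enrichment_result("feature_proportion_in_peaks", observed, null_values)
}

#' TF overlap enrichment by label shuffling
#'
#' For each TF, the statistic is the mean over its peaks of (bp overlap with
#' the reference peak set) / (peak length). The null shuffles TF labels over
#' the pooled peaks `n_shuffles` times, preserving per-TF counts and the
#' multiset of intervals; the attainable p-value resolution is
#' `1/n_shuffles`.
#'
#' @param tf_peaksets named list of peak data.frames or `GRanges` (>= 2 TFs)
#' @param reference_peaks reference peak set
#' @param n_shuffles number of label shuffles
#' @param seed integer seed
#' @return named list of `enrichment_result`, one per TF
#' @export
tf_overlap_enrichment <- function(tf_peaksets, reference_peaks,
                                  n_shuffles = 40000, seed = 1) {
  if (length(tf_peaksets) < 2L) abort("need >= 2 TF peak sets",
                                      "peakodds_invalid_input")
  ref <- GenomicRanges::reduce(gr_from_peaks(reference_peaks))
  grs <- lapply(tf_peaksets, gr_from_peaks)
  labels <- rep(names(grs), times = vapply(grs, length, 0L))
  pooled <- do.call(c, unname(grs))
  widths <- GenomicRanges::width(pooled)
  if (any(widths == 0)) abort("zero-length peak", "peakodds_invalid_input")
  ov <- GenomicRanges::findOverlaps(pooled, ref)
  ovw <- numeric(length(pooled))
  if (length(ov)) {
    inter <- IRanges::pintersect(pooled[S4Vectors::queryHits(ov)],
                                 ref[S4Vectors::subjectHits(ov)])
    per <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    ovw[as.integer(names(per))] <- per
  }
  o <- ovw / widths
  lab_f <- factor(labels, levels = names(grs))
  obs <- tapply(o, lab_f, mean)

  null_mat <- with_fixed_seed(seed, {
    counts <- as.integer(table(lab_f))
    m <- matrix(0, nrow = n_shuffles, ncol = length(counts))
    for (r in seq_len(n_shuffles)) {
      perm <- sample(o)
      m[r, ] <- rowsum(perm, lab_f, reorder = TRUE) / counts
    }
    m
  })
  out <- lapply(seq_along(obs), function(t)
    enrichment_result(paste0("mean_normalized_overlap:", names(obs)[t]),
                      obs[[t]], null_mat[, t]))
  names(out) <- names(obs)
  out
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail p-value of the observed overlap between two gene sets drawn
#' from a universe of known size (delegates to [hypergeom_test()]).
#'
#' @param set_a,set_b character vectors of gene ids (subsets of the universe)
#' @param universe_size size of the gene universe
#' @return list: `overlap`, `p_enriched`, `p_depleted`
#' @export
geneset_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size)
    abort("set exceeds the universe", "peakodds_invalid_input")
  k <- length(intersect(set_a, set_b))
  ht <- hypergeom_test(k, length(set_a), length(set_b), universe_size)
  c(list(overlap = k), ht)
}

#' Normalised motif-class expression profile over timepoints
#'
#' Per timepoint, the fraction of differentially expressed genes carrying the
#' motif class, divided by the mean fraction across timepoints. Timepoints
#' with zero DE genes are undefined (`NA`) and excluded from the mean.
#'
#' @param de_genes_per_timepoint named list: per timepoint, a character vector
#'   of differentially expressed genes
#' @param motif_class_members character vector of genes carrying the motif
#' @return data.table: `timepoint`, `n_de`, `fraction`, `normalized`
#' @export
motif_class_expression_profile <- function(de_genes_per_timepoint,
                                           motif_class_members) {
  if (length(de_genes_per_timepoint) < 1L)
    abort("need >= 1 timepoint", "peakodds_invalid_input")
  n_de <- vapply(de_genes_per_timepoint, length, 0L)
  frac <- vapply(de_genes_per_timepoint, function(g)
    if (length(g) == 0L) NA_real_ else mean(g %in% motif_class_members), 0)
  norm <- frac / mean(frac, na.rm = TRUE)
  data.table(timepoint = names(de_genes_per_timepoint) %||%
               as.character(seq_along(frac)),
             n_de = n_de, fraction = frac, normalized = norm)
}
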