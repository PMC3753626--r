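new_distance_histogram <- function(d, binsize, range, datum = "TSS",
                                   query = "peak summit") {
  breaks <- seq(-range, range, by = binsize)
  if (breaks[length(breaks)] < range) breaks <- c(breaks, breaks[length(breaks)] + binsize)
  keep <- d >= breaks[1] & d <= breaks[length(breaks)]
  h <- hist(d[keep], breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 datum = datum, query = query, n_pairs = sum(keep)),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("distance_histogram: %s vs %s, %d pairs in [%d, %d], %d bins\n",
              x$query, x$datum, x$n_pairs, min(x$breaks), max(x$breaks),
              length(x$counts)))
  invisible(x)
}

#' Histogram of peak summit to TSS distances
#'
#' Signed distance (positive = upstream in the gene's orientation) from each
#' peak summit to the TSS of its chosen gene, binned over a symmetric range.
#' With an odds table the chosen gene is the argmax-odds candidate; without
#' one it is the nearest TSS. Pairs beyond the range are dropped (the counts
#' sum to the retained pairs).
#'
#' @param peaks data.frame of peaks (`chrom`, `summit`)
#' @param annotation a [genome_annotation()]
#' @param binsize bin width in bp (> 0)
#' @param range half-width of the histogram in bp
#' @param odds optional [odds_table()]
#' @return a `distance_histogram`
#' @export
peak_tss_histogram <- function(peaks, annotation, binsize = 500,
                               range = 10000, odds = NULL) {
  if (binsize <= 0) abort("binsize must be > 0", "peakodds_invalid_input")
  best <- classify_peaks(peaks, annotation, odds)
  new_distance_histogram(best$d, binsize, range)
}

#' Keep one occurrence per (gene, motif kind)
#'
#' For each gene and motif kind, the occurrence with the smallest corrected
#' p-value is kept; ties break to the 5'-most (smallest) position, so the
#' choice is deterministic across runs.
#'
#' @param occurrences data.frame with columns `gene_id`, `motif`, `pos`,
#'   `corrected_p`
#' @return data.table with one row per (gene, motif)
#' @export
select_best_motif_per_gene <- function(occurrences) {
  occ <- as.data.table(occurrences)
  if (nrow(occ) == 0L) return(occ)
  setorder(occ, gene_id, motif, corrected_p, pos)
  occ[!duplicated(occ[, .(gene_id, motif)])]
}

#' Histogram of distances between two motifs across genes
#'
#' For every gene carrying a selected occurrence of both motifs, the signed
#' start-to-start distance (query minus datum, in genome orientation of the
#' datum occurrence) is measured; pairs farther apart than `max_distance` are
#' excluded, and the rest binned symmetrically.
#'
#' @param selected output of [select_best_motif_per_gene()]
#' @param datum,query motif names
#' @param max_distance retain only |distance| <= this (bp)
#' @param binsize bin width in bp
#' @return a `distance_histogram`; empty (with a warning) when the motifs
#'   share no gene
#' @export
intermotif_distances <- function(selected, datum, query, max_distance = 500,
                                 binsize = 10) {
  sel <- as.data.table(selected)
  a <- sel[motif == datum, .(gene_id, datum_pos = pos)]
  b <- sel[motif == query, .(gene_id, query_pos = pos)]
  m <- merge(a, b, by = "gene_id")
  if (nrow(m) == 0L) {
    warning("no shared genes between '", datum, "' and '", query, "'")
    return(new_distance_histogram(numeric(0), binsize, max_distance,
                                  datum, query))
  }
  d <- m$query_pos - m$datum_pos
  d <- d[abs(d) <= max_distance]
  new_distance_histogram(d, binsize, max_distance, datum, query)
}

#' Chi-squared co-occurrence of two motifs across peaks
#'
#' 2x2 presence/absence contingency over peaks, Pearson chi-squared with 1 df
#' and (by default) no continuity correction; the direction is enriched when
#' joint presence exceeds its expectation under independence. A degenerate
#' margin (motif present in all peaks or none) yields chi2 = 0 and direction
#' "neither".
#'
#' @param presence logical matrix, peaks x motifs (column names = motif
#'   names), >= 2 rows
#' @param pair character vector of two motif names
#' @param yates apply the Yates continuity correction
#' @return list of class `cooccurrence_cell`: `pair`, `table` (2x2 counts),
#'   `chi2`, `direction`
#' @export
cooccurrence_chi2 <- function(presence, pair, yates = FALSE) {
  if (nrow(presence) < 2L) abort("need >= 2 peaks", "peakodds_invalid_input")
  x <- as.logical(presence[, pair[1]])
  y <- as.logical(presence[, pair[2]])
  tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                nrow = 2, dimnames = list(c("y", "!y"), c("x", "!x")))
  tab <- t(tab)
  N <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    return(structure(list(pair = pair, table = tab, chi2 = 0,
                          direction = "neither"),
                     class = "cooccurrence_cell"))
  E <- outer(rs, cs) / N
  dev <- abs(tab - E)
  if (yates) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / E)
  direction <- if (tab[1, 1] > E[1, 1]) "enriched"
               else if (tab[1, 1] < E[1, 1]) "depleted" else "neither"
  structure(list(pair = pair, table = tab, chi2 = chi2, direction = direction),
            class = "cooccurrence_cell")
}

#' @export
print.cooccurrence_cell <- function(x, ...) {
  cat(sprintf("cooccurrence %s ~ %s: chi2 = %.3f (%s)\n",
              x$pair[1], x$pair[2], x$chi2, x$direction))
  invisible(x)
}

#' All pairwise motif co-occurrence statistics
#'
#' @param presence logical matrix, peaks x motifs
#' @param yates apply the Yates continuity correction
#' @return data.table with one row per unordered motif pair: `motif_a`,
#'   `motif_b`, `chi2`, `direction`
#' @export
cooccurrence_matrix <- function(presence, yates = FALSE) {
  motifs <- colnames(presence)
  pairs <- utils::combn(motifs, 2, simplify = FALSE)
  rbindlist(lapply(pairs, function(p) {
    cell <- cooccurrence_chi2(presence, p, yates)
    data.table(motif_a = p[1], motif_b = p[2], chi2 = cell$chi2,
               direction = cell$direction)
  }))
}
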