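#' Construct a regulation-odds table
#'
#' Houses the learned model: per location category, the mean and standard
#' deviation of the regulation odds (frequency of the category among observed
#' peak summits divided by its frequency under random placement). `NA` marks
#' categories that could not be estimated (no mass in the null placements).
#'
#' @param df data.frame with columns `bin`, `context`, `mean_odds`, `sd_odds`
#'   (missing categories are filled with `NA`)
#' @return object of class `odds_table`: a data.table with one row per valid
#'   category, in canonical category order.
#' @export
odds_table <- function(df) {
  cats <- as.data.table(location_categories())
  df <- as.data.table(df)
  if (!all(c("bin", "context", "mean_odds") %in% names(df)))
    abort("odds table needs bin, context, mean_odds columns",
          "peakodds_invalid_odds")
  if (!"sd_odds" %in% names(df)) df[, sd_odds := NA_real_]
  bad <- !category_key(df$bin, df$context) %in% cats$key
  if (any(bad))
    abort(sprintf("invalid location category: %s",
                  category_key(df$bin, df$context)[bad][1]),
          "peakodds_invalid_odds")
  if (any(df$mean_odds < 0, na.rm = TRUE))
    abort("mean odds must be non-negative", "peakodds_invalid_odds")
  out <- merge(cats, df[, .(key = category_key(bin, context), mean_odds, sd_odds)],
               by = "key", all.x = TRUE, sort = FALSE)
  out <- out[match(cats$key, out$key)]
  structure(out[, .(bin, context, key, mean_odds, sd_odds)],
            class = c("odds_table", class(data.table())))
}

# named vector key -> mean odds (NA for unestimable categories)
odds_vector <- function(odds) {
  stopifnot(inherits(odds, "odds_table"))
  setNames(odds$mean_odds, odds$key)
}

#' @export
print.odds_table <- function(x, ...) {
  cat("Regulation odds by location category:\n")
  df <- as.data.frame(x)[, c("bin", "context", "mean_odds", "sd_odds")]
  df$mean_odds <- ifelse(is.na(df$mean_odds), "N/A", sprintf("%.2f", df$mean_odds))
  df$sd_odds <- ifelse(is.na(df$sd_odds), "N/A", sprintf("%.2f", df$sd_odds))
  print(df, row.names = FALSE)
  invisible(x)
}

# uniform null summits: one summit per requested peak, chromosome chosen with
# probability proportional to its (mappable) length, position uniform within.
sample_null_summits <- function(n, chromosomes, mask = NULL) {
  if (is.null(mask)) {
    chroms <- names(chromosomes)
    lens <- as.numeric(chromosomes)
    ci <- sample.int(length(chroms), n, replace = TRUE, prob = lens)
    data.table(chrom = chroms[ci],
               summit = as.integer(floor(runif(n) * lens[ci])))
  } else {
    m <- as.data.table(as.data.frame(mask))
    m <- m[, .(chrom = as.character(seqnames), start = start - 1L, end = end)]
    w <- m$end - m$start
    off <- cumsum(c(0, head(w, -1)))
    total <- sum(w)
    x <- floor(runif(n) * total)
    i <- findInterval(x, off)
    data.table(chrom = m$chrom[i],
               summit = as.integer(m$start[i] + (x - off[i])))
  }
}

# per-strand category frequencies of a best-candidate assignment
strand_category_freq <- function(best) {
  if (nrow(best) == 0L)
    return(data.table(gene_strand = character(), key = character(), freq = numeric()))
  counts <- best[, .(count = .N), by = .(gene_strand, key)]
  counts[, freq := count / sum(count), by = gene_strand]
  counts[, .(gene_strand, key, freq)]
}

#' Learn regulation odds from peak locations
#'
#' For each of the 16 location categories, the odds of regulation are the
#' frequency of the category among observed peak summits divided by its mean
#' frequency over `n_null_replicates` uniform random placements of equally
#' many summits, computed separately for genes on the + and - strands; the
#' reported mean and SD are taken across the two strand estimates.
#'
#' Classifying a summit requires choosing a candidate gene. By default
#' (`max_iter = 1`) summits — observed and null alike — are classified
#' against the nearest TSS, and the odds are learned in a single pass; the
#' learned odds then guide [assign_peaks()]. Setting `max_iter > 1` enables a
#' self-consistent refinement (alternate learn/assign with the current odds
#' until the table changes by less than `tol` per category), but note this
#' feedback is winner-take-all when the true odds landscape is flat: the
#' category whose estimate is highest by sampling noise captures every summit
#' that has any candidate in it, so calibration under the null is lost (see
#' the methods vignette).
#'
#' @param peaks data.frame of peaks (`chrom`, `summit` required)
#' @param annotation a [genome_annotation()]
#' @param n_null_replicates number of random-placement replicates (>= 1)
#' @param seed integer seed for the null placements
#' @param mask optional mappability mask (`GRanges`); when given, null summits
#'   are drawn from the mappable space only
#' @param max_iter,tol iteration controls for the learn/assign refinement
#' @return an [odds_table()] with attributes `iterations` and `converged`
#' @export
learn_odds <- function(peaks, annotation, n_null_replicates = 10, seed = 1,
                       mask = NULL, max_iter = 1, tol = 1e-3) {
  peaks <- as.data.table(peaks)
  if (nrow(peaks) == 0L) abort("no peaks", "peakodds_invalid_input")
  if (n_null_replicates < 1) abort("n_null_replicates must be >= 1",
                                   "peakodds_invalid_input")
  if (!all(peaks$chrom %in% names(annotation$chromosomes)))
    abort("peak chromosome absent from annotation", "peakodds_unknown_chromosome")

  obs_cand <- candidate_table(peaks, annotation)
  null_summits <- with_fixed_seed(seed, {
    rbindlist(lapply(seq_len(n_null_replicates), function(r) {
      s <- sample_null_summits(nrow(peaks), annotation$chromosomes, mask)
      s[, rep_id := r]
      s
    }))
  })
  null_cand <- candidate_table(null_summits, annotation)
  null_rep <- null_summits$rep_id  # indexed by sid

  cats <- location_categories()$key
  odds <- NULL
  prev <- rep(0, length(cats))
  iterations <- 0L
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    iterations <- it
    obs_best <- best_candidates(obs_cand, odds)
    null_best <- best_candidates(null_cand, odds)
    obs_freq <- strand_category_freq(obs_best)

    null_best[, rep_id := null_rep[sid]]
    nf <- null_best[, .(count = .N), by = .(rep_id, gene_strand, key)]
    nf[, freq := count / sum(count), by = .(rep_id, gene_strand)]
    # mean per-replicate frequency; replicates without the category count as 0
    null_freq <- nf[, .(freq = sum(freq) / n_null_replicates),
                    by = .(gene_strand, key)]

    grid <- data.table(expand.grid(gene_strand = c("+", "-"), key = cats,
                                   stringsAsFactors = FALSE))
    grid <- merge(grid, obs_freq, by = c("gene_strand", "key"), all.x = TRUE)
    setnames(grid, "freq", "obs")
    grid <- merge(grid, null_freq, by = c("gene_strand", "key"), all.x = TRUE)
    setnames(grid, "freq", "null")
    grid[is.na(obs), obs := 0]
    grid[, odds := ifelse(is.na(null) | null == 0, NA_real_, obs / null)]

    est <- grid[, .(mean_odds = if (all(is.na(odds))) NA_real_
                                else mean(odds, na.rm = TRUE),
                    sd_odds = if (sum(!is.na(odds)) < 2) {
                      if (all(is.na(odds))) NA_real_ else 0
                    } else sd(odds, na.rm = TRUE)),
                by = key]
    all_cats <- data.table(k = cats)
    setnames(all_cats, "k", "key")
    est <- merge(all_cats, est, by = "key", sort = FALSE)
    kp <- strsplit(est$key, "|", fixed = TRUE)
    est[, `:=`(bin = vapply(kp, `[`, "", 1L), context = vapply(kp, `[`, "", 2L))]
    odds_new <- odds_table(est[, .(bin, context, mean_odds, sd_odds)])

    cur <- odds_vector(odds_new)[cats]
    cur[is.na(cur)] <- 0
    if (max(abs(cur - prev)) < tol) {
      odds <- odds_new
      converged <- TRUE
      break
    }
    prev <- cur
    odds <- odds_new
  }
  attr(odds, "iterations") <- iterations
  attr(odds, "converged") <- if (max_iter == 1L) NA else converged
  odds
}

#' Assign peaks to their most likely regulated genes
#'
#' Among all candidate (gene, TSS) pairs on the peak's chromosome (no distance
#' cutoff), each peak is assigned to the gene whose location category has the
#' maximal mean odds; ties break by smaller |distance|, then lexicographic
#' gene id. Unestimable (`NA`) categories are treated as odds 0. The per-peak
#' probability of regulation is `odds / (odds + 1)`.
#'
#' @param peaks data.frame of peaks (`chrom`, `summit`; other columns carried
#'   through)
#' @param annotation a [genome_annotation()]
#' @param odds an [odds_table()] with at least one estimable category
#' @return data.table with one row per input peak: `peak_id` (input row
#'   number), chosen `gene_id` (`NA` when no gene exists on the peak's
#'   chromosome), `bin`, `context`, `key`, `tss`, `distance`, `odds`,
#'   `probability`, plus the peak's own columns.
#' @export
assign_peaks <- function(peaks, annotation, odds) {
  stopifnot(inherits(odds, "odds_table"))
  if (all(is.na(odds$mean_odds)))
    abort("odds table has no estimable category", "peakodds_invalid_odds")
  peaks <- as.data.table(peaks)
  best <- best_candidates(candidate_table(peaks, annotation), odds)
  out <- data.table(peak_id = seq_len(nrow(peaks)))
  out <- cbind(out, peaks)
  keep <- best[, .(peak_id = sid, gene_id, bin, context, key, tss,
                   distance = d, odds, gene_strand)]
  out <- merge(out, keep, by = "peak_id", all.x = TRUE, sort = TRUE)
  out[, probability := odds / (odds + 1)]
  out[]
}

#' @rdname assign_peaks
#' @param peak a single-row data.frame (or list) with `chrom` and `summit`
#' @return `assign_peak()`: a list of class `peak_assignment` (fields `gene_id`,
#'   `category`, `odds`, `probability`, `distance`, `tss`), or an unassigned
#'   marker (`gene_id = NA`) when the chromosome has no genes.
#' @export
assign_peak <- function(peak, annotation, odds) {
  row <- assign_peaks(as.data.frame(peak), annotation, odds)
  structure(list(gene_id = row$gene_id,
                 category = list(bin = row$bin, context = row$context),
                 key = row$key, tss = row$tss, distance = row$distance,
                 odds = row$odds, probability = row$probability),
            class = "peak_assignment")
}

#' Combine per-peak probabilities into gene scores
#'
#' Per gene, the contributions of all peaks assigned to it are combined:
#' `noisy_or` (default) scores `1 - prod(1 - p_i)`, treating each binding site
#' as an independent chance of regulation, so a gene regulated by several weak
#' sites can still rank highly; `product` multiplies the probabilities
#' literally; `log_sum` sums `log(odds_i)`.
#'
#' @param assignments output of [assign_peaks()]
#' @param mode combination rule
#' @return data.table (`gene_id`, `score`, `n_peaks`, `peak_ids`), ranked by
#'   decreasing score; empty input gives an empty table.
#' @export
score_genes <- function(assignments, mode = c("noisy_or", "product", "log_sum")) {
  mode <- match.arg(mode)
  a <- as.data.table(assignments)
  a <- a[!is.na(gene_id)]
  if (nrow(a) == 0L)
    return(data.table(gene_id = character(), score = numeric(),
                      n_peaks = integer(), peak_ids = character()))
  if (any(a$probability < 0 | a$probability > 1, na.rm = TRUE))
    abort("assignment probabilities must lie in [0, 1]", "peakodds_invalid_input")
  out <- a[, .(score = switch(mode,
                              noisy_or = 1 - prod(1 - probability),
                              product = prod(probability),
                              log_sum = sum(log(odds))),
               n_peaks = .N,
               peak_ids = paste(peak_id, collapse = ",")),
           by = gene_id]
  setorder(out, -score, gene_id)
  out[]
}

#' Traditional promoter-window gene assignment
#'
#' The conventional comparison method: each peak is assigned to the gene with
#' the nearest TSS within `window` bp of its summit (peaks farther from every
#' TSS are dropped); exact distance ties break lexicographically by gene id.
#' Per-gene score is the sum of the MACS significance scores (log-scale) of
#' its peaks.
#'
#' @param peaks data.frame of peaks (`chrom`, `summit`, `score`)
#' @param annotation a [genome_annotation()]
#' @param window half-width of the promoter window in bp (> 0)
#' @return data.table (`gene_id`, `score`, `n_peaks`), ranked by decreasing
#'   score.
#' @export
traditional_assign <- function(peaks, annotation, window = 2000) {
  if (window <= 0) abort("window must be > 0", "peakodds_invalid_input")
  peaks <- as.data.table(peaks)
  if (!"score" %in% names(peaks)) peaks[, score := 0]
  cand <- candidate_table(peaks, annotation)
  if (nrow(cand) == 0L)
    return(data.table(gene_id = character(), score = numeric(),
                      n_peaks = integer()))
  cand[, absd := abs(d)]
  cand <- cand[absd <= window]
  if (nrow(cand) == 0L)
    return(data.table(gene_id = character(), score = numeric(),
                      n_peaks = integer()))
  setorder(cand, sid, absd, gene_id, transcript_id)
  best <- cand[!duplicated(sid)]
  best[, score := peaks$score[sid]]
  out <- best[, .(score = sum(score), n_peaks = .N), by = gene_id]
  setorder(out, -score, gene_id)
  out[]
}

#' Overlap between the top of two ranked gene lists
#'
#' @param list_a,list_b ranked gene lists: character vectors or data.frames
#'   with a `gene_id` column (already ordered best-first)
#' @param top_n number of top genes to compare; if it exceeds a list's
#'   length, that full list is used (with a warning) but the denominator
#'   stays `top_n`
#' @return `|top_n(A) intersect top_n(B)| / top_n`
#' @export
compare_assignments <- function(list_a, list_b, top_n) {
  ga <- if (is.data.frame(list_a)) list_a$gene_id else list_a
  gb <- if (is.data.frame(list_b)) list_b$gene_id else list_b
  if (top_n < 1) abort("top_n must be >= 1", "peakodds_invalid_input")
  if (top_n > length(ga) || top_n > length(gb))
    warning("top_n exceeds list length; using the full shorter list")
  length(intersect(head(ga, top_n), head(gb, top_n))) / top_n
}
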