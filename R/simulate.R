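#' Specification for a synthetic fixture dataset
#'
#' Deterministic generator settings for toy genomes, annotations, peaks and
#' planted motifs with known structure. The same spec and seed always produce
#' byte-identical outputs. Defaults give a 5 Mb genome (2 chromosomes), 100
#' multi-exon genes and 2000 peaks — large enough for stable category
#' frequencies, small enough for seconds-scale tests.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length length of each chromosome (bp)
#' @param n_genes total number of genes (split evenly across chromosomes)
#' @param gene_length_range min/max gene length (bp); the 4-12 kb default
#'   keeps every location category either well-populated or structurally
#'   impossible (categories needing > 25 kb intragenic distance cannot occur)
#' @param n_exons_range min/max exons per transcript
#' @param first_exon_range min/max length of the 5'-most exon (bp)
#' @param min_first_intron minimum length of the first intron (bp); together
#'   with `first_exon_range` this populates both the proximal-downstream exon
#'   and intron categories
#' @param desert_fraction fraction of each chromosome kept gene-free at its
#'   centre, giving the distal (25 kb - 1 Mb) categories stable mass; the four
#'   desert-edge genes get fixed strands (+ on odd chromosomes, - on even)
#'   so both strand estimates see the distal categories
#' @param second_transcript_prob probability a gene gets a second transcript
#'   with a shifted TSS
#' @param composition named A/C/G/T background base frequencies
#' @param n_peaks number of peaks to plant
#' @param peak_length_range min/max peak length (bp)
#' @param category_factors named numeric vector (names = category keys from
#'   [location_categories()]): planted enrichment factor per category;
#'   unlisted categories default to 1 (uniform)
#' @param datum_motif consensus of the primary (datum) motif planted at every
#'   peak summit
#' @param pwm_strength consensus-base probability of the planted motifs
#' @param query_motifs named list; each element is
#'   `list(consensus =, offsets =)` where `offsets` is a named numeric vector
#'   mapping a signed offset (bp, relative to the summit) to the probability
#'   of planting the query motif there
#' @param feature_coverage fraction of each chromosome covered by the
#'   synthetic feature track
#' @param mask_gap_fraction fraction of each chromosome removed from the
#'   mappability mask
#' @param seed master seed; sub-steps derive fixed offsets from it
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(n_chromosomes = 2, chrom_length = 2.5e6,
                         n_genes = 400, gene_length_range = c(4000, 12000),
                         n_exons_range = c(2, 4),
                         first_exon_range = c(800, 1200),
                         min_first_intron = 2000,
                         desert_fraction = 0.3,
                         second_transcript_prob = 0.3,
                         composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         n_peaks = 2000, peak_length_range = c(200, 400),
                         category_factors = numeric(),
                         datum_motif = "TGGGACTTTCCA",
                         pwm_strength = 0.97,
                         query_motifs = list(),
                         feature_coverage = 0.1, mask_gap_fraction = 0.1,
                         seed = 42) {
  if (any(category_factors < 0)) abort("factors must be >= 0",
                                       "peakodds_invalid_input")
  bad <- setdiff(names(category_factors), location_categories()$key)
  if (length(bad)) abort(paste0("unknown category: ", bad[1]),
                         "peakodds_invalid_input")
  if (feature_coverage < 0 || feature_coverage > 1 ||
      mask_gap_fraction < 0 || mask_gap_fraction > 1)
    abort("coverage fractions must lie in [0, 1]", "peakodds_invalid_input")
  structure(as.list(environment()), class = "fixture_spec")
}

# uniform non-overlapping placement of intervals with given lengths in
# [0, total): the spacings construction (sorted uniform starts in the slack,
# shifted by cumulative lengths). Errors when the intervals cannot fit.
pack_intervals <- function(lengths, total) {
  k <- length(lengths)
  if (k == 0L) return(integer(0))
  slack <- total - sum(lengths)
  if (slack < 0) abort("intervals cannot be packed into the available space",
                       "peakodds_packing_failure")
  sort(floor(runif(k) * (slack + 1))) + cumsum(c(0, head(lengths, -1)))
}

# exon structure in transcript-local 5'->3' coordinates [0, len): a defined
# first exon, a first intron of at least min_intron, then alternating
# exon/intron segments with the last exon ending at len. Falls back to a
# single exon when the transcript is too short. Returns [start, end) rows.
make_exon_layout <- function(len, n_exons, first_exon_range, min_intron) {
  L1 <- round(runif(1, first_exon_range[1], first_exon_range[2]))
  if (len < L1 + min_intron + 2L * n_exons + 200L || n_exons == 1L)
    return(data.table(start = 0L, end = as.integer(len)))
  lo <- L1 + min_intron
  n_cuts <- 2L * (n_exons - 1L) - 1L
  cuts <- sort(sample(seq.int(lo, len - 1L), n_cuts))
  es <- c(0L, cuts[seq(1, n_cuts, by = 2)])
  ee <- c(L1, if (n_cuts > 1L) cuts[seq(2, n_cuts, by = 2)], as.integer(len))
  data.table(start = as.integer(es), end = as.integer(ee))
}

# mirror transcript-local exon rows onto the genome for a given strand
place_exons <- function(layout, t_start, t_end, strand) {
  if (strand == "+")
    data.table(start = t_start + layout$start, end = t_start + layout$end)
  else
    data.table(start = t_end - layout$end, end = t_end - layout$start)
}

#' Generate a synthetic genome and annotation
#'
#' I.i.d. background sequence at the spec's base composition; multi-exon
#' genes placed without overlap (uniformly over admissible configurations);
#' some genes carry a second transcript with a downstream-shifted TSS so that
#' multi-TSS handling is exercised.
#'
#' @param spec a [fixture_spec()]
#' @return list: `genome` (`DNAStringSet`), `annotation`
#'   ([genome_annotation()])
#' @export
make_genome <- function(spec) {
  with_fixed_seed(spec$seed, {
    chroms <- setNames(rep(spec$chrom_length, spec$n_chromosomes),
                       paste0("chr", seq_len(spec$n_chromosomes)))
    seqs <- Biostrings::DNAStringSet(vapply(names(chroms), function(ch)
      paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE,
                   prob = spec$composition), collapse = ""), ""))
    names(seqs) <- names(chroms)

    genes <- transcripts <- exons <- list()
    per_chrom <- diff(round(seq(0, spec$n_genes,
                                length.out = spec$n_chromosomes + 1)))
    gi <- 0L
    for (ci in seq_along(chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      lens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]),
                     ng, replace = TRUE)
      # genes live in two clusters flanking a central gene-free desert
      desert <- round(spec$chrom_length * spec$desert_fraction)
      half_len <- (spec$chrom_length - desert) %/% 2L
      n_left <- ng %/% 2L
      starts <- c(pack_intervals(lens[seq_len(n_left)], half_len),
                  if (ng > n_left)
                    half_len + desert +
                      pack_intervals(lens[(n_left + 1L):ng],
                                     spec$chrom_length - half_len - desert))
      strands <- sample(c("+", "-"), ng, replace = TRUE)
      # fix the strands of the two desert-edge genes: with both "+" (odd
      # chromosomes) the desert is downstream-outside of the left edge gene
      # and upstream of the right edge gene; with both "-" (even chromosomes)
      # the same two roles fall to the - strand, so both strand estimates see
      # the distal categories
      edge_strand <- if (ci %% 2L == 1L) "+" else "-"
      if (n_left >= 1L) strands[n_left] <- edge_strand
      if (ng > n_left) strands[n_left + 1L] <- edge_strand
      for (g in seq_len(ng)) {
        gi <- gi + 1L
        gid <- sprintf("G%04d", gi)
        strand <- strands[g]
        g_start <- as.integer(starts[g]); g_end <- as.integer(starts[g] + lens[g])
        genes[[gi]] <- data.table(gene_id = gid, chrom = names(chroms)[ci],
                                  strand = strand)
        tx_bounds <- list(c(g_start, g_end))
        if (runif(1) < spec$second_transcript_prob) {
          shift <- as.integer(round(lens[g] * runif(1, 0.1, 0.4)))
          tx_bounds[[2]] <- if (strand == "+") c(g_start + shift, g_end)
                            else c(g_start, g_end - shift)
        }
        for (t in seq_along(tx_bounds)) {
          tid <- sprintf("%s.T%d", gid, t)
          ts <- tx_bounds[[t]][1]; te <- tx_bounds[[t]][2]
          transcripts[[length(transcripts) + 1L]] <-
            data.table(gene_id = gid, transcript_id = tid, start = ts, end = te)
          k <- sample(seq(spec$n_exons_range[1], spec$n_exons_range[2]), 1)
          layout <- make_exon_layout(te - ts, k, spec$first_exon_range,
                                     spec$min_first_intron)
          ex <- place_exons(layout, ts, te, strand)
          ex[, transcript_id := tid]
          exons[[length(exons) + 1L]] <- ex[, .(transcript_id, start, end)]
        }
      }
    }
    ann <- genome_annotation(
      chroms,
      if (length(genes)) rbindlist(genes) else
        data.frame(gene_id = character(), chrom = character(), strand = character()),
      if (length(transcripts)) rbindlist(transcripts) else
        data.frame(gene_id = character(), transcript_id = character(),
                   start = integer(), end = integer()),
      if (length(exons)) rbindlist(exons) else NULL)
    list(genome = seqs, annotation = ann)
  })
}

#' Plant peaks with per-category enrichment
#'
#' Summits are drawn from a mixture: with probability `factor_c * q_c`
#' (where `q_c` is the category's share of the genome under uniform
#' placement, estimated from uniform probe positions classified against the
#' nearest TSS) a summit is placed uniformly within category `c`'s territory;
#' the remaining mass is spread uniformly over the rest of the genome. The
#' observed summit frequency in an enriched category is therefore exactly
#' `factor_c` times its null frequency — the planting oracle the recovery
#' tests use. True category labels are recorded per peak.
#'
#' @param spec a [fixture_spec()]
#' @param annotation a [genome_annotation()]
#' @param n_peaks override the spec's peak count
#' @param n_probes uniform probe positions used to estimate the category
#'   territories
#' @return list: `peaks` (data.table: `chrom`, `start`, `end`, `summit`,
#'   `score`), `truth` (data.table: `peak_id`, `gene_id`, `key`, `distance`)
#' @export
plant_peaks <- function(spec, annotation, n_peaks = spec$n_peaks,
                        n_probes = 50000) {
  chroms <- annotation$chromosomes
  if (n_peaks == 0L) {
    truth <- data.table(peak_id = integer(), gene_id = character(),
                        distance = integer())
    truth[, key := character(0)]
    return(list(peaks = data.table(chrom = character(), start = integer(),
                                   end = integer(), summit = integer(),
                                   score = numeric()),
                truth = truth[, .(peak_id, gene_id, key, distance)]))
  }
  with_fixed_seed(spec$seed + 1L, {
    n_probes <- max(n_probes, 25L * n_peaks)
    probes <- sample_null_summits(n_probes, chroms)
    probes[, `:=`(key = NA_character_, gene_id = NA_character_,
                  distance = NA_integer_)]
    if (nrow(annotation$genes)) {
      cls <- classify_peaks(probes, annotation)
      probes[cls$sid, `:=`(key = cls$key, gene_id = cls$gene_id,
                           distance = cls$d)]
    } else if (length(spec$category_factors)) {
      abort("category factors need an annotation with genes",
            "peakodds_invalid_input")
    }
    fac <- spec$category_factors
    q_spec <- vapply(names(fac), function(k) mean(probes$key %in% k), 0)
    p_spec <- fac * q_spec
    if (sum(p_spec) > 1)
      abort("requested enrichment factors are infeasible (mass > 1)",
            "peakodds_invalid_input")
    u <- runif(n_peaks)
    cum <- cumsum(p_spec)
    pick <- findInterval(u, c(0, cum), left.open = TRUE)
    pick[u >= sum(p_spec)] <- 0L  # remainder component
    draw_from <- function(pool_idx, m) {
      if (length(pool_idx) == 0L)
        abort("a requested category has no territory in this genome",
              "peakodds_invalid_input")
      pool_idx[sample.int(length(pool_idx), m, replace = m > length(pool_idx))]
    }
    rows <- integer(n_peaks)
    rest_pool <- which(!probes$key %in% names(fac))
    for (ci in seq_along(fac)) {
      sel <- pick == ci
      if (any(sel))
        rows[sel] <- draw_from(which(probes$key %in% names(fac)[ci]), sum(sel))
    }
    if (any(pick == 0L))
      rows[pick == 0L] <- draw_from(rest_pool, sum(pick == 0L))
    out <- probes[rows]
    lens <- sample(seq(spec$peak_length_range[1], spec$peak_length_range[2]),
                   n_peaks, replace = TRUE)
    offs <- floor(runif(n_peaks) * lens)
    out[, start := pmax(0L, as.integer(summit - offs))]
    out[, end := pmin(as.integer(chroms[chrom]), as.integer(start + lens))]
    out[, end := pmax(end, summit + 1L)]
    out[, score := round(rgamma(n_peaks, shape = 2, scale = 60), 2)]
    out[, peak_id := seq_len(n_peaks)]
    list(peaks = out[, .(chrom, start, end, summit, score)],
         truth = out[, .(peak_id, gene_id, key, distance)])
  })
}

#' Plant motif sites into a genome at peak summits
#'
#' Writes the datum-motif consensus at every peak summit and, per query
#' motif, a consensus copy at a configured signed offset from the summit with
#' the configured probability (at most one offset per peak is chosen). Sites
#' falling outside chromosome bounds or overlapping an earlier planted site
#' are skipped; the truth table records what was actually written.
#'
#' @param spec a [fixture_spec()]
#' @param genome `DNAStringSet` to edit
#' @param peaks data.table of peaks (`chrom`, `summit`)
#' @return list: `genome` (edited copy), `truth` (data.table: `peak_id`,
#'   `motif`, `pos` = 0-based start of the planted site)
#' @export
plant_motifs <- function(spec, genome, peaks) {
  peaks <- as.data.table(peaks)
  with_fixed_seed(spec$seed + 2L, {
    sites <- list(data.table(peak_id = seq_len(nrow(peaks)),
                             motif = "datum", consensus = spec$datum_motif,
                             chrom = peaks$chrom, pos = peaks$summit))
    for (qn in names(spec$query_motifs)) {
      q <- spec$query_motifs[[qn]]
      offs <- q$offsets
      if (sum(offs) > 1 + 1e-9)
        abort("offset probabilities must sum to <= 1", "peakodds_invalid_input")
      u <- runif(nrow(peaks))
      cum <- cumsum(offs)
      pick <- findInterval(u, c(0, cum), left.open = TRUE)
      chosen <- pick >= 1 & pick <= length(offs) & u < cum[length(cum)]
      if (any(chosen)) {
        oi <- pick[chosen]
        sites[[length(sites) + 1L]] <-
          data.table(peak_id = which(chosen), motif = qn,
                     consensus = q$consensus, chrom = peaks$chrom[chosen],
                     pos = peaks$summit[chosen] +
                       as.integer(names(offs))[oi])
      }
    }
    all_sites <- rbindlist(sites)
    all_sites[, width := nchar(consensus)]
    lens <- setNames(Biostrings::width(genome), names(genome))
    all_sites <- all_sites[pos >= 0 & pos + width <= lens[chrom]]
    # drop sites overlapping an earlier one (datum first, file order within)
    setorder(all_sites, chrom, pos)
    keep <- all_sites[, {
      ok <- logical(.N); last_end <- -1L
      for (i in seq_len(.N)) {
        if (pos[i] >= last_end) { ok[i] <- TRUE; last_end <- pos[i] + width[i] }
      }
      ok
    }, by = chrom]$V1
    all_sites <- all_sites[keep]
    edited <- genome
    for (ch in unique(all_sites$chrom)) {
      s <- all_sites[chrom == ch]
      edited[[ch]] <- Biostrings::replaceAt(
        edited[[ch]], IRanges::IRanges(s$pos + 1L, s$pos + s$width),
        Biostrings::DNAStringSet(s$consensus))
    }
    list(genome = edited,
         truth = all_sites[, .(peak_id, motif, pos)])
  })
}

#' Synthetic feature track and mappability mask
#'
#' `make_feature_track` covers roughly the requested fraction of each
#' chromosome with disjoint intervals; `make_mask` removes gap intervals
#' totalling the requested fraction.
#'
#' @param spec a [fixture_spec()]
#' @param chromosomes named chromosome lengths
#' @param n_intervals intervals per chromosome
#' @return `GRanges`
#' @export
make_feature_track <- function(spec, chromosomes, n_intervals = 50) {
  with_fixed_seed(spec$seed + 3L, {
    grs <- lapply(names(chromosomes), function(ch) {
      len <- chromosomes[[ch]]
      ivl <- max(1L, as.integer(round(len * spec$feature_coverage / n_intervals)))
      starts <- pack_intervals(rep(ivl, n_intervals), len)
      GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1L, starts + ivl),
                             seqlengths = chromosomes)
    })
    GenomicRanges::sort(do.call(c, grs))
  })
}

#' @rdname make_feature_track
#' @export
make_mask <- function(spec, chromosomes, n_intervals = 20) {
  with_fixed_seed(spec$seed + 4L, {
    grs <- lapply(names(chromosomes), function(ch) {
      len <- chromosomes[[ch]]
      whole <- GenomicRanges::GRanges(ch, IRanges::IRanges(1L, len),
                                      seqlengths = chromosomes)
      if (spec$mask_gap_fraction == 0) return(whole)
      ivl <- max(1L, as.integer(round(len * spec$mask_gap_fraction / n_intervals)))
      starts <- pack_intervals(rep(ivl, n_intervals), len)
      gaps <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1L, starts + ivl),
                                     seqlengths = chromosomes)
      GenomicRanges::setdiff(whole, gaps)
    })
    GenomicRanges::sort(do.call(c, grs))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Produces FASTA, GTF, a MACS-dialect peak file, feature and mask BED files
#' and truth TSVs; repeated runs with the same spec are byte-identical.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory (created)
#' @return invisible named list of output paths
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- make_genome(spec)
  pk <- plant_peaks(spec, g$annotation)
  pm <- plant_motifs(spec, g$genome, pk$peaks)
  feat <- make_feature_track(spec, g$annotation$chromosomes)
  mask <- make_mask(spec, g$annotation$chromosomes)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                peaks = file.path(dir, "peaks.xls"),
                features = file.path(dir, "features.bed"),
                mask = file.path(dir, "mask.bed"),
                truth_peaks = file.path(dir, "truth_peaks.tsv"),
                truth_motifs = file.path(dir, "truth_motifs.tsv"))
  Biostrings::writeXStringSet(pm$genome, paths$fasta)
  write_gtf(g$annotation, paths$gtf)
  write_peaks_macs(pk$peaks, paths$peaks,
                   comments = sprintf("synthetic fixture seed=%d", spec$seed))
  rtracklayer::export(feat, paths$features, format = "BED")
  rtracklayer::export(mask, paths$mask, format = "BED")
  fwrite(pk$truth, paths$truth_peaks, sep = "\t")
  fwrite(pm$truth, paths$truth_motifs, sep = "\t")
  invisible(paths)
}
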