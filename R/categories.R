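# Location categories: each peak summit, relative to a candidate (gene, TSS)
# pair, falls into one of 16 categories combining a signed distance bin with a
# gene-structure context. Positive distances are upstream of the TSS in the
# gene's transcription orientation; negative distances are downstream, and are
# subdivided by whether the summit lies in an exon, an intron, or beyond the
# transcript end.

UPSTREAM_BINS   <- c("0-2k", "2k-25k", "25k-1Mb", ">1Mb")
DOWNSTREAM_BINS <- c("-2k-0", "-25k--2k", "-1Mb--25k", "<-1Mb")
BIN_BREAKS      <- c(0, 2000, 25000, 1e6)
DOWNSTREAM_CONTEXTS <- c("intron", "exon", "downstream_outside_transcript")
ALL_CONTEXTS <- c("upstream", DOWNSTREAM_CONTEXTS)

#' The 16 valid location categories
#'
#' Peak summit positions relative to a TSS are classified by a signed distance
#' bin (four upstream, four downstream, boundaries at 2 kb, 25 kb and 1 Mb;
#' distance 0 belongs to the 0-2k upstream bin) crossed with a structural
#' context. Upstream positions have a single context; downstream positions are
#' exonic, intronic, or outside the transcript, giving 4 + 4 x 3 = 16
#' categories.
#'
#' @return data.frame with columns `bin`, `context` and `key` (the
#'   `"bin|context"` string used throughout the package), one row per category.
#' @export
location_categories <- function() {
  up <- data.frame(bin = UPSTREAM_BINS, context = "upstream",
                   stringsAsFactors = FALSE)
  down <- expand.grid(bin = DOWNSTREAM_BINS, context = DOWNSTREAM_CONTEXTS,
                      stringsAsFactors = FALSE)
  out <- rbind(up, down[order(down$bin), ])
  out$key <- category_key(out$bin, out$context)
  rownames(out) <- NULL
  out
}

#' Distance bin for a signed TSS distance
#'
#' Bins are half-open on the absolute distance: `[0, 2k)`, `[2k, 25k)`,
#' `[25k, 1Mb)`, `[1Mb, Inf)`. Distance 0 is assigned to the upstream 0-2k bin
#' by convention.
#'
#' @param d signed distance(s) in bp (positive = upstream)
#' @return character vector of bin labels
#' @export
distance_bin <- function(d) {
  i <- findInterval(abs(d), BIN_BREAKS)
  ifelse(d >= 0, UPSTREAM_BINS[i], DOWNSTREAM_BINS[i])
}

#' @rdname location_categories
#' @param bin distance bin label(s)
#' @param context context label(s)
#' @export
category_key <- function(bin, context) paste(bin, context, sep = "|")
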