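#' @importFrom data.table data.table as.data.table setkey setkeyv setnames setorder := .N .SD .I rbindlist fread fwrite copy
#' @importFrom stats phyper sd runif rgamma setNames
#' @importFrom graphics hist
#' @importFrom utils head tail packageVersion write.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "bin", "context", "key", "d", "pos", "pos2", "tss", "t_start", "t_end",
  "gene_id", "transcript_id", "strand", "sid", "odds", "mean_odds", "sd_odds",
  "category", "score", "probability", "peak_id", "chrom", "start", "end",
  "summit", "motif", "corrected_p", "n_peaks", "inside", "exonic", "absd",
  "row_id", "best", "gene_strand", "freq", "count", "total", "rep_id",
  "start0", "seqnames", "type", "width", "offset", "m_start", "m_end", "m_off",
  "q_start", "q_end", "x.start", "i.start", "grp", "raw_p", "n_tests",
  "best_pos", "best_score", "tile_start", "tile_end", "datum_pos", "query_pos",
  "obs", "null", "est", "V1", "consensus", "peaks", "tf", "null_freq"
))

abort <- function(msg, class) {
  stop(structure(class = c(class, "peakodds_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

#' Evaluate an expression with a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] used by every stochastic operation so
#' that identical seeds give bit-identical results.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_fixed_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
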