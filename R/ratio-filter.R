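# Threshold filtration of scored reads and the four-category summary
# (counts, percentages, ratio histogram).

#' Filter configuration
#'
#' The default threshold of 0.8 is deliberately conservative: the two
#' libraries are non-exhaustive, so only reads clearly of non-insect origin
#' should be removed. The comparison is inclusive (>= 0.8) by default;
#' `inclusive = FALSE` gives the strict (> threshold) variant.
#'
#' @param threshold positive ratio threshold (default 0.8).
#' @param inclusive logical; keep reads exactly at the threshold
#'   (default TRUE).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(threshold = 0.8, inclusive = TRUE) {
  stopifnot(is.numeric(threshold), threshold > 0, is.logical(inclusive))
  structure(list(threshold = threshold, inclusive = inclusive),
            class = "filter_config")
}

kept_mask <- function(scored, config) {
  cat_ <- as.character(scored$category)
  pass <- if (config$inclusive) scored$ratio >= config$threshold
          else scored$ratio > config$threshold
  cat_ == "I_ONLY" | (!is.na(scored$ratio) & pass)
}

#' Split scored reads into kept and discarded sets
#'
#' A read is kept iff it hit only the Insecta library (I_ONLY: no
#' denominator exists and the read cannot be of clearly non-insect origin),
#' or its ratio passes the threshold. Reads with no Insecta hit (NO_I) are
#' always discarded. The two sets partition the input.
#'
#' @param scored a `scored_reads` data.frame.
#' @param config a [filter_config()].
#' @return list with character vectors `kept` and `discarded` of read ids.
#' @export
filter_reads <- function(scored, config = filter_config()) {
  stopifnot(nrow(scored) > 0L)
  keep <- kept_mask(scored, config)
  list(kept = scored$read_id[keep], discarded = scored$read_id[!keep])
}

#' Summarize filtration into the four-category counts and percentages
#'
#' Counts: `n_kept` (passing reads incl. I_ONLY), `n_below` (reads with a
#' defined ratio failing the threshold), `n_no_insecta` (reads without an
#' Insecta hit). Percentages are 100 * count / n_total; `print` displays
#' them at two decimals.
#'
#' @param scored a `scored_reads` data.frame.
#' @param config a [filter_config()].
#' @return an object of class `filter_summary`.
#' @export
summarize_filter <- function(scored, config = filter_config()) {
  stopifnot(nrow(scored) > 0L)
  keep <- kept_mask(scored, config)
  no_i <- as.character(scored$category) == "NO_I"
  n_total <- nrow(scored)
  n_kept <- sum(keep)
  n_no_insecta <- sum(no_i & !keep)
  n_below <- n_total - n_kept - n_no_insecta
  structure(list(n_total = n_total, n_kept = n_kept, n_below = n_below,
                 n_no_insecta = n_no_insecta,
                 pct_kept = 100 * n_kept / n_total,
                 pct_below = 100 * n_below / n_total,
                 pct_no_insecta = 100 * n_no_insecta / n_total,
                 threshold = config$threshold,
                 inclusive = config$inclusive),
            class = "filter_summary")
}

#' Build a filter summary directly from category counts
#'
#' Convenience for recomputing percentages from printed counts (e.g. a
#' figure caption): expands the counts into a minimal scored-read table and
#' summarizes it, so percentages always come from the same code path.
#'
#' @param n_kept,n_below,n_no_insecta category counts.
#' @param config a [filter_config()].
#' @return a `filter_summary`.
#' @export
summary_from_counts <- function(n_kept, n_below, n_no_insecta,
                                config = filter_config()) {
  eps <- min(config$threshold / 2, 0.5)
  scored <- scored_reads(
    read_id = sprintf("r%d", seq_len(n_kept + n_below + n_no_insecta)),
    s_insecta = c(rep(100, n_kept), rep(100 * eps, n_below),
                  rep(NA_real_, n_no_insecta)),
    s_non_insecta = c(rep(NA_real_, n_kept), rep(100, n_below),
                      rep(100, n_no_insecta)))
  summarize_filter(scored, config)
}

#' @export
print.filter_summary <- function(x, ...) {
  cmp <- if (x$inclusive) ">=" else ">"
  cat(sprintf("Filter summary (ratio %s %.2f): %d reads\n", cmp,
              x$threshold, x$n_total))
  cat(sprintf("  kept:           %8d  (%.2f%%)\n", x$n_kept, x$pct_kept))
  cat(sprintf("  below cut-off:  %8d  (%.2f%%)\n", x$n_below, x$pct_below))
  cat(sprintf("  no Insecta hit: %8d  (%.2f%%)\n", x$n_no_insecta,
              x$pct_no_insecta))
  invisible(x)
}

#' Histogram of score ratios
#'
#' Bins reads with a defined ratio over `[0, ratio_cap]` (half-open bins,
#' last bin closed). I_ONLY reads (no denominator) go to a separate
#' `i_only` overflow bucket, reads with ratio above the cap to `overflow`,
#' NO_I reads to `no_hit`. Bucket counts sum to the number of reads.
#'
#' @param scored a `scored_reads` data.frame.
#' @param n_bins number of bins (>= 1).
#' @param ratio_cap upper edge of the binned range (> 1).
#' @return data.frame with columns `bin` (label), `lower`, `upper`,
#'   `count`.
#' @export
ratio_histogram <- function(scored, n_bins = 20L, ratio_cap = 2) {
  stopifnot(n_bins >= 1L, ratio_cap > 1)
  edges <- seq(0, ratio_cap, length.out = n_bins + 1L)
  r <- scored$ratio
  cat_ <- as.character(scored$category)
  defined <- !is.na(r)
  in_range <- defined & r <= ratio_cap
  idx <- pmin(findInterval(r[in_range], edges, rightmost.closed = TRUE),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(
    bin = c(sprintf("[%.3g,%.3g%s", edges[-length(edges)], edges[-1],
                    c(rep(")", n_bins - 1L), "]")),
            "overflow", "i_only", "no_hit"),
    lower = c(edges[-length(edges)], ratio_cap, NA, NA),
    upper = c(edges[-1], Inf, NA, NA),
    count = c(counts, sum(defined & r > ratio_cap),
              sum(cat_ == "I_ONLY"), sum(cat_ == "NO_I")),
    stringsAsFactors = FALSE)
}

#' Write filter outputs: kept reads, summary JSON, histogram TSV
#'
#' @param scored a `scored_reads` data.frame.
#' @param reads named character vector of read sequences.
#' @param config a [filter_config()].
#' @param dir output directory.
#' @return named vector of output paths, invisibly.
#' @export
write_filter_outputs <- function(scored, reads, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fl <- filter_reads(scored, config)
  sm <- summarize_filter(scored, config)
  paths <- c(kept = file.path(dir, "kept_reads.fasta"),
             summary = file.path(dir, "filter_summary.json"),
             histogram = file.path(dir, "ratio_histogram.tsv"))
  write_fasta(reads[fl$kept], paths[["kept"]])
  jsonlite::write_json(unclass(sm), paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)
  write.table(ratio_histogram(scored), paths[["histogram"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
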