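# Dual-library read scoring: raw Smith-Waterman best-hit scores against the
# Insecta and Non-Insecta partitions, the ratio of scores, and the
# four-category classification.

CATEGORY_LEVELS <- c("I_ONLY", "I_GT_N", "N_GT_I", "NO_I")

#' Scoring parameters for the local-alignment scorer
#'
#' Defaults follow blastn-task scoring (match +2, mismatch -3, gap open -5,
#' gap extend -2). Hits are reported by raw-score threshold
#' (`min_report_score`, default 50) rather than E-value: ratios of raw
#' scores are insensitive to common rescaling, and a database-size-dependent
#' E-value is not meaningful for desk-scale libraries. A gap of length k
#' costs `gap_open + k * gap_extend`.
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch penalty.
#' @param gap_open non-positive gap opening penalty.
#' @param gap_extend non-positive gap extension penalty.
#' @param min_report_score positive raw score below which "no hit" is
#'   reported.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, min_report_score = 50L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_report_score > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_report_score = as.integer(min_report_score)),
            class = "scoring_params")
}

lib_sequences <- function(library) {
  if (inherits(library, "ref_seq")) library <- list(library)
  if (is.list(library))
    return(vapply(library, `[[`, "", "sequence"))
  as.character(library)
}

#' Best local-alignment score of a read against a library
#'
#' Maximum raw Smith-Waterman score of the read (either strand) against any
#' library sequence, or `NA` when that maximum falls below
#' `params$min_report_score` (no hit). An empty library is treated as no
#' hit.
#'
#' @param read nucleotide string (length >= 1).
#' @param library list of [ref_seq()] records or character vector of
#'   sequences.
#' @param params a [scoring_params()] object.
#' @return integer score, or `NA_integer_` for no hit.
#' @export
best_hit_score <- function(read, library, params = scoring_params()) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) >= 1L)
  refs <- lib_sequences(library)
  if (length(refs) == 0L) return(NA_integer_)
  s <- .rf_sw_best_scores(normalize_dna(read), normalize_dna(refs),
                          params$match, params$mismatch, params$gap_open,
                          params$gap_extend)
  s <- max(s)
  if (s < params$min_report_score) NA_integer_ else as.integer(s)
}

#' Parse an external aligner hit table (BLAST outfmt 6)
#'
#' Standard 12-column tabular output (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Per query, the maximum
#' value of the chosen score column is retained. The same `score_column`
#' must be applied to both libraries for ratios to be meaningful.
#'
#' @param path path to the tabular file.
#' @param score_column `"bitscore"` (column 12, default) or `"raw"`
#'   (a 13th column holding raw scores, as produced by
#'   `-outfmt "6 std score"`).
#' @return named numeric vector: best score per query id (empty for an
#'   empty file).
#' @export
parse_external_hits <- function(path, score_column = c("bitscore", "raw")) {
  score_column <- match.arg(score_column)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(setNames(numeric(0), character(0)))
  need <- if (score_column == "raw") 13L else 12L
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < need)
  if (length(bad) > 0L)
    stop("malformed hit table line ", bad[1], ": expected >= ", need,
         " columns, found ", nf[bad[1]])
  qid <- vapply(parts, `[[`, "", 1L)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", need)))
  if (anyNA(sc)) {
    bad <- which(is.na(sc))[1]
    stop("malformed hit table line ", bad, ": non-numeric score")
  }
  tapply(sc, qid, max)[unique(qid)]
}

#' Score reads against both library partitions
#'
#' For each read, the best-hit raw score against the Insecta and the
#' Non-Insecta partition under identical parameters, the ratio of Insecta
#' over Non-Insecta scores when both exist, and the four-way category:
#' \describe{
#'   \item{I_ONLY}{hit only in the Insecta library;}
#'   \item{I_GT_N}{both hits, ratio >= 1 (ties kept on the Insecta side);}
#'   \item{N_GT_I}{both hits, ratio < 1;}
#'   \item{NO_I}{no Insecta hit.}
#' }
#'
#' @param reads named character vector of read sequences (names are read
#'   ids), or a data.frame with columns `read_id` and `sequence`.
#' @param partition a `lib_partition` from [partition_by_node()].
#' @param params a [scoring_params()] object.
#' @return a `scored_reads` data.frame with columns `read_id`, `s_insecta`,
#'   `s_non_insecta`, `ratio`, `category`.
#' @export
score_reads <- function(reads, partition, params = scoring_params()) {
  if (is.data.frame(reads))
    reads <- setNames(reads$sequence, reads$read_id)
  stopifnot(length(reads) > 0L, !is.null(names(reads)))
  seqs <- normalize_dna(as.character(reads))
  score_side <- function(side) {
    refs <- lib_sequences(side)
    if (length(refs) == 0L) return(rep(NA_integer_, length(seqs)))
    s <- .rf_sw_best_scores(seqs, normalize_dna(refs), params$match,
                            params$mismatch, params$gap_open,
                            params$gap_extend)
    s[s < params$min_report_score] <- NA_integer_
    s
  }
  si <- score_side(partition$insecta)
  sn <- score_side(partition$non_insecta)
  scored_reads(names(reads), si, sn)
}

#' Assemble a scored-read table from per-library scores
#'
#' Computes the ratio and category from the two (possibly missing) scores;
#' used both by [score_reads()] and by the external-hits path.
#'
#' @param read_id character vector of read ids.
#' @param s_insecta,s_non_insecta numeric scores, `NA` = no hit.
#' @return a `scored_reads` data.frame.
#' @export
scored_reads <- function(read_id, s_insecta, s_non_insecta) {
  stopifnot(length(read_id) == length(s_insecta),
            length(read_id) == length(s_non_insecta))
  ratio <- ifelse(!is.na(s_insecta) & !is.na(s_non_insecta),
                  s_insecta / s_non_insecta, NA_real_)
  category <- ifelse(is.na(s_insecta), "NO_I",
              ifelse(is.na(s_non_insecta), "I_ONLY",
              ifelse(ratio >= 1, "I_GT_N", "N_GT_I")))
  out <- data.frame(read_id = as.character(read_id),
                    s_insecta = as.numeric(s_insecta),
                    s_non_insecta = as.numeric(s_non_insecta),
                    ratio = ratio,
                    category = factor(category, levels = CATEGORY_LEVELS),
                    stringsAsFactors = FALSE)
  class(out) <- c("scored_reads", "data.frame")
  out
}

#' Combine two external hit tables into a scored-read table
#'
#' @param insecta_hits,non_insecta_hits named numeric vectors from
#'   [parse_external_hits()] (one per library, same score column).
#' @param read_ids optionally, the full universe of read ids (reads with no
#'   hit in either table are then reported as NO_I).
#' @return a `scored_reads` data.frame.
#' @export
external_scored_reads <- function(insecta_hits, non_insecta_hits,
                                  read_ids = NULL) {
  if (is.null(read_ids))
    read_ids <- union(names(insecta_hits), names(non_insecta_hits))
  scored_reads(read_ids,
               unname(insecta_hits[read_ids]),
               unname(non_insecta_hits[read_ids]))
}

#' Write a scored-read table as TSV
#'
#' @param scored a `scored_reads` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_tsv <- function(scored, path) {
  write.table(scored, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
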