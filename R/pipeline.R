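# The iterative filtration pipeline: build libraries -> score -> filter ->
# assemble, augmenting the Insecta library with complete assembled
# sequences between cycles, with a JSON run manifest.

#' Pipeline configuration
#'
#' @param reads path to the read FASTA/FASTQ.
#' @param insecta_fasta,non_insecta_fasta taxonomy-annotated reference
#'   FASTAs (see [parse_taxonomy_fasta()]).
#' @param out_dir output directory.
#' @param scoring a [scoring_params()].
#' @param filter a [filter_config()].
#' @param assembler an [assembler_spec()] (recorded in the manifest; the
#'   internal assembler is used unless an external binary is requested).
#' @param cycles maximum number of filtration cycles (>= 1).
#' @param min_overlap greedy assembler minimum exact overlap.
#' @param complete_min_length contig length at which an assembled sequence
#'   counts as "complete" and augments the Insecta library between cycles.
#' @param seed integer seed recorded in the manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, insecta_fasta, non_insecta_fasta,
                            out_dir, scoring = scoring_params(),
                            filter = filter_config(),
                            assembler = assembler_spec(), cycles = 1L,
                            min_overlap = 40L,
                            complete_min_length = 1000L, seed = 1L) {
  stopifnot(cycles >= 1L)
  for (p in c(reads, insecta_fasta, non_insecta_fasta))
    if (!file.exists(p)) stop("path does not exist: ", p)
  structure(list(reads = reads, insecta_fasta = insecta_fasta,
                 non_insecta_fasta = non_insecta_fasta, out_dir = out_dir,
                 scoring = scoring, filter = filter, assembler = assembler,
                 cycles = as.integer(cycles),
                 min_overlap = as.integer(min_overlap),
                 complete_min_length = as.integer(complete_min_length),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the iterative filtration pipeline
#'
#' Per cycle: score all reads against the current Insecta / Non-Insecta
#' partition, filter at the ratio threshold, assemble the kept reads
#' (greedy exact-overlap assembly followed by majority-vote polishing),
#' and add assembled sequences at or above `complete_min_length` to the
#' Insecta library for the next cycle. Stops after `cycles` iterations or
#' as soon as the kept-read set is unchanged between cycles (convergence).
#' Writes kept reads, contigs, per-cycle summaries, and a JSON manifest
#' recording all parameters.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[ribofilt] ", sprintf(...))
  reads <- read_sequences(config$reads)
  insecta <- parse_taxonomy_fasta(config$insecta_fasta)
  non_insecta <- parse_taxonomy_fasta(config$non_insecta_fasta)
  partition <- structure(list(anchor_node = "Insecta", insecta = insecta,
                              non_insecta = non_insecta, cycle = 0L),
                         class = "lib_partition")
  prev_kept <- NULL
  cycles_run <- list()
  contigs <- list()
  converged <- FALSE
  for (cy in seq_len(config$cycles)) {
    log_msg("cycle %d: scoring %d reads against %d + %d references", cy,
            length(reads), length(partition$insecta),
            length(partition$non_insecta))
    scored <- score_reads(reads, partition, config$scoring)
    fl <- filter_reads(scored, config$filter)
    sm <- summarize_filter(scored, config$filter)
    log_msg("cycle %d: kept %d / %d reads (%.2f%%)", cy, sm$n_kept,
            sm$n_total, sm$pct_kept)
    if (!is.null(prev_kept) && identical(sort(fl$kept), prev_kept)) {
      converged <- TRUE
      log_msg("cycle %d: kept-read set unchanged; converged", cy)
      cycles_run[[cy]] <- list(cycle = cy, summary = unclass(sm),
                               converged = TRUE)
      break
    }
    prev_kept <- sort(fl$kept)
    contigs <- tryCatch(
      greedy_assemble(reads[fl$kept], config$min_overlap),
      error = function(e) stop("assembly failed in cycle ", cy, ": ",
                               conditionMessage(e)))
    contigs <- polish_contigs(contigs, reads[fl$kept],
                              params = config$scoring)
    lens <- vapply(contigs, function(ct) nchar(ct$sequence), integer(1))
    complete <- contigs[lens >= config$complete_min_length]
    log_msg("cycle %d: %d contigs (%d complete, >= %d nt)", cy,
            length(contigs), length(complete), config$complete_min_length)
    cycles_run[[cy]] <- list(
      cycle = cy, summary = unclass(sm),
      n_contigs = length(contigs),
      n_complete = length(complete),
      contig_lengths = sort(lens, decreasing = TRUE),
      converged = FALSE)
    if (cy < config$cycles && length(complete) > 0L) {
      new_seqs <- setNames(
        vapply(complete, `[[`, "", "sequence"),
        sprintf("assembled_c%d_%s", cy,
                vapply(complete, `[[`, "", "id")))
      partition <- augment_insecta(partition, new_seqs)
    }
    # persist per-cycle outputs
    cyc_dir <- file.path(config$out_dir, sprintf("cycle_%d", cy))
    write_filter_outputs(scored, reads, config$filter, cyc_dir)
    write_contigs(contigs, file.path(cyc_dir, "contigs.fasta"),
                  file.path(cyc_dir, "contigs.tsv"))
  }
  manifest <- list(
    parameters = list(
      reads = config$reads, insecta_fasta = config$insecta_fasta,
      non_insecta_fasta = config$non_insecta_fasta,
      scoring = unclass(config$scoring),
      filter = unclass(config$filter),
      kmer_lengths = config$assembler$kmer_lengths,
      cycles = config$cycles, min_overlap = config$min_overlap,
      complete_min_length = config$complete_min_length,
      seed = config$seed),
    n_reads = length(reads),
    cycles = cycles_run,
    converged = converged,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a flat key=value config file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Every CLI flag has a config twin; flags win.
#'
#' @param path config file path.
#' @return named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L)
    stop("malformed config line ", bad[1], ": '", lines[bad[1]], "'")
  setNames(trimws(vapply(kv, `[[`, "", 3L)),
           trimws(vapply(kv, `[[`, "", 2L)))
}
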