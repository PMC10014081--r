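# Synthetic-data generators: rRNA references with conserved/variable block
# architecture, related taxa at controlled divergence, contaminated
# specimen read sets with truth labels, and COI amplicon read pairs. All
# generators are pure functions of (parameters, seed).

#' rRNA gene architecture
#'
#' Describes a gene as an ordered list of conserved and variable blocks.
#' Defaults: LSU (28S-like) 3,900 nt, SSU (18S-like) 1,900 nt, alternating
#' conserved(300)/variable(200) blocks (~60% conserved), substitution rate
#' between related taxa 0.02 in conserved and 0.25 in variable blocks —
#' this produces the bimodal score-ratio structure real specimens show,
#' where conserved-region reads are ambiguous between libraries and
#' variable-region reads are diagnostic.
#'
#' @param gene `"LSU"` or `"SSU"`.
#' @param total_length gene length (defaults 3,900 LSU / 1,900 SSU).
#' @param blocks data.frame with columns `kind`
#'   (`"conserved"`/`"variable"`) and `length`; built automatically when
#'   NULL.
#' @param conserved_divergence,variable_divergence substitution rates
#'   between related taxa per block kind
#'   (0 <= conserved < variable <= 1).
#' @return an object of class `rrna_architecture`.
#' @export
rrna_architecture <- function(gene = c("LSU", "SSU"), total_length = NULL,
                              blocks = NULL, conserved_divergence = 0.02,
                              variable_divergence = 0.25) {
  gene <- match.arg(gene)
  if (is.null(total_length))
    total_length <- if (gene == "LSU") 3900L else 1900L
  total_length <- as.integer(total_length)
  if (is.null(blocks)) {
    kinds <- character(0); lens <- integer(0)
    left <- total_length
    k <- "conserved"
    while (left > 0L) {
      take <- min(left, if (k == "conserved") 300L else 200L)
      kinds <- c(kinds, k); lens <- c(lens, take)
      left <- left - take
      k <- if (k == "conserved") "variable" else "conserved"
    }
    blocks <- data.frame(kind = kinds, length = lens,
                         stringsAsFactors = FALSE)
  }
  stopifnot(sum(blocks$length) == total_length,
            all(blocks$kind %in% c("conserved", "variable")),
            conserved_divergence >= 0,
            conserved_divergence < variable_divergence,
            variable_divergence <= 1)
  structure(list(gene = gene, total_length = total_length, blocks = blocks,
                 conserved_divergence = conserved_divergence,
                 variable_divergence = variable_divergence),
            class = "rrna_architecture")
}

block_starts <- function(architecture) {
  cumsum(c(1L, architecture$blocks$length[-nrow(architecture$blocks)]))
}

# per-position block kind ("conserved"/"variable")
position_kinds <- function(architecture) {
  rep(architecture$blocks$kind, architecture$blocks$length)
}

#' Classify a read window against the block architecture
#'
#' `"conserved"` when the window lies entirely within conserved blocks,
#' otherwise `"variable"` (touching at least one variable base). Reads
#' from fully conserved windows are inherently ambiguous between
#' libraries; the classifier benchmark exempts them from its recall
#' requirement.
#'
#' @param architecture an [rrna_architecture()].
#' @param start,end 1-based inclusive window on the sense strand
#'   (vectorised).
#' @return character vector of window kinds.
#' @export
window_kind <- function(architecture, start, end) {
  kinds <- position_kinds(architecture)
  mapply(function(s, e) {
    if (all(kinds[s:e] == "conserved")) "conserved" else "variable"
  }, start, end)
}

#' Generate a random rRNA reference under an architecture
#'
#' Uniform base composition over A/C/G/T; the block annotation is retained
#' as the attribute `architecture`. Deterministic under `seed`.
#'
#' @param architecture an [rrna_architecture()].
#' @param seed integer seed.
#' @param id record id.
#' @param taxonomy taxonomy path for the record.
#' @return a [ref_seq()] with attribute `architecture`.
#' @export
make_reference <- function(architecture, seed, id = architecture$gene,
                           taxonomy = c("Root", "Synthetic", id)) {
  stopifnot(inherits(architecture, "rrna_architecture"))
  seq_ <- with_seed(seed, random_dna(architecture$total_length))
  out <- ref_seq(id, seq_, taxonomy)
  attr(out, "architecture") <- architecture
  out
}

#' Derive a related taxon from a base reference
#'
#' Applies substitutions at `conserved_divergence` within conserved blocks
#' and `variable_divergence` within variable blocks (binomial per block;
#' each substitution is to a uniformly chosen different base). The realized
#' per-block divergence is binomial around the nominal rate.
#'
#' @param base a [ref_seq()] from [make_reference()] (matching
#'   architecture).
#' @param architecture the [rrna_architecture()] used for `base`; rates may
#'   be overridden by passing a modified copy.
#' @param taxonomy taxonomy path for the derived record.
#' @param seed integer seed.
#' @param id record id.
#' @return a [ref_seq()] with attribute `architecture`.
#' @export
derive_relative <- function(base, architecture, taxonomy, seed,
                            id = paste0(base$id, "_rel")) {
  stopifnot(inherits(base, "ref_seq"),
            inherits(architecture, "rrna_architecture"),
            nchar(base$sequence) == architecture$total_length)
  seq_ <- with_seed(seed, {
    s <- base$sequence
    starts <- block_starts(architecture)
    for (b in seq_len(nrow(architecture$blocks))) {
      rate <- if (architecture$blocks$kind[b] == "conserved")
        architecture$conserved_divergence
      else architecture$variable_divergence
      if (rate <= 0) next
      len <- architecture$blocks$length[b]
      off <- starts[b] - 1L
      hit <- which(runif(len) < rate)
      s <- substitute_bases(s, off + hit)
    }
    s
  })
  out <- ref_seq(id, seq_, taxonomy)
  attr(out, "architecture") <- architecture
  out
}

#' Specimen read-mixture description
#'
#' @param host_fraction fraction of reads of host origin, in (0, 1].
#' @param contaminants data.frame with columns `label` (e.g. `"blood"`,
#'   `"mite"`, `"microbiota"`), `ref_id`, `fraction`; fractions plus
#'   `host_fraction` must sum to 1.
#' @param read_length read length (default 150, the Illumina read length
#'   the method was designed around).
#' @param error_rate per-base substitution error rate.
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @return an object of class `specimen_mix`.
#' @export
specimen_mix <- function(host_fraction = 0.7, contaminants = NULL,
                         read_length = 150L, error_rate = 0.01,
                         n_reads = 1000L, seed = 1L) {
  stopifnot(host_fraction > 0, host_fraction <= 1)
  total <- host_fraction +
    if (is.null(contaminants)) 0 else sum(contaminants$fraction)
  if (abs(total - 1) > 1e-8) stop("fractions must sum to 1")
  structure(list(host_fraction = host_fraction,
                 contaminants = contaminants,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 seed = as.integer(seed)),
            class = "specimen_mix")
}

#' Simulate a contaminated specimen read set with truth labels
#'
#' Each read is a `read_length` window at a uniform position on its origin
#' reference, on a uniform strand, with substitution errors at
#' `error_rate`. Host reads are drawn uniformly from the host references
#' (e.g. the LSU and SSU genes in proportion to length); contaminant reads
#' from their labelled references. Truth labels (origin reference, window,
#' strand, error count) are total, enabling exact precision/recall
#' computation downstream. Deterministic under the mix's seed.
#'
#' @param mix a [specimen_mix()].
#' @param references named list of [ref_seq()] records; names
#'   `host` / contaminant `ref_id`s must resolve. The `host` entry may be a
#'   list of several references.
#' @return data.frame with columns `read_id`, `sequence`, `origin`
#'   (label), `ref_id`, `start`, `end`, `strand`, `n_errors`.
#' @export
simulate_specimen <- function(mix, references) {
  stopifnot(inherits(mix, "specimen_mix"))
  host_refs <- references[["host"]]
  if (inherits(host_refs, "ref_seq")) host_refs <- list(host_refs)
  stopifnot(length(host_refs) > 0L)
  labels <- "host"
  fracs <- mix$host_fraction
  if (!is.null(mix$contaminants)) {
    labels <- c(labels, mix$contaminants$label)
    fracs <- c(fracs, mix$contaminants$fraction)
  }
  pick_ref <- function(lab) {
    if (lab == "host") {
      lens <- vapply(host_refs, function(r) nchar(r$sequence), integer(1))
      host_refs[[sample.int(length(host_refs), 1L, prob = lens)]]
    } else {
      rid <- mix$contaminants$ref_id[mix$contaminants$label == lab][1]
      r <- references[[rid]]
      if (is.null(r)) stop("reference '", rid, "' does not resolve")
      r
    }
  }
  with_seed(mix$seed, {
    origin <- sample(labels, mix$n_reads, replace = TRUE, prob = fracs)
    rows <- vector("list", mix$n_reads)
    for (i in seq_len(mix$n_reads)) {
      r <- pick_ref(origin[i])
      L <- nchar(r$sequence)
      if (L < mix$read_length)
        stop("reference '", r$id, "' shorter than the read length")
      s <- sample.int(L - mix$read_length + 1L, 1L)
      e <- s + mix$read_length - 1L
      sq <- substr(r$sequence, s, e)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") sq <- revcomp(sq)
      err <- which(runif(mix$read_length) < mix$error_rate)
      if (length(err) > 0L) sq <- substitute_bases(sq, err)
      rows[[i]] <- data.frame(read_id = sprintf("read_%06d", i),
                              sequence = sq, origin = origin[i],
                              ref_id = r$id, start = s, end = e,
                              strand = strand, n_errors = length(err),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a COI amplicon and its Sanger read pair
#'
#' The source begins with the forward Folmer primer and ends with the
#' reverse complement of the reverse primer; the forward trimming anchor
#' (TTTTGG) is planted just downstream of the forward primer and the
#' reverse anchor context near the 3' end, so the trimming rules are
#' exercised. The forward read covers a 5' span and the reverse read the
#' reverse complement of a 3' span; the spans overlap. Read qualities are
#' high (Q40) with low-quality (Q15) 3' tails to exercise quality
#' trimming. Deterministic under `seed`.
#'
#' @param source_length amplicon length (default 658, the Folmer product).
#' @param read_span length of each Sanger read (must exceed half the
#'   source).
#' @param error_rate per-base substitution error rate (default 0).
#' @param seed integer seed.
#' @return list with `source` (DNA string), `forward`, `reverse`
#'   ([sanger_read()]s).
#' @export
simulate_coi_pair <- function(source_length = 658L, read_span = 400L,
                              error_rate = 0, seed = 1L) {
  source_length <- as.integer(source_length)
  read_span <- as.integer(read_span)
  if (read_span <= source_length / 2)
    stop("read_span too short: reads must overlap")
  fwd_p <- folmer_primers[["LCO1490"]]
  rev_p_rc <- revcomp(folmer_primers[["HCO2198"]])
  head_ <- paste0(fwd_p, "ACACA", COI_ANCHOR_FORWARD)
  tail_ <- paste0("AGATCC", "TGTGT", rev_p_rc)
  interior_len <- source_length - nchar(head_) - nchar(tail_)
  stopifnot(interior_len > 0L)
  with_seed(seed, {
    src <- paste0(head_, random_dna(interior_len), tail_)
    stopifnot(nchar(src) == source_length)
    make_read <- function(seq_, direction) {
      n <- nchar(seq_)
      if (error_rate > 0) {
        err <- which(runif(n) < error_rate)
        seq_ <- substitute_bases(seq_, err)
      }
      qual <- rep(40L, n)
      qual[(n - 4L):n] <- 15L
      sanger_read(direction, seq_, qual)
    }
    forward <- make_read(substr(src, 1L, read_span), "forward")
    reverse <- make_read(revcomp(substr(src, source_length - read_span + 1L,
                                        source_length)), "reverse")
    list(source = src, forward = forward, reverse = reverse)
  })
}

#' Materialize a full synthetic test corpus
#'
#' Writes taxonomy-annotated reference FASTAs (a host-relative Insecta
#' library and contaminant Non-Insecta libraries), a specimen read FASTA,
#' and a truth TSV, all derived from one seed. This is the one-command
#' fixture generator behind the `simulate` CLI subcommand.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_reads number of specimen reads.
#' @param host_fraction host read fraction (remainder is a blood-like
#'   contaminant).
#' @param error_rate per-base substitution error rate.
#' @return named list with the generated objects and file paths,
#'   invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, n_reads = 2000L,
                          host_fraction = 0.7, error_rate = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lsu <- rrna_architecture("LSU")
  ssu <- rrna_architecture("SSU")
  base_lsu <- make_reference(lsu, seed, id = "anc_LSU")
  base_ssu <- make_reference(ssu, seed + 1L, id = "anc_SSU")
  host_lsu <- derive_relative(base_lsu, lsu,
                              c("Eukaryota", "Arthropoda", "Insecta",
                                "Culicidae", "Specimen"),
                              seed + 2L, id = "host_LSU")
  host_ssu <- derive_relative(base_ssu, ssu,
                              c("Eukaryota", "Arthropoda", "Insecta",
                                "Culicidae", "Specimen"),
                              seed + 3L, id = "host_SSU")
  near <- function(ref, arch, sd_, id)
    derive_relative(ref, rrna_architecture(arch$gene,
                                           conserved_divergence = 0.01,
                                           variable_divergence = 0.05),
                    c("Eukaryota", "Arthropoda", "Insecta", "Culicidae",
                      "Relative"), sd_, id = id)
  rel_lsu <- near(host_lsu, lsu, seed + 4L, "relative_LSU")
  rel_ssu <- near(host_ssu, ssu, seed + 5L, "relative_SSU")
  blood_lsu <- derive_relative(base_lsu, lsu,
                               c("Eukaryota", "Chordata", "Vertebrata",
                                 "Blood"), seed + 6L, id = "blood_LSU")
  blood_ssu <- derive_relative(base_ssu, ssu,
                               c("Eukaryota", "Chordata", "Vertebrata",
                                 "Blood"), seed + 7L, id = "blood_SSU")
  refs <- list(host = list(host_lsu, host_ssu), blood_LSU = blood_lsu,
               blood_SSU = blood_ssu)
  mix <- specimen_mix(host_fraction = host_fraction,
                      contaminants = data.frame(
                        label = c("blood_l", "blood_s"),
                        ref_id = c("blood_LSU", "blood_SSU"),
                        fraction = rep((1 - host_fraction) / 2, 2L),
                        stringsAsFactors = FALSE),
                      error_rate = error_rate, n_reads = n_reads,
                      seed = seed + 10L)
  reads <- simulate_specimen(mix, refs)
  tax_fa <- function(recs) setNames(
    vapply(recs, `[[`, "", "sequence"),
    vapply(recs, function(r) paste(r$id, paste(r$taxonomy, collapse = ";")),
           ""))
  paths <- c(insecta = file.path(dir, "insecta.fasta"),
             non_insecta = file.path(dir, "non_insecta.fasta"),
             reads = file.path(dir, "reads.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(tax_fa(list(rel_lsu, rel_ssu)), paths[["insecta"]])
  write_fasta(tax_fa(list(blood_lsu, blood_ssu)), paths[["non_insecta"]])
  write_fasta(setNames(reads$sequence, reads$read_id), paths[["reads"]])
  write.table(reads[, setdiff(names(reads), "sequence")], paths[["truth"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(host = list(lsu = host_lsu, ssu = host_ssu),
                 relative = list(lsu = rel_lsu, ssu = rel_ssu),
                 blood = list(lsu = blood_lsu, ssu = blood_ssu),
                 reads = reads, paths = paths))
}

#' Evaluate assembled contigs against a known source sequence
#'
#' For simulation studies where the true host gene is known: aligns each
#' contig (of at least `min_contig_length`) to the truth, keeps alignments
#' at or above `min_identity` percent identity, and reports the fraction
#' of the truth covered by the union of their spans together with the
#' length-weighted mean identity of the contributing alignments.
#'
#' @param contigs list of [contig()] records.
#' @param truth a [ref_seq()]: the simulation's true source sequence.
#' @param min_identity percent identity for a span to count (default 99).
#' @param min_contig_length ignore contigs below this length (default 300).
#' @param params a [scoring_params()] for the alignments.
#' @return list with `coverage_pct`, `identity_pct`, `n_contigs_used`.
#' @export
contig_recovery <- function(contigs, truth, min_identity = 99,
                            min_contig_length = 300L,
                            params = scoring_params()) {
  stopifnot(inherits(truth, "ref_seq"))
  L <- nchar(truth$sequence)
  covered <- logical(L)
  idw <- 0; wsum <- 0; used <- 0L
  for (ct in contigs) {
    if (nchar(ct$sequence) < min_contig_length) next
    best <- NULL
    for (s in c(ct$sequence, revcomp(ct$sequence))) {
      al <- .rf_sw_align(s, truth$sequence, params$match, params$mismatch,
                         params$gap_open, params$gap_extend)
      if (is.null(best) || al$score > best$score) best <- al
    }
    q <- utf8ToInt(best$q_aln); r <- utf8ToInt(best$r_aln)
    if (length(q) == 0L) next
    ident <- 100 * sum(q == r) / length(q)
    if (ident < min_identity) next
    covered[best$r_start:best$r_end] <- TRUE
    w <- best$r_end - best$r_start + 1L
    idw <- idw + ident * w; wsum <- wsum + w
    used <- used + 1L
  }
  list(coverage_pct = 100 * mean(covered),
       identity_pct = if (wsum > 0) idw / wsum else NA_real_,
       n_contigs_used = used)
}
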