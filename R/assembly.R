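# Assembly of kept reads into full-length rRNA consensus sequences:
# a deterministic greedy overlap assembler for desk-scale data, a
# reference-guided consensus mode (the trusted-contig rescue), majority-vote
# polishing, contig binning, and an adapter contract for an external
# assembler.

#' Construct a contig record
#'
#' @param id contig identifier.
#' @param sequence nucleotide string.
#' @param per_base_coverage integer vector, one count per base.
#' @param mode `"de_novo"` or `"guided"`.
#' @param guide_id identifier of the guide sequence (guided mode only).
#' @return an object of class `contig`.
#' @export
contig <- function(id, sequence, per_base_coverage,
                   mode = c("de_novo", "guided"), guide_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(nchar(sequence) == length(per_base_coverage))
  if (!all(is.na(per_base_coverage) | per_base_coverage >= 0))
    stop("negative coverage")
  structure(list(id = id, sequence = sequence,
                 per_base_coverage = as.numeric(per_base_coverage),
                 mean_coverage = mean(per_base_coverage),
                 mode = mode, guide_id = guide_id),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s: %d nt, %.1fx mean coverage, %s%s>\n", x$id,
              nchar(x$sequence), x$mean_coverage, x$mode,
              if (!is.null(x$guide_id)) paste0(" (guide ", x$guide_id, ")")
              else ""))
  invisible(x)
}

#' External assembler invocation spec
#'
#' Mirrors the options used for rRNA assembly with a de Bruijn assembler:
#' ascending odd k-mer lengths (default 31, 51, 71), free-form mode flags
#' (e.g. an rna mode), and optional trusted contigs passed through to guide
#' reconstruction of hard specimens.
#'
#' @param kmer_lengths ascending odd integers, each below the read length.
#' @param mode_flags character vector of extra flags.
#' @param trusted_contigs optional list of [ref_seq()] records.
#' @return an object of class `assembler_spec`.
#' @export
assembler_spec <- function(kmer_lengths = c(31L, 51L, 71L),
                           mode_flags = "--rna", trusted_contigs = NULL) {
  stopifnot(all(kmer_lengths %% 2L == 1L),
            !is.unsorted(kmer_lengths, strictly = TRUE))
  structure(list(kmer_lengths = as.integer(kmer_lengths),
                 mode_flags = mode_flags,
                 trusted_contigs = trusted_contigs),
            class = "assembler_spec")
}

#' Greedy overlap assembly with exact overlaps
#'
#' Iteratively merges the pair of sequences with the longest exact
#' suffix-prefix overlap at or above `min_overlap`, considering both
#' strands, until no merge applies; unmergeable reads become singleton
#' contigs. Overlap-length ties are broken by the lexicographically smaller
#' merged sequence, making the result deterministic. Per-base coverage
#' counts constituent reads per position. Exact-overlap merging never
#' votes, so errors carried by reads persist where a single read covers a
#' position; see [polish_contigs()].
#'
#' @param reads character vector of read sequences.
#' @param min_overlap minimum exact overlap (must be below the read
#'   length).
#' @return list of [contig()] records (mode `"de_novo"`), longest first.
#' @export
greedy_assemble <- function(reads, min_overlap = 40L) {
  reads <- normalize_dna(as.character(reads))
  stopifnot(length(reads) > 0L, min_overlap >= 1L,
            min_overlap < max(nchar(reads)))
  res <- .rf_greedy_assemble(reads, as.integer(min_overlap))
  ord <- order(-nchar(res$sequence), res$sequence)
  out <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    out[[k]] <- contig(sprintf("contig_%d", k), res$sequence[[i]],
                       res$coverage[[i]], mode = "de_novo")
  }
  out
}

# Best placement of one read on a guide: strand-aware local alignment.
# A fast score-only pass picks the strand and the alignment end point;
# the traceback then runs only on a read-sized window of the guide.
# Returns NULL when the read is not placeable under the identity and
# span constraints.
place_read <- function(read, guide_seq, params, min_identity, min_frac) {
  rc <- revcomp(read)
  s_f <- .rf_sw_score_end(read, guide_seq, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
  s_r <- .rf_sw_score_end(rc, guide_seq, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
  if (max(s_f[1], s_r[1]) <= 0) return(NULL)
  query <- if (s_f[1] >= s_r[1]) read else rc
  end <- if (s_f[1] >= s_r[1]) s_f[3] else s_r[3]
  margin <- 30L
  win_from <- max(1L, end - nchar(read) - margin)
  win_to <- min(nchar(guide_seq), end + margin)
  a <- .rf_sw_align(query, substr(guide_seq, win_from, win_to),
                    params$match, params$mismatch, params$gap_open,
                    params$gap_extend)
  a$r_start <- a$r_start + win_from - 1L
  a$r_end <- a$r_end + win_from - 1L
  if (a$score <= 0) return(NULL)
  q <- utf8ToInt(a$q_aln)
  r <- utf8ToInt(a$r_aln)
  ncol_ <- length(q)
  if (ncol_ == 0L) return(NULL)
  ident <- 100 * sum(q == r) / ncol_
  frac <- ncol_ / nchar(read)
  if (ident < min_identity) return(NULL)
  if (frac < min_frac) return(NULL)
  gap <- utf8ToInt("-")
  keep <- r != gap                       # columns that consume a guide base
  rpos <- a$r_start + cumsum(r != gap) - 1L
  list(pos = rpos[keep & q != gap], base = q[keep & q != gap],
       identity = ident, frac = frac)
}

# majority vote over a subset of placements; ties (including a tie with
# the guide's own base) resolve to the guide base
vote_consensus <- function(placements, sel, guide_chars, min_depth) {
  codes <- c(A = utf8ToInt("A"), C = utf8ToInt("C"), G = utf8ToInt("G"),
             T = utf8ToInt("T"), N = utf8ToInt("N"))
  gl <- length(guide_chars)
  votes <- matrix(0L, nrow = 5L, ncol = gl,
                  dimnames = list(names(codes), NULL))
  depth <- integer(gl)
  for (p in placements[sel]) {
    bi <- match(p$base, codes)
    ok <- !is.na(bi)
    votes[cbind(bi[ok], p$pos[ok])] <- votes[cbind(bi[ok], p$pos[ok])] + 1L
    depth[p$pos] <- depth[p$pos] + 1L
  }
  cons <- guide_chars
  low_depth <- depth < min_depth
  call_cols <- which(!low_depth)
  if (length(call_cols) > 0L) {
    top <- apply(votes[, call_cols, drop = FALSE], 2L, max)
    for (k in seq_along(call_cols)) {
      j <- call_cols[k]
      winners <- names(codes)[votes[, j] == top[k]]
      if (!(guide_chars[j] %in% winners)) cons[j] <- winners[1]
    }
  }
  list(sequence = paste(cons, collapse = ""), depth = depth,
       low_depth = which(low_depth))
}

#' Reference-guided consensus (trusted-contig rescue)
#'
#' Places each read at its best local-alignment position on the guide
#' (either strand) and calls a per-column majority vote. Columns with depth
#' below `min_depth` fall back to the guide base and are flagged; vote ties
#' resolve to the guide base (conservative toward the trusted sequence).
#' Only reads with at least `min_identity` percent identity to the guide
#' over at least `min_frac` of their length vote in the draft — reads of a
#' co-assembling foreign organism fall below the identity floor against
#' the host's nearest relative and are excluded from the pileup.
#'
#' Per-read identity thresholds at typical read lengths are noisy, so
#' with `competitive = TRUE` (the default) the draft is refined when the
#' read set is heterogeneous: an unfloored consensus of all placeable
#' reads is built (under excess foreign coverage this converges to the
#' foreign sequence), every read is scored against both consensuses, and
#' the final host consensus is rebuilt from the reads that score strictly
#' higher against the host draft. This competitive assignment separates
#' two 95%-identical organisms far more sharply than any identity floor.
#' When draft and unfloored consensus already agree (homogeneous reads),
#' the draft is returned as is.
#'
#' @param reads character vector of read sequences.
#' @param guide a [ref_seq()] record (length >= read length).
#' @param min_depth minimum depth to call a column from the reads.
#' @param params a [scoring_params()].
#' @param min_identity placement identity floor (percent, default 95).
#' @param min_frac minimum aligned fraction of the read (default 0.5).
#' @param competitive refine by competitive read assignment when the
#'   pileup is heterogeneous (default TRUE).
#' @return a [contig()] of the guide's length (mode `"guided"`), with
#'   attribute `low_depth`: positions that fell back to the guide base.
#' @export
guided_consensus <- function(reads, guide, min_depth = 2L,
                             params = scoring_params(), min_identity = 95,
                             min_frac = 0.5, competitive = TRUE) {
  stopifnot(inherits(guide, "ref_seq"))
  reads <- normalize_dna(as.character(reads))
  if (length(reads) == 0L) stop("empty read list")
  guide_chars <- strsplit(guide$sequence, "", fixed = TRUE)[[1]]
  # one unfloored placement pass; floors are applied on the records
  placements <- lapply(reads, function(rd)
    place_read(rd, guide$sequence, params, min_identity = 0,
               min_frac = 0))
  placeable <- !vapply(placements, is.null, logical(1))
  ident <- vapply(placements, function(p)
    if (is.null(p)) 0 else p$identity, numeric(1))
  frac <- vapply(placements, function(p)
    if (is.null(p)) 0 else p$frac, numeric(1))
  draft_sel <- placeable & ident >= min_identity & frac >= min_frac
  if (!any(draft_sel)) stop("guide unrelated to read set")
  draft <- vote_consensus(placements, draft_sel, guide_chars, min_depth)
  result <- draft
  if (competitive && sum(placeable) > sum(draft_sel)) {
    full <- vote_consensus(placements, placeable, guide_chars, min_depth)
    if (alignment_identity(draft$sequence, full$sequence,
                           params) < 99) {
      s_draft <- .rf_sw_best_scores(reads, draft$sequence, params$match,
                                    params$mismatch, params$gap_open,
                                    params$gap_extend)
      s_full <- .rf_sw_best_scores(reads, full$sequence, params$match,
                                   params$mismatch, params$gap_open,
                                   params$gap_extend)
      host_sel <- placeable & s_draft > s_full
      if (any(host_sel))
        result <- vote_consensus(placements, host_sel, guide_chars,
                                 min_depth)
    }
  }
  out <- contig(paste0(guide$id, "_consensus"), result$sequence,
                result$depth, mode = "guided", guide_id = guide$id)
  attr(out, "low_depth") <- result$low_depth
  out
}

# Assign each read to the contigs it shares at least one exact k-mer
# with (either strand). Returns a list of integer vectors of read indices
# per contig. A shared k-mer is a cheap necessary condition for the
# high-identity placement the polish performs, so alignment effort is
# spent only where a read can actually vote.
kmer_read_assignment <- function(contig_seqs, reads, k = 31L) {
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(contig_seqs)) {
    s <- contig_seqs[[i]]
    L <- nchar(s)
    if (L < k) next
    for (km in unique(substring(s, 1:(L - k + 1L), k:L))) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  out <- vector("list", length(contig_seqs))
  rc <- revcomp(reads)
  for (j in seq_along(reads)) {
    L <- nchar(reads[[j]])
    if (L < k) next
    kms <- unique(c(substring(reads[[j]], 1:(L - k + 1L), k:L),
                    substring(rc[[j]], 1:(L - k + 1L), k:L)))
    hit <- unique(unlist(lapply(kms, function(km)
      index[[km]]), use.names = FALSE))
    for (i in hit) out[[i]] <- c(out[[i]], j)
  }
  out
}

#' Majority-vote polish of assembled contigs
#'
#' Runs [guided_consensus()] with each contig as its own guide, so that
#' read errors frozen into the exact-overlap assembly are outvoted by the
#' covering reads. Reads are pre-assigned to contigs by shared exact
#' k-mers (both strands), so each read is only aligned where it can
#' plausibly vote. Contigs shorter than `min_length` are returned
#' unpolished (singleton read fragments carry too little signal to vote).
#'
#' @param contigs list of [contig()] records.
#' @param reads character vector of read sequences.
#' @param min_length polish only contigs at least this long.
#' @param kmer length of the exact k-mer used for read pre-assignment.
#' @param ... passed to [guided_consensus()].
#' @return list of [contig()] records, polished where applicable.
#' @export
polish_contigs <- function(contigs, reads, min_length = 300L, kmer = 31L,
                           ...) {
  reads <- normalize_dna(as.character(reads))
  polish_idx <- which(vapply(contigs, function(ct)
    nchar(ct$sequence) >= min_length, logical(1)))
  if (length(polish_idx) == 0L) return(contigs)
  assign_ <- kmer_read_assignment(
    lapply(contigs[polish_idx], `[[`, "sequence"), reads, k = kmer)
  for (k in seq_along(polish_idx)) {
    i <- polish_idx[k]
    cand <- assign_[[k]]
    if (length(cand) == 0L) next
    ct <- contigs[[i]]
    guide <- ref_seq(ct$id, ct$sequence, "contig")
    p <- tryCatch(guided_consensus(reads[cand], guide,
                                   competitive = FALSE, ...),
                  error = function(e) NULL)
    if (is.null(p)) next
    contigs[[i]] <- contig(ct$id, p$sequence, p$per_base_coverage,
                           mode = ct$mode, guide_id = ct$guide_id)
  }
  contigs
}

# percent identity of the best local alignment, excluding end gaps (local
# alignments have none)
alignment_identity <- function(a, b, params = scoring_params()) {
  al <- .rf_sw_align(normalize_dna(a), normalize_dna(b), params$match,
                     params$mismatch, params$gap_open, params$gap_extend)
  al_rc <- .rf_sw_align(revcomp(normalize_dna(a)), normalize_dna(b),
                        params$match, params$mismatch, params$gap_open,
                        params$gap_extend)
  if (al_rc$score > al$score) al <- al_rc
  q <- utf8ToInt(al$q_aln)
  r <- utf8ToInt(al$r_aln)
  if (length(q) == 0L) return(0)
  100 * sum(q == r) / length(q)
}

#' Bin contigs into host and foreign sets by identity to a host reference
#'
#' Contigs with at least `host_identity_min` percent identity to the host
#' reference go to the host bin; all others to the foreign bin. Each bin is
#' annotated with its mean-coverage ratio relative to the other, which in a
#' parasitized specimen exposes the co-assembled organism (e.g. a water
#' mite at 10-fold the host coverage and ~95% identity). The default 97%
#' cut separates a 95%-identical foreign organism while tolerating
#' intraspecific variation.
#'
#' @param contigs list of [contig()] records.
#' @param host_reference a [ref_seq()].
#' @param identity_fn function(contig_sequence, host_sequence) -> percent
#'   identity; defaults to best local-alignment identity.
#' @param host_identity_min percent identity cut (default 97).
#' @return list with `host_bin`, `foreign_bin` (lists of contigs, each with
#'   an `identity` attribute), and `coverage_ratio` =
#'   mean(foreign coverage) / mean(host coverage) (NA when a bin is empty).
#' @export
bin_contigs <- function(contigs, host_reference, identity_fn = NULL,
                        host_identity_min = 97) {
  stopifnot(length(contigs) > 0L, inherits(host_reference, "ref_seq"))
  if (is.null(identity_fn))
    identity_fn <- function(a, b) alignment_identity(a, b)
  ident <- vapply(contigs, function(ct)
    identity_fn(ct$sequence, host_reference$sequence), numeric(1))
  is_host <- ident >= host_identity_min
  annotate <- function(idx) {
    lapply(idx, function(i) {
      ct <- contigs[[i]]
      attr(ct, "identity") <- ident[i]
      ct
    })
  }
  host_bin <- annotate(which(is_host))
  foreign_bin <- annotate(which(!is_host))
  mean_cov <- function(bin) {
    if (length(bin) == 0L) return(NA_real_)
    mean(vapply(bin, `[[`, numeric(1), "mean_coverage"))
  }
  list(host_bin = host_bin, foreign_bin = foreign_bin,
       coverage_ratio = mean_cov(foreign_bin) / mean_cov(host_bin))
}

#' Adapter for an external de Bruijn assembler
#'
#' Probes for the external binary on the PATH; if present, invokes it with
#' the k-mer list, mode flags, and (when supplied) a trusted-contigs FASTA,
#' then parses the resulting contig FASTA. Coverage is taken from headers
#' of the form `NODE_1_length_200_cov_12.5` when present, otherwise
#' computed by re-mapping `reads` when given, else reported as NA.
#'
#' @param kept_reads_path FASTA/FASTQ of kept reads.
#' @param spec an [assembler_spec()].
#' @param binary name of the assembler executable (default `"spades.py"`).
#' @param out_dir working directory for the assembler.
#' @param reads optional named character vector for coverage re-mapping.
#' @return list of [contig()] records.
#' @export
external_assembler_adapter <- function(kept_reads_path, spec,
                                       binary = "spades.py",
                                       out_dir = tempfile("asm"),
                                       reads = NULL) {
  stopifnot(inherits(spec, "assembler_spec"))
  path <- Sys.which(binary)
  if (!nzchar(path))
    stop("external assembler '", binary, "' not found on PATH; ",
         "use the internal greedy_assemble() fallback instead")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- c("-s", kept_reads_path, "-k",
            paste(spec$kmer_lengths, collapse = ","), spec$mode_flags,
            "-o", out_dir)
  if (!is.null(spec$trusted_contigs)) {
    tc <- file.path(out_dir, "trusted_contigs.fasta")
    write_fasta(setNames(vapply(spec$trusted_contigs, `[[`, "", "sequence"),
                         vapply(spec$trusted_contigs, `[[`, "", "id")), tc)
    args <- c(args, "--trusted-contigs", tc)
  }
  status <- system2(path, args, stdout = file.path(out_dir, "log.txt"),
                    stderr = file.path(out_dir, "log.txt"))
  if (status != 0L)
    stop("external assembler exited with status ", status, "; see ",
         file.path(out_dir, "log.txt"))
  parse_contig_fasta(file.path(out_dir, "contigs.fasta"), reads = reads)
}

#' Parse a contig FASTA into contig records
#'
#' Recognises the `NODE_<i>_length_<L>_cov_<c>` header dialect; headers
#' without a coverage field get coverage from re-mapping `reads` when
#' supplied, else NA coverage.
#'
#' @param path contig FASTA.
#' @param reads optional character vector of reads for coverage
#'   re-mapping.
#' @param params a [scoring_params()] for re-mapping.
#' @return list of [contig()] records.
#' @export
parse_contig_fasta <- function(path, reads = NULL,
                               params = scoring_params()) {
  seqs <- read_sequences(path)
  lapply(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    L <- nchar(seqs[[i]])
    m <- regmatches(nm, regexec("cov_([0-9.]+)", nm))[[1]]
    if (length(m) == 2L) {
      cov <- as.numeric(m[2])
      return(contig(nm, seqs[[i]], rep(cov, L)))
    }
    if (!is.null(reads)) {
      guide <- ref_seq(nm, seqs[[i]], "contig")
      ct <- tryCatch(guided_consensus(reads, guide, min_depth = 1L,
                                      params = params),
                     error = function(e) NULL)
      if (!is.null(ct))
        return(contig(nm, seqs[[i]], ct$per_base_coverage))
    }
    contig(nm, seqs[[i]], rep(NA_real_, L))
  })
}

#' Write contigs as FASTA (NODE-style headers) and a coverage TSV
#'
#' @param contigs list of [contig()] records.
#' @param fasta_path,tsv_path output paths.
#' @return named vector of paths, invisibly.
#' @export
write_contigs <- function(contigs, fasta_path, tsv_path = NULL) {
  hdr <- vapply(seq_along(contigs), function(i) {
    ct <- contigs[[i]]
    sprintf("NODE_%d_length_%d_cov_%s", i, nchar(ct$sequence),
            format(round(ct$mean_coverage, 6), trim = TRUE,
                   scientific = FALSE, drop0trailing = TRUE))
  }, "")
  write_fasta(setNames(vapply(contigs, `[[`, "", "sequence"), hdr),
              fasta_path)
  if (!is.null(tsv_path)) {
    df <- data.frame(id = vapply(contigs, `[[`, "", "id"),
                     length = vapply(contigs, function(ct)
                       nchar(ct$sequence), integer(1)),
                     mean_coverage = vapply(contigs, `[[`, numeric(1),
                                            "mean_coverage"),
                     mode = vapply(contigs, `[[`, "", "mode"))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta_path, tsv = tsv_path))
}
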