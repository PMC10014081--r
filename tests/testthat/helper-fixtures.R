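# Shared fixtures and the independent alignment oracle.

# Brute-force Smith-Waterman (Gotoh affine) scoring oracle, written as a
# plain dynamic program over full matrices, independent of the package's
# compiled scorer. Gap of length k costs gap_open + k * gap_extend.
sw_oracle <- function(a, b, match = 2, mismatch = -3, gap_open = -5,
                      gap_extend = -2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F_[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                      F_[i - 1, j] + gap_extend)
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] %in% c("A", "C", "G", "T"))
        match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# oracle analogue of best_hit_score: both strands, any reference, NA below
# the reporting threshold
oracle_best_hit <- function(read, refs, params = scoring_params()) {
  rc <- revcomp(read)
  best <- 0
  for (ref in refs) {
    best <- max(best,
                sw_oracle(read, ref, params$match, params$mismatch,
                          params$gap_open, params$gap_extend),
                sw_oracle(rc, ref, params$match, params$mismatch,
                          params$gap_open, params$gap_extend))
  }
  if (best < params$min_report_score) NA_integer_ else as.integer(best)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# write a small taxonomy FASTA and return its path
write_tax_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(records, function(r)
    c(paste0(">", r$id, " ", paste(r$taxonomy, collapse = ";")),
      r$sequence)))
  writeLines(lines, path)
  path
}

# three-record reference set: one insect, two others
tiny_records <- function() {
  list(ref_seq("ins1", strrep("ACGT", 30),
               c("Eukaryota", "Arthropoda", "Insecta", "Aedes aegypti")),
       ref_seq("vert1", strrep("GGCA", 30),
               c("Eukaryota", "Chordata", "Vertebrata", "Homo sapiens")),
       ref_seq("bact1", strrep("TTGC", 30),
               c("Bacteria", "Proteobacteria", "Escherichia coli")))
}

# deterministic scored-read table spanning all four categories
make_scored <- function(n, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cat_ <- sample(c("I_ONLY", "BOTH", "NO_I"), n, replace = TRUE,
                 prob = c(0.2, 0.6, 0.2))
  si <- ifelse(cat_ == "NO_I", NA_real_, round(runif(n, 50, 300)))
  sn <- ifelse(cat_ == "I_ONLY", NA_real_, round(runif(n, 50, 300)))
  scored_reads(sprintf("r%06d", seq_len(n)), si, sn)
}
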