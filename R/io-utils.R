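# Sequence I/O and small shared helpers. FASTA/FASTQ parsing goes through
# Biostrings; sequences are handled internally as named character vectors
# in the DNA alphabet {A,C,G,T,N} (U mapped to T at ingest).

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T; any other
#' character becomes N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  .rf_revcomp(toupper(x))
}

normalize_dna <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- gsub("[^ACGTN]", "N", x)
  x
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over Biostrings readers returning a named character vector.
#' The format is taken from the file extension (`.fq`/`.fastq` => FASTQ),
#' otherwise FASTA. Qualities, if any, are dropped.
#'
#' @param path file path.
#' @return named character vector of upper-case DNA sequences (U mapped to T).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  ss <- Biostrings::readBStringSet(path, format = fmt)
  out <- normalize_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.character(x), !is.null(names(x)))
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Evaluate expr with the RNG seeded, restoring prior RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate bases at the given positions to a uniformly random *different* base
substitute_bases <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}
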