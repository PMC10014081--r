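# Taxonomy-annotated rRNA reference handling: parsing SILVA-style headers,
# the two-partition (Insecta / Non-Insecta) library, and iterative
# augmentation with newly assembled sequences.

#' Construct a reference sequence record
#'
#' @param id record identifier (opaque string).
#' @param sequence nucleotide string; U is mapped to T, other non-ACGTN
#'   characters to N.
#' @param taxonomy character vector of rank names, root to leaf.
#' @return an object of class `ref_seq`.
#' @export
ref_seq <- function(id, sequence, taxonomy) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string (record ", id, ")")
  taxonomy <- as.character(taxonomy)
  if (length(taxonomy) == 0L || any(!nzchar(taxonomy)))
    stop("taxonomy must be a non-empty list of rank names (record ", id, ")")
  structure(list(id = id, sequence = sequence, taxonomy = taxonomy),
            class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat(sprintf("<ref_seq %s: %d nt; %s>\n", x$id, nchar(x$sequence),
              paste(x$taxonomy, collapse = ";")))
  invisible(x)
}

#' Parse a FASTA file with semicolon-delimited taxonomy headers
#'
#' Headers follow the SILVA dialect: `>ID root;rank1;...;leaf`, i.e. the
#' taxonomy string is everything after the first whitespace, split on `;`.
#' U is mapped to T so RNA-alphabet databases and DNA reads share one
#' alphabet. A header without a taxonomy string is an error; records are
#' never silently bucketed.
#'
#' @param path path to a FASTA file (or connection readable by Biostrings).
#' @return list of [ref_seq()] records.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 Eukaryota;Arthropoda;Insecta;Aedes aegypti", "ACGU"), tf)
#' parse_taxonomy_fasta(tf)
parse_taxonomy_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) return(list())
  headers <- names(ss)
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    h <- headers[i]
    id <- sub("\\s.*$", "", h)
    rest <- sub("^\\S+\\s*", "", h)
    if (!nzchar(rest) || identical(rest, h))
      stop("header without taxonomy: record '", id, "'")
    tax <- trimws(strsplit(rest, ";", fixed = TRUE)[[1]])
    tax <- tax[nzchar(tax)]
    if (length(tax) == 0L)
      stop("header without taxonomy: record '", id, "'")
    out[[i]] <- ref_seq(id, as.character(ss[[i]]), tax)
  }
  out
}

#' Partition references at a taxonomy node
#'
#' A record goes to the anchored (Insecta) side iff `anchor_node` equals one
#' of its taxonomy ranks exactly — substring matches such as "Insectarium"
#' do not count. The partition is disjoint and exhaustive by construction.
#'
#' @param records list of [ref_seq()] records.
#' @param anchor_node rank name to cut at (default `"Insecta"`).
#' @return an object of class `lib_partition` with elements `anchor_node`,
#'   `insecta`, `non_insecta` (lists of `ref_seq`), and `cycle` (0).
#' @export
partition_by_node <- function(records, anchor_node = "Insecta") {
  stopifnot(length(records) > 0L)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    # keep the first occurrence of each id; partition counts distinct ids
    records <- records[!duplicated(ids)]
  }
  hit <- vapply(records, function(r) anchor_node %in% r$taxonomy, logical(1))
  structure(list(anchor_node = anchor_node,
                 insecta = records[hit],
                 non_insecta = records[!hit],
                 cycle = 0L),
            class = "lib_partition")
}

#' @export
print.lib_partition <- function(x, ...) {
  cat(sprintf("<lib_partition anchor=%s cycle=%d: %d %s, %d non-%s>\n",
              x$anchor_node, x$cycle, length(x$insecta), x$anchor_node,
              length(x$non_insecta), x$anchor_node))
  invisible(x)
}

partition_ids <- function(partition) {
  c(vapply(partition$insecta, `[[`, "", "id"),
    vapply(partition$non_insecta, `[[`, "", "id"))
}

#' Augment the Insecta library with assembled sequences
#'
#' Implements the iterative filtration cycles: complete sequences assembled
#' in one cycle are added to the Insecta side before the next. New records
#' lacking the anchor rank are re-annotated with taxonomy
#' `c(anchor_node, "assembled", id)` so the partition invariant holds.
#' Adding a sequence already present (same id and sequence) is idempotent;
#' an id collision with a different sequence is an error.
#'
#' @param partition a `lib_partition`.
#' @param new_sequences list of [ref_seq()] records (or named character
#'   vector of sequences).
#' @return the augmented `lib_partition`, with `cycle` incremented.
#' @export
augment_insecta <- function(partition, new_sequences) {
  stopifnot(inherits(partition, "lib_partition"))
  if (is.character(new_sequences)) {
    stopifnot(!is.null(names(new_sequences)))
    new_sequences <- lapply(names(new_sequences), function(nm)
      ref_seq(nm, new_sequences[[nm]],
              c(partition$anchor_node, "assembled", nm)))
  }
  existing <- c(partition$insecta, partition$non_insecta)
  names(existing) <- vapply(existing, `[[`, "", "id")
  for (r in new_sequences) {
    stopifnot(inherits(r, "ref_seq"))
    if (r$id %in% names(existing)) {
      if (!identical(existing[[r$id]]$sequence, r$sequence))
        stop("id collision with a different sequence: '", r$id, "'")
      next  # identical id+sequence: idempotent
    }
    if (!(partition$anchor_node %in% r$taxonomy))
      r$taxonomy <- c(partition$anchor_node, "assembled", r$id)
    partition$insecta <- c(partition$insecta, list(r))
    existing[[r$id]] <- r
  }
  partition$cycle <- partition$cycle + 1L
  partition
}

#' Write a library partition to FASTA plus a JSON manifest
#'
#' Emits `insecta.fasta` and `non_insecta.fasta` (headers carry the
#' semicolon-joined taxonomy) suitable as external aligner databases, and
#' `partition.json` with counts and the cycle number.
#'
#' @param partition a `lib_partition`.
#' @param dir output directory (created if missing).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "lib_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_fa <- function(recs) {
    if (length(recs) == 0L) return(character(0))
    setNames(vapply(recs, `[[`, "", "sequence"),
             vapply(recs, function(r)
               paste(r$id, paste(r$taxonomy, collapse = ";")), ""))
  }
  paths <- c(insecta = file.path(dir, "insecta.fasta"),
             non_insecta = file.path(dir, "non_insecta.fasta"),
             manifest = file.path(dir, "partition.json"))
  write_fasta(as_fa(partition$insecta), paths[["insecta"]])
  write_fasta(as_fa(partition$non_insecta), paths[["non_insecta"]])
  jsonlite::write_json(list(anchor_node = partition$anchor_node,
                            n_insecta = length(partition$insecta),
                            n_non_insecta = length(partition$non_insecta),
                            cycle = partition$cycle),
                       paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
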