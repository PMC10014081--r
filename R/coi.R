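# COI barcode workflow: quality/anchor trimming of Sanger read pairs,
# overlap consensus construction, and rule-based species assignment used to
# validate morphological identification.

#' Folmer COI primer pair
#'
#' The universal LCO1490/HCO2198 primer pair amplifying the standard
#' 658 bp COI barcode fragment.
#' @export
folmer_primers <- c(
  LCO1490 = "GGTCAACAAATCATAAAGATATTGG",
  HCO2198 = "TAAACTTCAGGGTGACCAAAAAATCA")

# 5' anchors at which trimmed sequences are made to start (N = any base)
COI_ANCHOR_FORWARD <- "TTTTGG"
COI_ANCHOR_REVERSE <- "GGNTCT"

#' Construct a Sanger read
#'
#' @param direction `"forward"` or `"reverse"`.
#' @param sequence DNA string (may contain N).
#' @param qualities optional integer Phred scores, one per base.
#' @return an object of class `sanger_read`.
#' @export
sanger_read <- function(direction = c("forward", "reverse"), sequence,
                        qualities = NULL) {
  direction <- match.arg(direction)
  sequence <- normalize_dna(sequence)
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    stopifnot(length(qualities) == nchar(sequence))
  }
  structure(list(direction = direction, sequence = sequence,
                 qualities = qualities),
            class = "sanger_read")
}

#' @export
print.sanger_read <- function(x, ...) {
  cat(sprintf("<sanger_read %s: %d nt%s>\n", x$direction, nchar(x$sequence),
              if (is.null(x$qualities)) "" else ", with qualities"))
  invisible(x)
}

# first match position of an IUPAC-N anchor, 0 if absent
anchor_position <- function(sequence, anchor) {
  pat <- gsub("N", ".", anchor, fixed = TRUE)
  m <- regexpr(pat, sequence)
  if (m < 0) 0L else as.integer(m)
}

default_anchor <- function(read) {
  if (read$direction == "forward") COI_ANCHOR_FORWARD else COI_ANCHOR_REVERSE
}

#' Quality- and anchor-trim a Sanger read
#'
#' Bases are trimmed from both ends while their quality is below
#' `quality_floor` (when qualities are present); the read is then
#' 5'-trimmed so that it starts exactly at the first occurrence of the
#' anchor motif (N in the anchor matches any base). Trimming a trimmed
#' read is a no-op.
#'
#' @param read a [sanger_read()].
#' @param quality_floor Phred floor (default 30).
#' @param anchor 5' anchor motif; defaults to `TTTTGG` for forward reads
#'   and `GGNTCT` for reverse reads.
#' @return the trimmed [sanger_read()].
#' @export
trim_read <- function(read, quality_floor = 30L, anchor = NULL) {
  stopifnot(inherits(read, "sanger_read"))
  if (is.null(anchor)) anchor <- default_anchor(read)
  seq_ <- read$sequence
  qual <- read$qualities
  if (!is.null(qual)) {
    n <- length(qual)
    lo <- 1L
    while (lo <= n && qual[lo] < quality_floor) lo <- lo + 1L
    hi <- n
    while (hi >= lo && qual[hi] < quality_floor) hi <- hi - 1L
    if (lo > hi) stop("anchor not found: read entirely below Q",
                      quality_floor)
    seq_ <- substr(seq_, lo, hi)
    qual <- qual[lo:hi]
  }
  pos <- anchor_position(seq_, anchor)
  if (pos == 0L) stop("anchor not found: '", anchor,
                      "' absent after quality trimming")
  seq_ <- substr(seq_, pos, nchar(seq_))
  if (!is.null(qual)) qual <- qual[pos:length(qual)]
  sanger_read(read$direction, seq_, qual)
}

#' Build a consensus from a trimmed forward/reverse Sanger pair
#'
#' The reverse read is reverse-complemented, the best local alignment of
#' the two defines the overlap, and the consensus spans forward prefix +
#' overlap + reverse suffix. Overlap disagreements are resolved by the
#' higher-quality base; with no qualities the forward base wins. An
#' overlap shorter than `min_overlap_length` or with identity below
#' `min_overlap_identity` aborts ("read pair discordant"). Consensus
#' sequences longer than `max_length` are trimmed
#' at the 3' end; the result carries attribute `full_length`, TRUE when
#' the doubly/singly covered span reaches `target_length`.
#'
#' @param forward,reverse trimmed [sanger_read()]s.
#' @param min_overlap_identity percent identity floor for the overlap
#'   (default 98).
#' @param min_overlap_length minimum overlap length in alignment columns
#'   (default 30; spurious short matches between unrelated reads fall
#'   below this).
#' @param target_length nominal barcode length (default 621).
#' @param max_length maximum reported length (default 699).
#' @param params a [scoring_params()] for the overlap alignment.
#' @return the consensus DNA string with attributes `full_length` and
#'   `overlap_length`.
#' @export
build_consensus <- function(forward, reverse, min_overlap_identity = 98,
                            min_overlap_length = 30L,
                            target_length = 621L, max_length = 699L,
                            params = scoring_params()) {
  stopifnot(inherits(forward, "sanger_read"),
            inherits(reverse, "sanger_read"))
  f <- forward$sequence
  r <- revcomp(reverse$sequence)
  rq <- if (is.null(reverse$qualities)) NULL else rev(reverse$qualities)
  al <- .rf_sw_align(f, r, params$match, params$mismatch, params$gap_open,
                     params$gap_extend)
  qa <- strsplit(al$q_aln, "", fixed = TRUE)[[1]]
  ra <- strsplit(al$r_aln, "", fixed = TRUE)[[1]]
  if (length(qa) < min_overlap_length)
    stop("read pair discordant: overlap of ", length(qa),
         " columns is shorter than ", min_overlap_length)
  ident <- 100 * sum(qa == ra) / length(qa)
  if (ident < min_overlap_identity)
    stop(sprintf("read pair discordant: overlap identity %.1f%% < %.1f%%",
                 ident, min_overlap_identity))
  fq <- forward$qualities
  # walk the overlap, resolving disagreements
  fi <- al$q_start; ri <- al$r_start
  ov <- character(length(qa))
  for (k in seq_along(qa)) {
    if (qa[k] == ra[k]) {
      ov[k] <- qa[k]
    } else if (qa[k] == "-") {
      ov[k] <- ""                       # base only in reverse: insertion
      # kept only if reverse strongly supported; forward wins by default
    } else if (ra[k] == "-") {
      ov[k] <- qa[k]
    } else {
      qf <- if (!is.null(fq)) fq[fi] else NA_integer_
      qr <- if (!is.null(rq)) rq[ri] else NA_integer_
      ov[k] <- if (!is.na(qf) && !is.na(qr) && qr > qf) ra[k] else qa[k]
    }
    if (qa[k] != "-") fi <- fi + 1L
    if (ra[k] != "-") ri <- ri + 1L
  }
  cons <- paste0(substr(f, 1L, al$q_start - 1L),
                 paste(ov, collapse = ""),
                 substr(r, al$r_end + 1L, nchar(r)))
  full <- nchar(cons) >= target_length
  if (nchar(cons) > max_length) cons <- substr(cons, 1L, max_length)
  structure(cons, full_length = full, overlap_length = length(qa))
}

#' Construct a species-call record
#'
#' @param status one of `confirmed`, `revised`, `ambiguous_sister_species`,
#'   `genus_only`, `no_reference`.
#' @param species binomial species name or NA.
#' @param genus genus name or NA.
#' @param evidence data.frame of (reference_name, percent_identity).
#' @return an object of class `species_call`.
#' @export
species_call <- function(status, species = NA_character_,
                         genus = NA_character_, evidence = NULL) {
  status <- match.arg(status, c("confirmed", "revised",
                                "ambiguous_sister_species", "genus_only",
                                "no_reference"))
  if (status == "genus_only" && (is.na(genus) || !is.na(species)))
    stop("genus_only requires a genus and no species")
  if (status %in% c("confirmed", "revised") && is.na(species))
    stop(status, " requires a species")
  structure(list(status = status, species = species, genus = genus,
                 evidence = evidence),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  lab <- switch(x$status,
                confirmed = paste("confirmed:", x$species),
                revised = paste("revised to:", x$species),
                ambiguous_sister_species =
                  paste("ambiguous sister species; retained:", x$species),
                genus_only = paste0("genus only: ", x$genus, " sp."),
                no_reference = "no reference")
  cat("<species_call ", lab, ">\n", sep = "")
  invisible(x)
}

species_of <- function(name) {
  w <- strsplit(trimws(name), "\\s+")[[1]]
  if (length(w) >= 2L) paste(w[1:2], collapse = " ") else w[1]
}

genus_of <- function(name) strsplit(trimws(name), "\\s+")[[1]][1]

#' Assign a species identity from ranked barcode hits
#'
#' Applies the barcode decision rules against a morphological
#' identification. With `species_threshold` (default 95%, the species
#' delineation threshold) and `revision_margin` (default 2%):
#' \enumerate{
#'   \item no hits at or above the threshold, but all hit species share one
#'     genus: `genus_only` ("unknown member of their genus");
#'   \item the top two distinct-species hits are within one substitution's
#'     worth of identity (100/`consensus_length` percent):
#'     `ambiguous_sister_species`, the morphological id is retained;
#'   \item top hit passes the threshold and matches the morphological id:
#'     `confirmed`;
#'   \item top hit passes, differs from the morphological id, and beats the
#'     morphological species' own best identity by more than the margin:
#'     `revised` to the top-hit species;
#'   \item top hit differs but the margin is not exceeded:
#'     `ambiguous_sister_species`;
#'   \item otherwise `no_reference`.
#' }
#' When the morphological species has no reference among the hits, its
#' baseline identity is the best hit of any other species than the top-hit
#' species (the comparison the sister-species check performs); with no such
#' hit a qualifying top hit revises.
#'
#' @param morphological_id binomial from morphological keys (may be NA).
#' @param hits data.frame with columns `reference_name` and
#'   `percent_identity`, sorted by identity descending (re-sorted if not).
#' @param species_threshold percent identity delineating species
#'   (default 95).
#' @param revision_margin percent margin a revision must exceed
#'   (default 2).
#' @param consensus_length barcode length defining "one substitution's
#'   worth" (default 621).
#' @return a [species_call()].
#' @export
assign_species <- function(morphological_id, hits, species_threshold = 95,
                           revision_margin = 2, consensus_length = 621L) {
  no_hits <- is.null(hits) || nrow(hits) == 0L
  if (no_hits && (is.null(morphological_id) || is.na(morphological_id)))
    stop("empty hit list and no morphological id")
  if (no_hits)
    return(species_call("no_reference", genus = genus_of(morphological_id),
                        evidence = hits))
  stopifnot(all(c("reference_name", "percent_identity") %in% names(hits)))
  hits <- hits[order(-hits$percent_identity), , drop = FALSE]
  hit_species <- unname(vapply(hits$reference_name, species_of, ""))
  hit_genus <- unname(vapply(hits$reference_name, genus_of, ""))
  morph_species <- if (is.null(morphological_id) || is.na(morphological_id))
    NA_character_ else species_of(morphological_id)
  qualifying <- hits$percent_identity >= species_threshold
  # (1) nothing at species level, but a single genus throughout
  if (!any(qualifying)) {
    if (length(unique(hit_genus)) == 1L)
      return(species_call("genus_only", genus = hit_genus[1],
                          evidence = hits))
    if (!is.na(morph_species) && !(morph_species %in% hit_species))
      return(species_call("no_reference", genus = genus_of(morph_species),
                          evidence = hits))
    return(species_call("ambiguous_sister_species", species = morph_species,
                        genus = genus_of(if (!is.na(morph_species))
                          morph_species else hit_species[1]),
                        evidence = hits))
  }
  top <- hits$percent_identity[1]
  top_species <- hit_species[1]
  # (2) sister-species ambiguity: top two distinct species within one
  # substitution's worth of identity
  one_sub <- 100 / consensus_length
  other <- which(hit_species != top_species)
  if (length(other) > 0L &&
      top - hits$percent_identity[other[1]] <= one_sub &&
      hits$percent_identity[other[1]] >= species_threshold) {
    retained <- if (!is.na(morph_species)) morph_species else top_species
    return(species_call("ambiguous_sister_species", species = retained,
                        genus = genus_of(retained), evidence = hits))
  }
  # (3) confirmation
  if (!is.na(morph_species) && top_species == morph_species)
    return(species_call("confirmed", species = morph_species,
                        genus = genus_of(morph_species), evidence = hits))
  # (4) revision: must beat the morphological species' own identity by
  # more than the margin
  baseline <- if (!is.na(morph_species) && morph_species %in% hit_species)
    max(hits$percent_identity[hit_species == morph_species])
  else if (length(other) > 0L) max(hits$percent_identity[other])
  else NA_real_
  if (is.na(morph_species) || is.na(baseline) ||
      top - baseline > revision_margin)
    return(species_call("revised", species = top_species,
                        genus = genus_of(top_species), evidence = hits))
  # (5) margin not exceeded
  species_call("ambiguous_sister_species", species = morph_species,
               genus = genus_of(morph_species), evidence = hits)
}

#' Write species calls as a TSV table
#'
#' @param calls list of [species_call()] records, optionally named by
#'   specimen.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_calls <- function(calls, path) {
  df <- data.frame(
    specimen = if (!is.null(names(calls))) names(calls)
               else sprintf("specimen_%d", seq_along(calls)),
    status = vapply(calls, `[[`, "", "status"),
    species = vapply(calls, function(x)
      ifelse(is.na(x$species), "", x$species), ""),
    genus = vapply(calls, function(x)
      ifelse(is.na(x$genus), "", x$genus), ""),
    top_hit_identity = vapply(calls, function(x)
      if (is.null(x$evidence) || nrow(x$evidence) == 0L) NA_real_
      else max(x$evidence$percent_identity), numeric(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
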