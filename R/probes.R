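# Antisense probe tiling for hybridization ribodepletion: non-overlapping
# windows along each target rRNA, reverse-complemented into DNA probes
# (e.g. 80-mers tiled over 28S, 18S, and 5.8S).

#' Tile antisense probes over target rRNA sequences
#'
#' Windows `[0,L), [L,2L), ...` are cut per target and reverse-complemented
#' into probes. When the target length is not a multiple of the probe
#' length, `remainder_policy` decides the 3' end: `"right_anchor"`
#' (default) adds a final window `[len-L, len)` overlapping the previous
#' one so the whole target is covered — variable 3' ends matter for
#' depletion — while `"drop"` leaves the remainder uncovered.
#'
#' @param targets list of [ref_seq()] records (each at least `probe_len`
#'   long).
#' @param probe_len probe length in nt (default 80).
#' @param remainder_policy `"right_anchor"` or `"drop"`.
#' @return data.frame with columns `id`, `sequence` (5'->3' antisense),
#'   `target_id`, `target_start`, `target_end` (0-based half-open, sense
#'   strand).
#' @export
#' @examples
#' t1 <- ref_seq("t1", strrep("ATGC", 20), "Insecta")
#' tile_probes(list(t1))
tile_probes <- function(targets, probe_len = 80L,
                        remainder_policy = c("right_anchor", "drop")) {
  remainder_policy <- match.arg(remainder_policy)
  stopifnot(probe_len >= 1L)
  if (inherits(targets, "ref_seq")) targets <- list(targets)
  rows <- list()
  for (tg in targets) {
    stopifnot(inherits(tg, "ref_seq"))
    len <- nchar(tg$sequence)
    if (len < probe_len)
      stop("target '", tg$id, "' is shorter (", len,
           " nt) than the probe length (", probe_len, ")")
    starts <- seq.int(0L, (len %/% probe_len) * probe_len - probe_len,
                      by = probe_len)
    if (remainder_policy == "right_anchor" && len %% probe_len != 0L)
      starts <- c(starts, len - probe_len)
    for (s in starts) {
      window <- substr(tg$sequence, s + 1L, s + probe_len)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_probe_%04d", tg$id, s),
        sequence = revcomp(window),
        target_id = tg$id,
        target_start = s,
        target_end = s + probe_len,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build an order-sheet manifest for a probe pool
#'
#' One row per probe (id, 5'->3' sequence, target, coordinates) plus pool
#' metadata; duplicate probe sequences (which arise when conserved blocks
#' repeat across targets) are flagged.
#'
#' @param probes data.frame from [tile_probes()].
#' @param pool_concentration pool concentration in micromolar
#'   (default 0.04).
#' @return data.frame with an added `duplicate` flag column and attributes
#'   `pool_concentration_uM` and `n_probes`.
#' @export
probe_pool_manifest <- function(probes, pool_concentration = 0.04) {
  stopifnot(is.data.frame(probes), nrow(probes) > 0L)
  if (is.null(pool_concentration) || !length(pool_concentration))
    pool_concentration <- 0.04
  out <- probes
  out$duplicate <- duplicated(probes$sequence) |
    duplicated(probes$sequence, fromLast = TRUE)
  attr(out, "pool_concentration_uM") <- pool_concentration
  attr(out, "n_probes") <- nrow(out)
  out
}

#' Write probe FASTA and order-sheet TSV
#'
#' @param probes data.frame from [tile_probes()] or
#'   [probe_pool_manifest()].
#' @param fasta_path,tsv_path output paths.
#' @return named vector of paths, invisibly.
#' @export
write_probes <- function(probes, fasta_path, tsv_path) {
  write_fasta(setNames(probes$sequence, probes$id), fasta_path)
  write.table(probes, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta_path, tsv = tsv_path))
}
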