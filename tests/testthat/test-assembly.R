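# Assembly: greedy exact-overlap merging, guided consensus, polishing,
# contig binning, and the external-assembler adapter contract.

test_that("greedy assembly reconstructs a tiled source exactly", {
  set.seed(41)
  src <- rand_dna(60)
  reads <- c(substr(src, 1, 30), substr(src, 21, 50), substr(src, 41, 60))
  ct <- greedy_assemble(reads, min_overlap = 10)
  expect_length(ct, 1L)
  expect_true(ct[[1]]$sequence %in% c(src, revcomp(src)))
  expect_equal(length(ct[[1]]$per_base_coverage), 60L)
  expect_equal(sum(ct[[1]]$per_base_coverage),
               sum(nchar(reads)))  # coverage conserves read bases

  # overlaps on the reverse strand merge too
  reads_rc <- c(substr(src, 1, 30), revcomp(substr(src, 21, 50)))
  ct2 <- greedy_assemble(reads_rc, min_overlap = 10)
  expect_length(ct2, 1L)
  expect_equal(nchar(ct2[[1]]$sequence), 50L)
})

test_that("unmergeable reads become singleton contigs", {
  # note poly-AC vs poly-GT would reverse-complement into each other;
  # these two share nothing on either strand
  r1 <- strrep("A", 40)
  r2 <- strrep("C", 40)
  ct <- greedy_assemble(c(r1, r2), min_overlap = 15)
  expect_length(ct, 2L)
  # single read: identity, all-1 coverage
  ct1 <- greedy_assemble("ACGTACGTACGT", min_overlap = 4)
  expect_equal(ct1[[1]]$sequence, "ACGTACGTACGT")
  expect_equal(ct1[[1]]$per_base_coverage, rep(1, 12))
  expect_equal(ct1[[1]]$mean_coverage, 1)
  expect_equal(ct1[[1]]$mode, "de_novo")
})

test_that("greedy assembly is deterministic under input permutation ties", {
  set.seed(42)
  src <- rand_dna(120)
  reads <- vapply(seq(1, 91, by = 10), function(s)
    substr(src, s, s + 29), "")
  ct_a <- greedy_assemble(reads, 15)
  ct_b <- greedy_assemble(rev(reads), 15)
  expect_equal(vapply(ct_a, `[[`, "", "sequence"),
               vapply(ct_b, `[[`, "", "sequence"))
})

test_that("guided consensus recovers the true source through a relative", {
  arch <- rrna_architecture("SSU", total_length = 1000,
                            blocks = data.frame(
                              kind = c("conserved", "variable",
                                       "conserved"),
                              length = c(400, 200, 400)))
  truth <- make_reference(arch, seed = 43, id = "truth")
  # a uniformly ~97%-identical relative acts as the trusted guide
  set.seed(44)
  guide_seq <- local({
    ch <- strsplit(truth$sequence, "")[[1]]
    for (i in which(runif(1000) < 0.03))
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  })
  guide <- ref_seq("guide", guide_seq, c("Insecta", "relative"))
  # error-free reads at 20x
  mix <- specimen_mix(host_fraction = 1, read_length = 150,
                      error_rate = 0, n_reads = 135, seed = 45)
  reads <- simulate_specimen(mix, list(host = truth))
  cons <- guided_consensus(reads$sequence, guide, min_depth = 2)
  expect_equal(cons$mode, "guided")
  expect_equal(cons$guide_id, "guide")
  expect_equal(nchar(cons$sequence), 1000L)
  # columns called from the reads match the true source exactly; columns
  # that fell back to the guide (coverage ramp at the gene ends) are
  # flagged and excluded from the exactness claim
  called <- setdiff(seq_len(1000L), attr(cons, "low_depth"))
  expect_gt(length(called), 900L)
  tch <- strsplit(truth$sequence, "")[[1]]
  cch <- strsplit(cons$sequence, "")[[1]]
  expect_identical(cch[called], tch[called])
  expect_gte(ribofilt:::alignment_identity(cons$sequence,
                                           truth$sequence), 99.5)

  # 1% substitution errors at 30x still give >= 99.5% identity
  mix_err <- specimen_mix(host_fraction = 1, read_length = 150,
                          error_rate = 0.01, n_reads = 200, seed = 46)
  reads_err <- simulate_specimen(mix_err, list(host = truth))
  cons_err <- guided_consensus(reads_err$sequence, guide, min_depth = 2)
  expect_gte(ribofilt:::alignment_identity(cons_err$sequence,
                                           truth$sequence), 99.5)

  # degenerate inputs
  expect_error(guided_consensus(character(0), guide), "empty")
  set.seed(47)
  unrelated <- replicate(5, rand_dna(150))
  expect_error(guided_consensus(unrelated, guide), "unrelated")
})

test_that("guided consensus is idempotent on its own output", {
  arch <- rrna_architecture("SSU", total_length = 600,
                            blocks = data.frame(kind = "conserved",
                                                length = 600),
                            variable_divergence = 0.2)
  truth <- make_reference(arch, seed = 48, id = "t")
  mix <- specimen_mix(host_fraction = 1, read_length = 120,
                      error_rate = 0, n_reads = 60, seed = 49)
  reads <- simulate_specimen(mix, list(host = truth))
  c1 <- guided_consensus(reads$sequence, truth, min_depth = 1)
  # reads re-simulated from c1's sequence reproduce it
  guide2 <- ref_seq("c1", c1$sequence, "contig")
  mix2 <- specimen_mix(host_fraction = 1, read_length = 120,
                       error_rate = 0, n_reads = 60, seed = 50)
  reads2 <- simulate_specimen(mix2, list(host = guide2))
  c2 <- guided_consensus(reads2$sequence, guide2, min_depth = 1)
  expect_equal(c2$sequence, c1$sequence)
})

test_that("contig binning separates host from a 95%-identical foreign", {
  set.seed(51)
  host_ref <- ref_seq("host", rand_dna(800), c("Insecta", "host"))
  # foreign at ~95% identity, 10x the coverage
  foreign_seq <- local({
    ch <- strsplit(host_ref$sequence, "")[[1]]
    idx <- sample(800, 40)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  })
  host_ct <- contig("c_host", host_ref$sequence, rep(10, 800))
  mite_ct <- contig("c_mite", foreign_seq, rep(100, 800))
  bins <- bin_contigs(list(host_ct, mite_ct), host_ref)
  expect_equal(vapply(bins$host_bin, `[[`, "", "id"), "c_host")
  expect_equal(vapply(bins$foreign_bin, `[[`, "", "id"), "c_mite")
  expect_equal(bins$coverage_ratio, 10)
  expect_lt(attr(bins$foreign_bin[[1]], "identity"), 97)

  # conservation: bins partition the contigs
  expect_equal(length(bins$host_bin) + length(bins$foreign_bin), 2L)

  # single perfect contig -> empty foreign bin
  b1 <- bin_contigs(list(host_ct), host_ref)
  expect_length(b1$foreign_bin, 0L)
  # everything below the identity floor -> empty host bin (misidentified
  # specimen signal)
  b2 <- bin_contigs(list(mite_ct), host_ref)
  expect_length(b2$host_bin, 0L)
})

test_that("external assembler adapter: probe, parse, round trip", {
  spec_ <- assembler_spec()
  expect_equal(spec_$kmer_lengths, c(31L, 51L, 71L))
  expect_error(
    external_assembler_adapter("reads.fasta", spec_,
                               binary = "no_such_assembler_xyz"),
    "greedy_assemble")

  # NODE header dialect carries coverage
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">NODE_1_length_200_cov_12.5", strrep("ACGT", 50)), tf)
  ct <- parse_contig_fasta(tf)
  expect_equal(ct[[1]]$mean_coverage, 12.5)
  expect_equal(nchar(ct[[1]]$sequence), 200L)

  # round trip: internal assembler output written and re-parsed
  set.seed(52)
  src <- rand_dna(300)
  reads <- vapply(seq(1, 251, by = 25), function(s)
    substr(src, s, s + 49), "")
  ctgs <- greedy_assemble(reads, 20)
  out <- tempfile(fileext = ".fasta")
  write_contigs(ctgs, out)
  back <- parse_contig_fasta(out)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(ctgs, `[[`, "", "sequence"))
  expect_equal(vapply(back, `[[`, numeric(1), "mean_coverage"),
               vapply(ctgs, function(x) round(x$mean_coverage, 6),
                      numeric(1)))
})

test_that("polishing outvotes singleton read errors", {
  set.seed(53)
  src <- rand_dna(500)
  # error-free tiling reads plus one read with a corrupted interior
  starts <- seq(1, 351, by = 25)
  reads <- vapply(starts, function(s) substr(src, s, s + 149), "")
  bad <- reads[5]
  substr(bad, 75, 75) <- if (substr(bad, 75, 75) == "A") "C" else "A"
  ctgs <- greedy_assemble(c(reads, bad), 40)
  polished <- polish_contigs(ctgs, c(reads, bad), min_length = 300)
  main <- polished[[which.max(vapply(polished, function(x)
    nchar(x$sequence), integer(1)))]]
  al_id <- ribofilt:::alignment_identity(main$sequence, src)
  expect_equal(al_id, 100)
})
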