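# Synthetic-data generators: determinism, block-wise divergence, read
# mixtures with truth labels, and the classifier benchmark they enable.

test_that("references have the stated gene lengths and are deterministic", {
  lsu <- make_reference(rrna_architecture("LSU"), seed = 1)
  ssu <- make_reference(rrna_architecture("SSU"), seed = 1)
  expect_equal(nchar(lsu$sequence), 3900L)
  expect_equal(nchar(ssu$sequence), 1900L)
  expect_equal(make_reference(rrna_architecture("LSU"), seed = 1)$sequence,
               lsu$sequence)
  expect_false(make_reference(rrna_architecture("LSU"),
                              seed = 2)$sequence == lsu$sequence)
  # block lengths tile the gene
  expect_equal(sum(rrna_architecture("LSU")$blocks$length), 3900L)
})

test_that("derived relatives diverge block-wise within binomial bounds", {
  arch <- rrna_architecture("SSU", total_length = 1200,
                            blocks = data.frame(
                              kind = c("conserved", "variable",
                                       "conserved"),
                              length = c(400, 400, 400)),
                            conserved_divergence = 0.02,
                            variable_divergence = 0.2)
  base <- make_reference(arch, seed = 81)
  rel <- derive_relative(base, arch, c("Insecta", "rel"), seed = 82)
  diff_at <- function(a, b, from, to) {
    sum(strsplit(substr(a, from, to), "")[[1]] !=
          strsplit(substr(b, from, to), "")[[1]])
  }
  # variable block: ~80 substitutions, within 3 sigma of Binomial(400, .2)
  v <- diff_at(base$sequence, rel$sequence, 401, 800)
  expect_lt(abs(v - 400 * 0.2), 3 * sqrt(400 * 0.2 * 0.8))
  # conserved blocks: ~8 each, within 3 sigma of Binomial(400, .02)
  for (blk in list(c(1, 400), c(801, 1200))) {
    cd <- diff_at(base$sequence, rel$sequence, blk[1], blk[2])
    expect_lt(abs(cd - 400 * 0.02), 3 * sqrt(400 * 0.02 * 0.98))
  }
  # zero conserved divergence leaves conserved blocks untouched
  arch0 <- rrna_architecture("SSU", total_length = 1200,
                             blocks = arch$blocks,
                             conserved_divergence = 0,
                             variable_divergence = 0.2)
  rel0 <- derive_relative(base, arch0, c("Insecta", "rel0"), seed = 83)
  expect_equal(substr(rel0$sequence, 1, 400), substr(base$sequence, 1, 400))
  # overall identity lies between the block-weighted extremes
  total_diff <- diff_at(base$sequence, rel$sequence, 1, 1200)
  expect_gt(total_diff / 1200, 0.02 * 0.5)
  expect_lt(total_diff / 1200, 0.2)
})

test_that("specimen simulation honours fractions, windows, and the seed", {
  arch <- rrna_architecture("SSU", total_length = 800,
                            blocks = data.frame(kind = c("conserved",
                                                         "variable"),
                                                length = c(500, 300)))
  host <- make_reference(arch, seed = 84, id = "host")
  blood <- derive_relative(host, arch, c("Vertebrata", "blood"),
                           seed = 85, id = "blood")
  refs <- list(host = host, blood = blood)
  mix <- specimen_mix(host_fraction = 0.7,
                      contaminants = data.frame(label = "blood",
                                                ref_id = "blood",
                                                fraction = 0.3),
                      read_length = 100, error_rate = 0,
                      n_reads = 10000L, seed = 86)
  reads <- simulate_specimen(mix, refs)
  expect_equal(nrow(reads), 10000L)
  # host-origin count within 3 sigma of Binomial(10000, 0.7)
  nh <- sum(reads$origin == "host")
  expect_lt(abs(nh - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
  # error-free reads are exact substrings of their origin (up to strand)
  idx <- sample(nrow(reads), 50)
  for (i in idx) {
    ref <- refs[[if (reads$origin[i] == "host") "host" else "blood"]]
    window <- substr(ref$sequence, reads$start[i], reads$end[i])
    expected <- if (reads$strand[i] == "-") revcomp(window) else window
    expect_equal(reads$sequence[i], expected)
  }
  # determinism under the mix seed
  reads2 <- simulate_specimen(mix, refs)
  expect_identical(reads, reads2)
  # truth labels are total
  expect_false(anyNA(reads$origin))
  expect_false(anyNA(reads$start))
})

test_that("window kinds classify conserved vs variable-touching reads", {
  arch <- rrna_architecture("SSU", total_length = 500,
                            blocks = data.frame(kind = c("conserved",
                                                         "variable"),
                                                length = c(300, 200)))
  expect_equal(window_kind(arch, c(1, 250, 301), c(100, 350, 400)),
               c("conserved", "variable", "variable"))
})

test_that("COI pair simulation is deterministic with the stated geometry", {
  sim <- simulate_coi_pair(seed = 87)
  expect_equal(nchar(sim$source), 658L)
  expect_true(startsWith(sim$source, folmer_primers[["LCO1490"]]))
  expect_true(endsWith(sim$source, revcomp(folmer_primers[["HCO2198"]])))
  sim2 <- simulate_coi_pair(seed = 87)
  expect_identical(sim, sim2)
  expect_error(simulate_coi_pair(read_span = 300), "overlap")
})

test_that("score-ratio classification separates variable-region reads", {
  # classifier benchmark: 30% blood-like contamination, libraries built
  # from the true host relative and the contaminant reference; reads
  # touching variable blocks must be kept/removed with precision and
  # recall >= 0.95 at threshold 0.8 (fully conserved windows are
  # inherently ambiguous and exempt from the recall requirement)
  arch <- rrna_architecture("SSU", total_length = 1000,
                            blocks = data.frame(
                              kind = rep(c("conserved", "variable"), 2),
                              length = c(300, 200, 300, 200)))
  anc <- make_reference(arch, seed = 88, id = "anc")
  host <- derive_relative(anc, arch, c("Insecta", "host"), seed = 89,
                          id = "host")
  blood <- derive_relative(anc, arch, c("Vertebrata", "blood"), seed = 90,
                           id = "blood")
  near_arch <- rrna_architecture("SSU", total_length = 1000,
                                 blocks = arch$blocks,
                                 conserved_divergence = 0.01,
                                 variable_divergence = 0.05)
  relative <- derive_relative(host, near_arch, c("Insecta", "relative"),
                              seed = 91, id = "relative")
  part <- partition_by_node(list(relative, blood))
  mix <- specimen_mix(host_fraction = 0.7,
                      contaminants = data.frame(label = "blood",
                                                ref_id = "blood",
                                                fraction = 0.3),
                      read_length = 150, error_rate = 0.01,
                      n_reads = 600L, seed = 92)
  reads <- simulate_specimen(mix, list(host = host, blood = blood))
  sc <- score_reads(setNames(reads$sequence, reads$read_id), part)
  kept <- filter_reads(sc)$kept
  kinds <- window_kind(arch, reads$start, reads$end)
  var_reads <- reads[kinds == "variable", ]
  is_host <- var_reads$origin == "host"
  is_kept <- var_reads$read_id %in% kept
  precision <- sum(is_host & is_kept) / sum(is_kept)
  recall <- sum(is_host & is_kept) / sum(is_host)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
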