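# COI barcode workflow: anchor/quality trimming, pair consensus, and the
# species-assignment decision rules.

test_that("trimming anchors the 5' end and respects qualities", {
  # forward anchor rule
  f <- sanger_read("forward", "AAAATTTTGGCCGG")
  expect_equal(trim_read(f)$sequence, "TTTTGGCCGG")

  # N wildcard in the reverse anchor
  r <- sanger_read("reverse", "CCGGATCTAAA")
  expect_equal(trim_read(r)$sequence, "GGATCTAAA")

  # trailing low-quality bases are removed before anchoring
  q <- c(rep(35L, 12), 20L, 20L)
  fq <- sanger_read("forward", "AAAATTTTGGCCGG", q)
  tr <- trim_read(fq, quality_floor = 30)
  expect_equal(tr$sequence, "TTTTGGCC")
  expect_equal(length(tr$qualities), nchar(tr$sequence))

  # idempotence
  expect_equal(trim_read(tr)$sequence, tr$sequence)

  # anchor absent -> error
  expect_error(trim_read(sanger_read("forward", "ACACACACAC")),
               "anchor not found")
})

test_that("pair consensus reconstructs a synthetic amplicon exactly", {
  sim <- simulate_coi_pair(source_length = 658, read_span = 400, seed = 71)
  f <- trim_read(sim$forward)
  r <- trim_read(sim$reverse)
  cons <- build_consensus(f, r)
  # the consensus must be the source interior: from the forward anchor
  # through the base whose complement starts the reverse anchor
  anchor_at <- regexpr("TTTTGG", sim$source, fixed = TRUE)
  # the planted reverse-anchor context sits just before the 26 nt
  # reverse primer and its 5 nt spacer: span ends at length - 31
  rev_anchor_end <- nchar(sim$source) - 31L
  expected <- substr(sim$source, anchor_at, rev_anchor_end)
  expect_equal(as.character(cons), expected)
  # this synthetic geometry anchors 597 nt of interior, short of the
  # nominal 621 nt barcode, so the full-length flag must be off
  expect_false(attr(cons, "full_length"))

  # identical forward and reverse-complement reads: consensus = sequence
  s <- paste0("TTTTGG", rand_dna(100))
  f2 <- sanger_read("forward", s)
  r2 <- sanger_read("reverse", revcomp(s))
  expect_equal(as.character(build_consensus(f2, r2)), s)

  # a single disagreement resolves to the higher-quality base
  s3 <- paste0("TTTTGG", strrep("ACGTT", 30))
  s3_mut <- s3
  substr(s3_mut, 50, 50) <- if (substr(s3, 50, 50) == "A") "G" else "A"
  f3 <- sanger_read("forward", s3, rep(40L, nchar(s3)))
  r3 <- sanger_read("reverse", revcomp(s3_mut), rep(20L, nchar(s3_mut)))
  expect_equal(as.character(build_consensus(f3, r3)), s3)
  # and symmetrically, the reverse wins when its quality is higher
  f4 <- sanger_read("forward", s3, rep(20L, nchar(s3)))
  r4 <- sanger_read("reverse", revcomp(s3_mut), rep(40L, nchar(s3_mut)))
  expect_equal(as.character(build_consensus(f4, r4)), s3_mut)

  # discordant pairs abort
  set.seed(72)
  f5 <- sanger_read("forward", rand_dna(200))
  r5 <- sanger_read("reverse", rand_dna(200))
  expect_error(build_consensus(f5, r5), "discordant")
})

test_that("species assignment reproduces the three documented rulings", {
  # revision: morphology says one species, the barcode cleanly says a
  # sister taxon with a > 2% margin over the next-best alternatives
  hits_simpsoni <- data.frame(
    reference_name = c("Aedes simpsoni isolate 1", "Aedes simpsoni 2",
                       "Aedes luteocephalus", "Aedes africanus"),
    percent_identity = c(100, 97, 90, 89))
  call1 <- assign_species("Aedes opok", hits_simpsoni)
  expect_equal(call1$status, "revised")
  expect_equal(call1$species, "Aedes simpsoni")

  # ambiguity: top two hits one substitution apart across sister species;
  # the morphological identity is retained
  one_sub <- 100 - 100 / 621
  hits_quinque <- data.frame(
    reference_name = c("Culex quinquefasciatus", "Culex pipiens"),
    percent_identity = c(100, one_sub))
  call2 <- assign_species("Culex quinquefasciatus", hits_quinque)
  expect_equal(call2$status, "ambiguous_sister_species")
  expect_equal(call2$species, "Culex quinquefasciatus")
  # the ruling must not depend on which sister tops the list
  call2b <- assign_species("Culex quinquefasciatus", hits_quinque[2:1, ])
  expect_equal(call2b$status, "ambiguous_sister_species")
  expect_equal(call2b$species, "Culex quinquefasciatus")

  # genus-only: nothing at species level but a single genus throughout
  hits_culex <- data.frame(
    reference_name = c("Culex neavei", "Culex perexiguus",
                       "Culex duttoni"),
    percent_identity = c(93, 92.5, 91))
  call3 <- assign_species("Culex sp.", hits_culex)
  expect_equal(call3$status, "genus_only")
  expect_equal(call3$genus, "Culex")
  expect_true(is.na(call3$species))
})

test_that("confirmation, no-reference, and margin rules behave", {
  hits <- data.frame(
    reference_name = c("Aedes albopictus", "Aedes aegypti"),
    percent_identity = c(99.5, 91))
  expect_equal(assign_species("Aedes albopictus", hits)$status,
               "confirmed")

  # top hit differs but within the revision margin -> ambiguous, retained
  hits2 <- data.frame(
    reference_name = c("Anopheles rhodesiensis", "Anopheles coustani"),
    percent_identity = c(98.5, 98))
  call <- assign_species("Anopheles coustani", hits2)
  expect_equal(call$status, "ambiguous_sister_species")
  expect_equal(call$species, "Anopheles coustani")

  # no hits at all, morphology present -> no_reference
  call_nr <- assign_species("Anopheles baezai",
                            data.frame(reference_name = character(0),
                                       percent_identity = numeric(0)))
  expect_equal(call_nr$status, "no_reference")
  expect_error(assign_species(NA_character_,
                              data.frame(reference_name = character(0),
                                         percent_identity = numeric(0))),
               "empty hit list")

  # equal-identity reorderings do not change the ruling
  hits3 <- data.frame(
    reference_name = c("Culex neavei", "Culex perexiguus"),
    percent_identity = c(96, 96))
  a <- assign_species("Culex neavei", hits3)
  b <- assign_species("Culex neavei", hits3[2:1, ])
  expect_equal(a$status, b$status)
  expect_equal(a$status, "ambiguous_sister_species")
})

test_that("species call table serialization mirrors the evidence", {
  calls <- list(
    S1 = assign_species("Aedes albopictus", data.frame(
      reference_name = "Aedes albopictus", percent_identity = 99.9)))
  tf <- tempfile(fileext = ".tsv")
  write_species_calls(calls, tf)
  tab <- read.delim(tf)
  expect_equal(tab$status, "confirmed")
  expect_equal(tab$top_hit_identity, 99.9)
})
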