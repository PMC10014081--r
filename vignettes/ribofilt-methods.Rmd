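---
title: "Score-ratio rRNA read filtration and guided assembly: methods"
author: "ribofilt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-ratio rRNA read filtration and guided assembly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofilt)
```

## The problem

Ribosomal RNA dominates total RNA in animal tissue (80% or more of the
cellular RNA pool), so total RNA-seq of a mosquito specimen is mostly rRNA
reads. Recovering the full-length 28S (LSU, ~3,900 nt) and 18S (SSU,
~1,900 nt) genes of the *host* from such data is harder than it sounds:
field-caught specimens also carry rRNA from vertebrate blood meals,
water-mite ectoparasites, and microbiota, and rRNA genes are strongly
conserved across all of these organisms. Reads from conserved regions of
non-host rRNA are similar enough to host rRNA to join — and corrupt — a de
novo assembly.

`ribofilt` implements a score-ratio filtration strategy for this problem,
together with the procedures around it: reference-library partitioning,
iterative library augmentation, assembly with a trusted-guide rescue mode,
antisense probe tiling for physical ribodepletion, and the COI barcode
workflow used to validate the morphological identification of specimens.

## The score-ratio classifier

Two disjoint reference libraries are cut from a taxonomy-annotated rRNA
database at the "Insecta" node: every sequence whose taxonomy path
contains the rank *Insecta* (exact rank match, not substring) goes to the
Insecta library, everything else to the Non-Insecta library. Each read
$r$ receives two raw local-alignment scores,

$$ S_I(r) = \max_{x \in \text{Insecta}} \mathrm{SW}(r, x), \qquad
   S_N(r) = \max_{x \in \text{Non-Insecta}} \mathrm{SW}(r, x), $$

where $\mathrm{SW}$ is the Smith–Waterman score over both strands, and is
classified by the ratio $\rho(r) = S_I(r) / S_N(r)$ into four categories:

i.   hits only in the Insecta library (`I_ONLY`);
ii.  both hits, $\rho \ge 1$ (`I_GT_N`);
iii. both hits, $\rho < 1$ (`N_GT_I`);
iv.  no Insecta hit (`NO_I`).

Reads with $\rho \ge 0.8$ (plus all of category i) are kept for assembly;
category iv is always discarded. The threshold is deliberately
conservative: both libraries are incomplete samples of their clades, so
only reads that are clearly of non-insect origin should be removed. A
read from a perfectly conserved region scores equally against both
libraries ($\rho = 1$) and is kept — conserved-region contamination is a
stated limitation of the approach, mitigated downstream by coverage and
binning rather than by the filter.

### Numerical choices

* **Scoring parameters.** `scoring_params()` defaults to match +2,
  mismatch −3, gap open −5, gap extend −2 (a gap of length $k$ costs
  $\mathrm{open} + k \cdot \mathrm{extend}$) — the classic blastn-style
  scheme. Ratios are invariant to common positive rescaling of all
  parameters, so the exact scale matters little; what matters is that the
  *same* parameters are used against both libraries.
* **Hit reporting.** A "hit" exists when the raw score reaches
  `min_report_score` (default 50). An E-value criterion would depend on
  library size, which is meaningless for the small synthetic libraries
  the package is tested on; the external-hits path
  (`parse_external_hits()`) instead inherits the external aligner's own
  reporting threshold, and the two paths are therefore not numerically
  identical.
* **Ties.** $\rho = 1$ is classed on the kept side (`I_GT_N`): the filter
  keeps ties anyway ($1 \ge 0.8$), so the choice only affects labelling.
* **Boundary.** The threshold comparison is inclusive ($\ge 0.8$) by
  default, with `inclusive = FALSE` available for the strict variant. The
  inclusive reading is the one whose worked category counts are
  checkable, which is why it is the default.

The scorer itself is an exact affine-gap Smith–Waterman in C++, not a
seeded heuristic. Its unit tests check it against two independent
references: a brute-force dynamic program written in plain R, and
`Biostrings::pairwiseAlignment()`.

## Iterative augmentation

Public rRNA databases contain few complete insect rRNA genes, so a single
filtration pass against them can be weak. `run_pipeline()` therefore
iterates: complete assembled sequences (length at or above
`complete_min_length`, default 1,000 nt) are added to the Insecta library
(taxonomy `Insecta;assembled;<id>`) and the score–filter–assemble cycle
repeats, stopping at the cycle cap or as soon as the kept-read set
reaches a fixpoint. The stopping rule is a design choice of this package:
a kept-set fixpoint is the natural formalisation of "repeat until the
filtration stops changing".

## Assembly

The internal assembler (`greedy_assemble()`) is a deterministic greedy
overlap-layout assembler over exact suffix–prefix overlaps (both strands,
longest overlap first, ties broken by the lexicographically smaller
merged sequence). It exists because the pipeline needs a dependency-free,
reproducible assembler at desk scale; it is not a de Bruijn assembler and
does not scaffold. An adapter (`external_assembler_adapter()`) carries
the contract for a production assembler — k-mer lengths 31/51/71, an rna
mode, trusted-contigs pass-through — and fails with an explicit pointer
to the internal fallback when the binary is absent.

Exact-overlap merging never takes a vote, so a sequencing error carried
by the single read covering a position survives into the contig.
`polish_contigs()` therefore re-places the kept reads onto each contig
(300 nt and longer) and majority-votes every column — the standard
consensus step of any assembler, implemented here by reusing the guided
consensus machinery with the contig as its own guide.

### The trusted-guide rescue

When a specimen is parasitized, the parasite's rRNA co-assembles with the
host's, often at much higher coverage, and the host assembly fragments.
`guided_consensus()` mirrors the trusted-contig rescue: given the 28S/18S
sequences of the host's nearest available relative as a guide, each read
is placed at its best local-alignment position on the guide and each
column is called by majority vote, with ties resolved to the guide base
and columns below `min_depth` falling back to the guide base (flagged in
the result).

Placement applies an identity floor (`min_identity`, default 95% over at
least half the read) to build a host-biased draft: host reads sit near
the host–guide identity (~97% for a congeneric guide), while reads of a
95%-identical foreign organism sit near 92% against the guide. The
default of 95% deliberately coincides with the species-delineation scale
used in barcoding. The floor alone is not sufficient under a large
coverage excess: at 150 nt the per-read identity has a standard
deviation of roughly 2 percentage points, so a few percent of foreign
reads clear any threshold between the two populations, and at 10-fold
coverage that leakage can outvote the host at the columns where the two
organisms differ. With `competitive = TRUE` (the default) the function
therefore refines heterogeneous pileups: it also builds the *unfloored*
consensus of all placeable reads — which, under foreign excess,
converges to the foreign sequence — scores every read against both
consensuses, and rebuilds the host consensus from the reads that score
strictly higher against the host draft. This competitive assignment is
the same idea as the dual-library score ratio, applied at the pileup
level, and separates two 95%-identical organisms far more sharply than
any single threshold. Homogeneous pileups (draft and unfloored consensus
at or above 99% identity) skip the refinement. The residual cost of the
identity floor is that a guide whose variable regions diverge much
beyond ~5% from the true host leaves those regions uncovered in the
draft (they fall back to guide bases and are flagged); for cross-genus
guides the floor should be lowered.

`bin_contigs()` then separates assembled contigs into host and foreign
bins at 97% identity to the host reference — between typical
intraspecific variation and the ~95% identity observed for a
co-assembled water mite — and annotates the bins with their mean-coverage
ratio, the diagnostic signature (~10×) of the parasite.

## Probe tiling for ribodepletion

Physical rRNA depletion hybridises tiled antisense DNA oligos to the rRNA
and digests the hybrids with RNase H. `tile_probes()` cuts
non-overlapping windows (default 80 nt) along each target gene and
reverse-complements them. When the gene length is not a multiple of the
probe length, the default `right_anchor` policy adds a final window
flush with the 3′ end (overlapping its neighbour) so the whole gene is
covered — variable 3′ ends matter for depletion — while `drop` leaves the
remainder uncovered. The target's own reference count and lengths decide
how many probes result; the policy is explicit because the probe count
alone cannot disambiguate it. `probe_pool_manifest()` attaches the pool
concentration (default 0.04 µM) and flags duplicate probe sequences,
which arise when conserved blocks repeat across targets.

## The COI barcode workflow

Species identity of specimens is validated with the standard 658 bp COI
barcode amplified by the Folmer primers (stored in `folmer_primers`).

* `trim_read()` removes bases below Q30 from both ends, then trims the 5′
  end to the first occurrence of the direction-specific anchor (`TTTTGG`
  forward, `GGNTCT` reverse, N matching any base), so all sequences start
  at homologous positions.
* `build_consensus()` reverse-complements the reverse read, aligns the
  pair locally, and merges them. Disagreements resolve to the
  higher-quality base; without qualities the forward base wins (a
  deterministic stand-in for manual trace inspection). Pairs whose
  overlap is shorter than 30 columns or below 98% identity are rejected
  as discordant. The nominal barcode is 621 nt with extension up to
  699 nt when both reads reach further; the result carries a
  `full_length` flag rather than being padded or truncated to the
  nominal length.
* `assign_species()` applies the delineation rules: <95% identity
  separates species; a revision of the morphological identification must
  beat the morphological species' own best identity by more than 2%; top
  hits of different species within one substitution's worth of identity
  (100/621 ≈ 0.16%) are an unresolvable sister-species ambiguity, in
  which case the morphological identity is retained. The sister-ambiguity
  check runs before confirmation: a top hit that nominally matches
  morphology is still ambiguous when a sister species is one substitution
  behind. When nothing reaches the species threshold but all hits share a
  genus, the call is genus-only ("*Culex* sp."); with no usable reference
  at all, `no_reference`. Ties among equal-identity hits of the same
  ruling are order-independent; ties that would change the ruling are
  reported as ambiguous with the full evidence table.

## The synthetic-data generator

Every fixture is generated in code from a seed; no external downloads are
needed, and all generators are pure functions of their parameters and the
seed.

* **Gene architecture.** `rrna_architecture()` models a gene as
  alternating conserved (300 nt) and variable (200 nt) blocks — about 60%
  conserved — with defaults of 3,900 nt (LSU) and 1,900 nt (SSU).
  Divergence between related taxa defaults to 2% in conserved and 25% in
  variable blocks. These rates reproduce the qualitative structure that
  makes the method necessary: conserved-region reads are ambiguous
  between libraries (ratio near 1), variable-region reads are diagnostic.
* **Specimens.** `simulate_specimen()` mixes host and contaminant reads
  (default 70:30, emulating a blood-fed specimen), drawing 150 nt windows
  uniformly from either strand with substitution errors (default 1%).
  Every read carries its true origin, window, and strand, so precision
  and recall of the filter are exactly computable.
* **COI pairs.** `simulate_coi_pair()` builds a 658 nt amplicon flanked
  by the Folmer primers with the trimming anchors planted at fixed
  offsets, and derives an overlapping forward/reverse Sanger pair with
  Q40 interiors and Q15 3′ tails, so the whole trim–consensus path is
  exercised.

What the generator does *not* model, and what passing tests therefore do
not show: indel sequencing errors and quality-ramped Illumina error
profiles (substitution-only errors keep the assembly and consensus
oracles exact), secondary-structure-aware rRNA evolution, chimeric PCR
artefacts, and the true size and redundancy of public rRNA databases.
Results on real specimens depend on those factors; the synthetic corpus
validates the logic of the method, not its field performance.

## Problem sizes in the shipped checks

The end-to-end checks run the full pipeline on a specimen of 2,000 reads
(about 36× coverage of each host gene at the 70:30 host:contaminant mix)
against libraries holding one near relative (~97% identity) of each host
gene and the contaminant references; the rescue check uses 2,288
error-free reads at an 8×/80× host/foreign coverage split over a 3,900 nt
gene. These sizes give stable statistics for coverage, identity, and the
10× coverage-ratio signature while staying desk-scale. The scorer is
verified against the brute-force dynamic program on 500 random instances
with reads up to 50 nt and references up to 200 nt, where exhaustive DP
is cheap.

## Known limitations

* The greedy assembler requires exact overlaps; at error rates well above
  ~1–2% or coverage well below ~20× it fragments, and the guided mode is
  the right tool.
* The identity floor of guided placement trades contamination exclusion
  against coverage of highly diverged variable regions (see above).
* Gene boundaries (where 28S ends and 18S begins) are only defined in
  guided mode, by the guide's own annotation; de novo contigs are
  reported as assembled, without boundary calling.
* Percent identity is computed over local-alignment columns; end gaps are
  not penalised, matching pairwise-BLAST convention but differing from
  global-identity definitions.
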