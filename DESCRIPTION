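Package: ribofilt
Title: Score-Ratio rRNA Read Filtration and Guided Assembly for Mosquito Total RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover full-length 28S and 18S ribosomal RNA sequences
    from total RNA-seq of field-caught mosquitoes. Each read is scored by local
    alignment against two disjoint reference libraries cut from a
    taxonomy-annotated rRNA database at the Insecta node; the ratio of
    Insecta over Non-Insecta best-hit scores classifies reads into four
    categories, and reads at or above a conservative ratio threshold (0.8)
    are admitted to assembly. Includes iterative library augmentation with
    newly assembled sequences, a deterministic greedy overlap assembler with
    majority-vote polishing, reference-guided consensus for specimens
    co-sequenced with parasites, contig binning by identity and coverage,
    antisense probe tiling for hybridization ribodepletion, a COI barcode
    trimming/consensus/species-assignment workflow, and synthetic-data
    generators emulating rRNA conserved/variable block architecture so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
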