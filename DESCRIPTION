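Package: pansorghum
Title: Pan-Genome Occupancy, Presence/Absence Phylogeny and LTR Dating for
    Multi-Genome Sorghum Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-assembly comparative genomics for multi-genome crop panels,
    built around a ten-genome bioenergy sorghum panel. Normalizes the
    nonstandard VCF dialect emitted by whole-genome syntenic variant callers
    (duplicate removal, fragmented-insertion merging, 50 bp size
    classification, per-type splitting), merges per-genotype variant sets
    into presence matrices with core/shell/cloud occupancy classification,
    builds neighbor-joining trees from Jaccard distances on presence/absence
    matrices, dates LTR retrotransposon insertions from left/right LTR
    divergence under the Kimura two-parameter model (T = K/(2r)), assigns
    phylogenetic age classes to genes from best-hit protein identities,
    performs one-sided Fisher-exact GO-term enrichment, and selects
    ideotype-group-specific variants. A synthetic-data module generates
    every input with ground-truth metadata so the full pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
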