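---
title: "Methods: pan-genome occupancy, PAV phylogeny and LTR dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome occupancy, PAV phylogeny and LTR dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansorghum)
```

This vignette is the package's account of the methods it implements: the
models and their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the
synthetic-data generators do and do not emulate.

## The setting

A panel of genome assemblies (here, ten bioenergy sorghum genotypes) is
aligned to a common reference and run through a syntenic variant caller.
Everything upstream — assembly, scaffolding, whole-genome alignment, the
caller itself, annotation lift-over, TE discovery — is out of scope and
consumed as input. The package covers the bespoke computations downstream:
cleaning the caller's output, pan-genome occupancy classification,
presence/absence (PAV) phylogeny, LTR retrotransposon dating, gene-age
profiling, GO enrichment, and ideotype-group contrasts.

## Normalizing the caller dialect

Syntenic callers report variants per syntenic block. Two artefacts follow:

* **Duplicates.** A variant inside overlapping blocks is reported once per
  block. Deduplication keeps the first record per identity key
  *(chrom, pos, type, ref, alt)*. INFO fields are deliberately excluded
  from the key: block-level copies differ only in provenance
  (`Parent`, `DupType`), and including them would leave true duplicates in
  place. This matches what byte-level VCF deduplication achieves on the
  core columns.
* **Fragmented insertions.** One long insertion can arrive as several INS
  records sharing (or nearly sharing) an anchor position. Records whose
  consecutive anchors lie within `gap_tol` bp merge into a single
  insertion; the merged ALT is the first fragment's anchored allele
  followed by the inserted parts of the rest, in ascending anchor order
  with ties broken by input order, so output is deterministic. The default
  `gap_tol = 0` (identical anchors only) is the most conservative reading
  of "combine fragments"; total inserted length is conserved for any
  `gap_tol`. Alleles are held in the standard anchored VCF representation
  (insertion ALT = anchor base + insert), so an insertion's event size is
  `nchar(alt) - nchar(ref)`.

Both operations are idempotent. Inversions and translocations are parsed,
counted and written through, but excluded from merging, size classes and
occupancy — they could not be validated downstream and their genotype
semantics against a linear reference are unclear. The 50 bp threshold
separating small indels from SVs follows the field's convention.
Coordinates are 1-based inclusive throughout.

## Occupancy: core, shell, cloud

`merge_genotypes()` takes the N per-genotype variant sets into one presence
matrix with absence meaning "carries the reference state" (the `-0` merge
semantics of standard VCF tooling). Classes are a pure function of the
presence count k: core (k = N), cloud (k = 1), shell (1 < k < N). Note the
reference itself is *not* a column: a "core" variant is one carried by all
N non-reference genotypes. For gene tables built from annotation lift-over
the same machinery applies; the presence calls are taken as input (the
lift-over threshold, 95% similarity, belongs to the annotation pipeline,
not here). Whether the reference should count as an (N+1)-th genome for
gene occupancy is ambiguous in general; the package keeps the reference
out and callers can append a reference column to the input table if their
convention differs.

Interval work (gene/TE flank overlap, genic variants) uses closed 1-based
intervals; contact exactly at the flank boundary counts as overlap. This
is a deliberate, documented tie-break — half-open conventions would
silently drop boundary cases. BED-style 0-based half-open input must be
converted on read.

## PAV phylogeny

Genotype columns of a binary PAV matrix are compared with the asymmetric
binary (Jaccard) distance: mismatched presences over the union of
presences, joint absences excluded. Joint absence of a gene carries no
signal about relatedness under a loss-only model, which is why the
symmetric simple-matching distance is not used.

Neighbor joining is implemented directly (Saitou–Nei Q-criterion,
two-point branch-length formulas) rather than delegated, because two
behaviors are pinned down that reference implementations leave
unspecified:

* **Tie-breaking.** When several pairs minimize Q, the lowest (i, j) pair
  in current label order joins, making output invariant across runs.
* **Negative branches.** NJ can produce negative branch lengths on
  non-additive input. They are clamped to zero with the deficit
  transferred to the sibling branch, preserving the path length through
  the joined pair — the common convention that keeps lengths
  interpretable as distances.

NJ is exact on additive matrices; the test suite verifies topology and
leaf-path distances (to 1e-9) against 200 random trees, and agreement with
`ape::nj` topologies on random non-additive matrices. Trees are unrooted,
bootstrap support is out of scope.

## LTR insertion dating

At insertion time the left and right LTRs are identical; divergence
accumulates afterwards in both copies. The pipeline is:

1. **Alignment.** Global (end-to-end) affine-gap alignment of the two
   LTRs, Gotoh three-state DP in compiled code. Default scores: match +2,
   mismatch −1, gap open −5, gap extend −1; a gap of length L costs
   `open + L·extend`. For a two-sequence task a pairwise aligner is
   equivalent to the multiple-alignment tools often used here, and the
   traceback uses a fixed state precedence so alignments are
   deterministic. N is scoring-neutral (0 against anything).
2. **K80 distance.** Columns containing a gap or N are excluded (pairwise
   deletion). With P the transition and Q the transversion proportion over
   the remaining `L_used` columns, `K = −½ ln(1−2P−Q) − ¼ ln(1−2Q)`.
   When `1−2P−Q ≤ 0` or `1−2Q ≤ 0` the logarithms are undefined — the
   pair is saturated. Saturation raises a dedicated condition class and
   `ltr_age_table()` flags such elements (`saturated = TRUE`, age `NA`)
   instead of dropping them, so the flagged count is visible.
3. **Age.** `T = K / (2r)` in Myr. The default clock,
   r = 0.013, is the rice LTR rate; its unit is interpreted as
   substitutions·site⁻¹·Myr⁻¹ (the natural reading for a per-site
   distance K) and it is an explicit parameter everywhere it appears.

The K80 estimator is consistent and effectively unbiased at these
divergences; parameter-recovery tests (ages 0.1, 1 and 5 Myr, 5 kb LTRs,
100 replicates) require the mean estimate within 10% of truth. K80
collapses to Jukes–Cantor when transitions:transversions are 1:2, which
the tests verify to 1e-12.

## Gene ages

Each gene's best-hit protein identities against a fixed outgroup ladder
decide its class, oldest clade first: Arabidopsis ≥ 50% → Viridiplantae;
else rice → Poaceae; else maize → Andropogoneae; else sorghum-specific.
The rule is evaluated strictly in that order, so a gene hitting rice and
maize (but not Arabidopsis) is Poaceae even if the maize identity is
higher — shared ancestry at the deeper node is what matters.
Brachypodium hits are accepted in the input but never classify; no rule is
defined for them, and dropping them silently would hide data, so they are
retained for transparency. A "hit" requires only identity ≥ threshold;
alignment coverage is not considered. The classification is monotone:
raising an identity can only move a gene to an older class.

## Enrichment and group contrasts

Per GO term, the one-sided Fisher exact p-value is the hypergeometric
upper tail `P(X ≥ k)` for k study genes annotated out of n, given K of N
population genes annotated. The significance flag uses the raw p < 0.05 —
deliberately uncorrected, matching the classic-Fisher screening
convention in this literature; a Benjamini–Hochberg column is emitted for
reference but does not gate the flag. Term-to-gene mappings are used as
given (no GO-DAG ancestor propagation); semantic-similarity reduction of
redundant terms is out of scope, the full p-sorted table is the output.

Group contrasts select variants present in **every** in-group genotype
and at most `max_out` out-group genotypes. "Rare among the out-group" is
not quantified in the underlying analyses, so it is an explicit parameter
with default `max_out = 1`; strict exclusivity is `max_out = 0`, and
results are worth reporting for both. With the whole panel as in-group
the selection is exactly the core rows.

## The synthetic-data generators

Every generator is a pure function of its parameters and an explicit
seed (the global RNG state is saved and restored), and returns a truth
list sufficient to score the downstream operation:

* `simulate_syri_vcf()` writes the caller dialect with known counts of
  injected byte-identical duplicates (`round(dup_rate · n)`) and
  fragmented insertions (2–4 distinct pieces at one anchor), shuffled
  line order. Normalization must remove exactly the injected artefacts.
* `simulate_occupancy()` plants exact core/shell/cloud counts; shell
  occupancy levels default to the empirical crop pan-genome shape (mode
  at N−1 genomes, secondary mode at 2). Default counts (62 / 8,556 /
  16,087 over N = 10) mirror the SV occupancy structure of the sorghum
  panel.
* `simulate_pav_on_tree()` evolves genes by irreversible loss along a
  known tree (loss probability `1 − exp(−rate · branch)`), the regime in
  which Jaccard + NJ is expected to work; genes lost everywhere are
  redrawn, so at vanishing loss rates the matrix tends to all-ones.
* `simulate_ltr_pairs()` evolves both LTR copies from a common ancestor
  using the exact K80 site transition probabilities at distance
  `r · T` per branch, with transition/transversion ratio kappa
  (default 2).
* `simulate_enrichment()` over-samples genes of planted terms by a stated
  fold; fold = 1 is the null. Defaults (population 2,000; 50 terms of
  40 genes; study 100) are a realistic desk-scale GO screen in which the
  discrete null rejects close to the nominal 5%.

What the generators do **not** emulate: real coordinate structure
(synteny breaks, clustered variation, centromeric repeat deserts),
caller-specific error modes beyond duplication/fragmentation, annotation
lift-over noise in PAV calls, homoplastic gene loss/regain, nested or
truncated LTR elements, and the correlated GO term structure of real
ontologies. Passing the recovery tests therefore shows the *computations*
are correct under their stated models, not that the models capture every
feature of real panel data.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design:
normalization scenarios of 500 variants, occupancy panels up to the
~25k-row SV structure, 10-leaf trees with 2,000 genes and 100 replicates,
300 LTR pairs of 5 kb, and exhaustive Fisher enumeration for all tables
with N ≤ 60 (agreement to 1e-12). Genome-scale figures from real panels
(millions of SNPs per genotype) require the original assemblies and are
not reproduced; the planted-structure scenarios stand in for them with
exact expected outcomes.

Other numerical conventions: percentages are rounded to two decimals
(summaries can sum to 100 ± 0.02); Newick branch lengths are written with
15 significant digits so round-trips preserve path lengths to well below
1e-9; distance matrices must be symmetric within 1e-8 and non-negative;
Jaccard is undefined (an error) when both vectors are all-zero, and PAV
rows absent everywhere are rejected or dropped with a message.

## Known limitations

* Occupancy treats each variant identity independently; no attempt is
  made to reconcile near-identical SVs with slightly different
  breakpoints across genotypes.
* The NJ implementation targets panel-scale taxa counts (tens), not
  thousands; it is O(n^3) in plain R.
* LTR dating assumes the two LTRs evolve independently at the panel-wide
  clock rate; gene conversion between LTRs biases ages downward and is
  not modelled.
* The Fisher test treats genes as exchangeable; gene length and
  annotation-density biases are not corrected.
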