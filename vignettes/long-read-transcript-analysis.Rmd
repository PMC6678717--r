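---
title: "Methods: long-read transcript triage, splicing profiles and lncRNA matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read transcript triage, splicing profiles and lncRNA matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescope)
```

`splicescope` operates downstream of long-read alignment and collapse: its
input is a set of per-sample transcript models (exon chains with read
support), not reads. This vignette documents the methods, conventions and
design decisions; the README shows the worked workflow.

## Coordinate convention

All internal coordinates are 0-based half-open, uniformly. GTF (1-based
inclusive) converts at the reader/writer boundary: internal
`start = gtf_start − 1`, `end = gtf_end`. BED and BED12 are consumed
verbatim. A single convention held everywhere removes the usual off-by-one
drift between modules; the round-trip tests assert bit-exact coordinate
recovery through every reader/writer pair.

Transcripts without a definite strand are rejected at load (with a reported
count): both the TSS and the A5/A3/AF/AL event semantics are undefined
without strand. The read-support GTF attribute key is configurable
(default `read_count`) because long-read collapse pipelines name it
inconsistently; absent attributes default to support 1 so count-free
inputs stay usable.

## TSS proximity

The TSS is the transcript's first transcribed base: first exon start on
`+`, last exon end − 1 on `-`. The distance to a feature is measured
TSS-to-nearest-edge — 0 when the TSS lies inside the feature, otherwise
the smaller gap to either edge — and signed by transcription direction
(negative = the feature lies upstream of the TSS). Edge distance is the
genome-browser-intuitive reading of "distance to the nearest mark"; a
midpoint convention would penalize wide histone domains that plainly cover
the TSS.

Conventions fixed here:

* When an upstream and a downstream feature tie in absolute distance, the
  downstream feature is reported. The choice is arbitrary but fixed, and
  affects only which feature is named, never `|distance|`.
* A track with no feature on the transcript's chromosome yields a missing
  distance, never a sentinel value; histograms count finite distances only.
* The filter keeps a transcript when `|distance| ≤ cutoff` — the boundary
  is inclusive, matching the "within 1 kb" reading. The default cutoff is
  1000 bp and the default mode is `any` (evidence in one track suffices);
  `all` is available for stricter validation. The tests verify that the
  kept set is monotone in the cutoff and that kept/discarded partition the
  input.

Nearest-feature candidates are found with `GenomicRanges`
(overlap/precede/follow); a property test checks the result against an
exhaustive linear scan over every interval (tracks of 300 intervals, 60
random TSS positions per replicate).

## Local splicing events

Events are classified per gene by pairwise comparison of isoform exon
chains, using the local-event vocabulary standard in the field (SE, A5,
A3, MX, RI, AF, AL). With all positions on the `+` genome axis:

* **SE** — one path has consecutive introns `(e1,s2)` and `(e2,s3)` around
  a cassette exon `(s2,e2)`; the other has the direct junction `(e1,s3)`.
  Coordinates `(e1, s2, e2, s3)`.
* **RI** — one path splices an intron whose flanking exons' outer bounds
  `(s1, e2)` are exactly spanned by a single exon of the other path.
  Coordinates `(s1, e1, s2, e2)`.
* **A5/A3** — two junctions share one boundary and differ at the other;
  the exons carrying the differing boundary must overlap (otherwise the
  variation is a distinct exon and is handled by SE/MX/AF/AL). Whether the
  varying side is the donor or acceptor is resolved by strand, so the same
  geometry is A5 on `+` and A3 on `-`.
* **MX** — two non-overlapping middle exons, each joined to the same outer
  flanks. Overlapping middles are not mutually exclusive; their shifted
  boundaries surface as A5/A3 instead.
* **AF/AL** — non-overlapping alternative terminal exons splicing to the
  same inner boundary, labelled first/last by transcription direction.
  Requiring non-overlap keeps terminal-end raggedness (ubiquitous in long
  reads) from being miscalled as alternative promoters/terminators.

Events are deduplicated at the gene level by a canonical id
(`gene;TYPE:chrom:coords:strand`); the same coordinates arising from
several isoform pairs count once, with inclusion/exclusion sets taken as
unions over supporting pairs. The inclusion label denotes the variant
retaining more exonic sequence (cassette-containing, intron-retaining,
shorter-intron path); for MX/AF/AL, where "inclusion" has no canonical
meaning, a fixed coordinate-based orientation is used. The orientation
affects labels only — never the event type, coordinates or counts.

Correctness is anchored two ways: seven-type implanted fixtures must be
recovered exactly, and an independent brute-force enumerator (a literal
transcription of the definitions, kept in the test helpers) must agree
with the classifier on an exhaustive grid of transcript pairs drawn from a
4-exon template with retained-intron variants (≈350 pairs per strand) plus
randomized 3–4-isoform genes from a 6-exon template. Mirror tests check
strand consistency: reflecting coordinates and flipping strand swaps
A5↔A3 and AF↔AL and fixes SE/RI/MX.

PSI quantification and per-event differential statistics are out of scope;
the package classifies events and compares type composition.

## Profile comparison and diversity

Per-sample event counts form a samples × 7 table, compared with Pearson's
χ² test of homogeneity (`stats::chisq.test`, no continuity correction —
the r×c homogeneity setting, not a 2×2 correction scenario). Event types
with zero total count are dropped before testing rather than producing
zero expected counts; fewer than two non-empty rows or columns is reported
as a degenerate table. A test recomputes the statistic from the margins
independently.

Isoform diversity of a gene in a sample is the Shannon entropy (base 2) of
its isoform read-support proportions, excluding zero-support isoforms:
0 bits when one isoform carries all reads, `log₂ n` when `n` isoforms are
used evenly. Entropy was chosen as the diversity functional because it is
the standard usage-spread measure with exactly those boundary properties;
the scorer sits behind its own function so an alternative functional could
be swapped without touching the ranking code. Cross-sample ranking uses
`D = |H_a − H_b|`, descending, ties broken by gene id. Genes observed in
only one sample are scored 0 in the other and flagged `one_sample_only`
rather than silently dropped — missingness (not detected) and absence of
diversity (one isoform) are different facts, and the flag lets users
choose. Pairwise two-sample comparison is implemented; n-way designs
reduce to pairs.

## Enrichment

Over-representation of a gene set (typically the top-D genes) is tested
per annotation term with the one-sided hypergeometric tail
`P(X ≥ k)` via `stats::phyper`, and corrected with Benjamini–Hochberg.
The background defaults to all annotated genes; supplying the expressed
gene set is recommended when available since it is the proper sampling
universe. Terms annotating fewer than 3 background genes are skipped by
default (they cannot reach stable significance and inflate the correction
burden). No ontology-graph propagation is performed — the annotation file
is taken as given and should be pre-propagated if ancestor counting is
wanted. A null-calibration analysis (1000 uniformly random queries of 10
genes against a 60-gene, 12-term map) checks that the fraction of terms
with `p_adj < 0.05` stays at or below the nominal 5%.

## lncRNA triage

The coding-potential classifiers themselves are external: the package
consumes their output tables (two tool dialects plus a generic two-column
format) and normalizes the labels. Downstream steps default to the
intersection of the two tools' noncoding calls — concordance of two
independent classifiers trades recall for precision, the sensible default
for candidate nomination — with the per-tool and union sets always
available.

A candidate is "known" when the catalog contains its intron chain
(same chromosome and strand, identical ordered intron set). Intron-chain
identity deliberately ignores terminal-exon extents: 5'/3' end variation
is a sequencing artifact in long reads and should not create spurious
novelty. Single-exon candidates, which have no chain, fall back to
reciprocal exonic overlap (default threshold 0.5 of each party's exonic
bases); `exon_overlap` mode applies that criterion throughout.

Tissue specificity is catalog-annotation-based: a matched candidate is
specific when the union of tissue labels over all its matched entries has
size exactly one. Candidates matching only unannotated entries are
reported as unassigned rather than specific — absence of annotation is not
evidence of restriction. Expression-based specificity indices (e.g. tau)
are a different method and out of scope.

## Figures

Every plot writes a JSON layout manifest alongside the image — element
coordinates for the gene overview, exact percentages for the proportion
bars, bin counts for the distance histograms, region counts for the Venn —
and tests assert on manifests while the images are smoke-tested only.
Pixel comparison is deliberately avoided: font and device variation makes
it brittle, while the manifest pins every number the figure displays.
Colors are style roles (novel = red, long-read-known = black, annotation =
blue, per-mark arrow colors), overridable per call; bar segments follow
the fixed alphabetical type order for cross-run comparability.

## Synthetic data: what it does and does not emulate

The generators build structure-level ground truth: exon chains with
implanted events (template editing: drop an exon for SE, merge for RI,
shift a junction edge for A5/A3, swap middles for MX, swap a terminal exon
for AF/AL), feature tracks with planned signed TSS distances plus decoys,
catalog clones differing only in terminal-exon extents, and planned
classifier calls. Defaults: 6-exon templates, exon lengths 80–200 bp,
introns 200–500 bp, gene spacing 25 kb, read supports from a shifted
negative binomial (mu 10, size 5, minimum 1 so entropy is always defined),
one implanted event per gene so truth tables stay unambiguous. Everything
is seeded and byte-reproducible.

Because isoforms of a gene share (nearly) the same TSS, track plans are
drawn once per gene; residual shadowing (one transcript's feature ending
up nearer to another's TSS than its own plan) is resolved by re-placing
the shadowed plan at its realized distance for a bounded number of rounds,
and the truth table always states the realized layout, verified by an
exhaustive scan inside the generator.

What passing these fixtures does *not* show: robustness to sequence-level
error (no FASTA or error models are simulated), to mis-collapsed isoforms,
to incomplete annotation, or to the overdispersed, length-biased support
counts of real libraries. The fixtures establish algorithmic correctness
on known structure, not end-to-end performance on real data.

## Problem sizes and degenerate inputs

The test suite runs at deliberately small scale — hundreds of template
pairs for the classifier grid, a 200-transcript fixture for distance
recovery, 1000 replicates for the null calibration — chosen so the whole
suite completes in about a minute on one core while still exercising every
code path. Degenerate inputs have defined behavior throughout: empty
tracks give missing distances; an empty track *list* is an error (the
filter would be vacuous); all-zero count tables, single-row tables and
all-zero supports are errors with named messages; zero-event genes return
empty event lists.

## Known limitations

* Event classification is pairwise-local; complex events spanning more
  than two alternative paths appear as their pairwise decomposition.
* The χ² test assumes independent event counts; events sharing transcripts
  are not independent in a strict sense, so p-values are comparative
  indices rather than exact error rates.
* Intron-chain matching requires exact splice-site agreement; a 1-bp
  splice-site wobble (common with noisy long reads unless reads were
  polished) produces a "novel" verdict. Use `exon_overlap` mode when
  inputs are unpolished.
* Gene grouping trusts the input `gene_id`; no positional re-clustering of
  transcripts into loci is attempted.
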