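# splicescope

Downstream analysis of transcript models from long-read (third-generation)
RNA sequencing — PacBio SMRT or Oxford Nanopore reads collapsed into
per-sample isoform models.

Long reads capture full-length isoforms and are therefore ideal for isoform
discovery and lncRNA identification, but their high per-read error rate
produces spurious transcript models. `splicescope` supports the routine
triage that follows collapse:

* **Full-length transcript validation.** The transcription start site (TSS)
  of a genuine transcript tends to sit near promoter-associated evidence —
  CAGE peaks, H3K4me3/H3K4me1/H3K27ac regions. For every transcript and
  feature track the package computes the signed distance from the TSS to
  the nearest feature (0 inside a feature, negative upstream in
  transcription direction) and filters transcripts with no feature within a
  cutoff (default 1 kb) of their first nucleotide.
* **Alternative-splicing profiles.** The seven local AS event types —
  skipped exon (SE), alternative 5'/3' splice site (A5/A3), mutually
  exclusive exons (MX), retained intron (RI), alternative first/last exon
  (AF/AL) — are classified from exon chains, per gene, by pairwise
  comparison of isoform structures, and tabulated per sample. Sample
  profiles are compared with a Pearson χ² homogeneity test on the
  samples × types contingency table.
* **Isoform diversity.** Per gene and sample, isoform usage is scored as
  the Shannon entropy `H = −Σ pᵢ log₂ pᵢ` of read-support proportions
  `pᵢ`; genes are ranked across two samples by `D = |H_a − H_b|` and the
  top-ranked set tested for GO term over-representation
  (one-sided hypergeometric test, Benjamini–Hochberg correction).
* **lncRNA triage.** Noncoding calls from two external coding-potential
  classifiers are combined into per-tool, intersection and union sets;
  candidates are matched against a lncRNA reference catalog by intron-chain
  identity (robust to ragged read ends), and matched candidates annotated
  in exactly one tissue are reported as tissue-specific.
* **Figures with manifests.** Transcript overview (gene-level tracks with
  read support in brackets), AS-type percentage bars, TSS-distance
  histograms and two-set Venn plots; every figure emits a JSON layout
  manifest carrying the exact numbers drawn.

A seeded synthetic-data module (`generate_genes`, `generate_tracks`,
`generate_lnc_inputs`, `generate_annotation`) produces every input format
with a ground-truth table, so the whole suite is testable offline.

## Worked example

```r
library(splicescope)

fx  <- generate_genes("fixtures", seed = 42)          # 7 genes, 1 event each
trk <- generate_tracks(fx$transcripts, "fixtures", seed = 42)
s   <- sample_transcriptome("liver_pacbio", fx$transcripts)

filter_by_distance(s, trk$tracks, cutoff_bp = 1000)
#> <filter_report> cutoff 1000 bp (mode any, tracks: CAGE, H3K4me1, H3K4me3,
#>                 H3K27ac): kept 14, discarded 0

evs <- unlist(lapply(group_by_gene(fx$transcripts), detect_events),
              recursive = FALSE)
events_to_df(evs)[, c("gene_id", "type", "coordinates")]
#>      gene_id type                               coordinates
#> G001    G001   SE                   25645-25893-25997-26324
#> G002    G002   A5                         51384-51424-51647
#> G003    G003   A3                         76260-76573-76613
#> G004    G004   MX 100533-100952-101040-101487-101673-101990
#> G005    G005   RI               126073-126252-126632-126814
#> G006    G006   AF        150000-150164-150224-150294-150648
#> G007    G007   AL        177506-177566-177636-177947-178137

d <- diversity_scores(s)
head(d[order(-d$score), ], 3)
#>      gene_id    sample_id     score n_isoforms
#> G007    G007 liver_pacbio 0.9932338          2
#> G006    G006 liver_pacbio 0.9852281          2
#> G005    G005 liver_pacbio 0.9340681          2
```

All 14 transcripts pass the 1 kb TSS filter because the generator placed a
feature within 1 kb of every planned TSS; each gene yields exactly its
implanted event, with the defining splice-site coordinates shown
dash-joined; the diversity scores approach 1 bit where the two isoforms of
a gene carry nearly equal read support.

A command-line front end for shell pipelines is installed at
`system.file("scripts/splicescope-cli.R", package = "splicescope")` with
subcommands `tss-dist`, `tss-filter`, `as-profile`, `score-d`, `go-enrich`,
`lnc-combine`, `lnc-match` and `simulate`.

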