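---
title: "Comparative tRNAome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative tRNAome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaome)
```

## What the package computes

Transfer RNA genes are among the most dynamic components of genomes:
their copy number varies over three orders of magnitude between
species, their anticodon repertoires differ systematically between the
three domains of life, and their processing products (tRNA-derived
fragments, tRFs) form highly redundant small-RNA pools. `trnaome`
implements the analysis chain for comparative censuses of tRNA gene
annotations:

1. parse tRNAscan-SE tabular annotations into normalized per-locus
   tables;
2. build per-genome censuses (copy number, anticodon repertoire,
   introns, pseudogenes, lengths) and apply a genome-quality filter;
3. aggregate across genomes: per-domain summary statistics,
   per-combination pervasiveness, universality-group classification,
   Venn overlaps, gene densities, genome-size scaling, and two-group
   tests;
4. summarise intraspecific copy-number variation across strains of one
   species;
5. type tRF sequences against mature-tRNA models and quantify pool
   redundancy;
6. generate synthetic cohorts with known parameters so that every
   stage is testable without database downloads.

## Anticodon algebra and the genetic code

All sequence computation happens in DNA notation (T, never U);
RNA-alphabet inputs are mapped on ingest and `dna_to_rna()` exists
only for display. An anticodon decodes the codon that is its exact
reverse complement, so the map is an involution over the 64 triplets.
Isotype prediction uses the standard genetic code (NCBI translation
table 1) only; organisms with reassigned codons are out of scope, and
for that reason the annotated isotype in an input file always takes
precedence over the prediction — the prediction is used solely to
flag *unusual* combinations. Three anticodons (TTA, CTA, TCA) are
complementary to stop codons; annotated suppressor tRNAs (`Sup`)
are always reported as unusual, while initiator-Met variants
(iMet/fMet at CAT) and selenocysteine at TCA are treated as standard
usage.

## Coordinate and length conventions

tRNAscan-SE reports 1-based inclusive coordinates and conveys the
minus strand by writing begin > end. `read_trnascan()` normalizes
immediately (begin ≤ end plus an explicit strand), so all downstream
arithmetic uses one convention; BED export converts to 0-based
half-open at the boundary. Gene length is `end − begin + 1`; mature
length is gene length minus the summed intron lengths. The mature
length is the *encoded* length: the post-transcriptionally added CCA
tail is not included (the tRF classifier compensates by also matching
3' fragments against CCA-appended mature sequences). A locus is a
pseudogene when its anticodon is undetermined (`NNN`/`???`) — the
operational definition of a tRNA pseudogene used throughout — or when
its note column says "pseudo". Although the flat tRNAscan-SE format
shows one intron pair, the parser accepts an extended dialect with
semicolon-separated pairs, because multi-intron tRNA genes occur and
the census's intron-count distribution should not be truncated at one.

## The genome-quality filter

Genomes with fewer than 20 annotated isoacceptors are removed before
comparative analysis; "isoacceptor" is read as *distinct anticodon*
(not locus count), which is the sense the term carries in repertoire
analysis. The boundary is inclusive: a repertoire of exactly 20 is
retained. Because the reading is a genuine interpretation choice,
`filter_genomes(on = "loci")` exposes the alternative.

## Pervasiveness and universality groups

For each (isotype, anticodon) combination and domain, pervasiveness is
the fraction of the domain's retained genomes carrying at least one
functional copy; mean copy number is averaged over *all* genomes of
the domain, zeros included. Classification into universality groups
uses two thresholds: `high = 0.70` (strict >) and `low = 0.30` (≤).
The high threshold is the conventional 70% cutoff for "present in most
genomes"; the low threshold is a design choice — "avoided" is not
quantified in the comparative-genomics literature with a standard
number — and is configurable. With these defaults the five named
groups (universal; eukaryote+archaea; prokaryote; eukaryote-only; rare
everywhere) are mutually exclusive by construction and everything with
a mixed intermediate profile (e.g. frequent in eukaryotes and bacteria
but rare in archaea) lands in `other` rather than being forced into a
named group.

## Statistics

Two-group contrasts use Welch's *t* (Satterthwaite degrees of
freedom) and the Mann–Whitney *U*, both two-sided, via R's `t.test()`
and `wilcox.test()`; *U* is exact for samples of at most 20 without
ties and otherwise uses the normal approximation with tie and
continuity correction. A zero-variance pair of samples is an explicit
error, not a NaN. Quantiles (median, IQR) use the linear-interpolation
convention (R type 7) so summaries are reproducible across
environments; single-genome strata report SD/SE as missing rather
than zero. Scaling analyses report both Spearman rank correlations on
raw values and least-squares slopes on log10–log10 axes for positive
values, since neither statistic alone captures a power law with
heavy-tailed noise; a constant margin is reported as rho 0 (all ranks
tied) with a missing p-value. P-values are reported raw — the
upstream analyses applied no multiple-testing correction — and users
can apply `p.adjust()` downstream.

## tRF typing

Fragments are typed by exact string match: a prefix of a mature
sequence is tRF-5, a suffix (with or without an appended CCA, the
CCA route being tagged) is tRF-3, and a prefix of the 3' trailer is
tRF-1. Exact matching is the right default because reference tRF
databases derive fragments from the exact genomic sequence. Fragments
shorter than 13 nt are rejected — 13–38 nt is the observed tRF length
range — and a fragment matching several categories is assigned by the
fixed priority tRF-5 > tRF-3 > tRF-1 and flagged ambiguous, so pool
totals are conserved rather than silently shrinking. Redundancy and
length spectra are computed on distinct sequences, which is what makes
pools comparable between species with very different sequencing
depths.

## The synthetic cohort generator

The generator emulates the statistical structure of real annotation
cohorts so parameter recovery can be tested end to end:

* **Genome sizes** are log-uniform within domain ranges of roughly
  1–6 Mb (Archaea), 0.5–10 Mb (Bacteria) and 10 Mb–100 Gb (Eukarya).
* **Copy number** follows a power law `CN = a · size^b` with
  lognormal noise; the exponents (eukaryotes b = 1.0, prokaryotes
  b = 0.5) are synthetic defaults chosen to reproduce the qualitative
  contrast that eukaryote tRNA counts expand much faster with genome
  size than prokaryote counts — they are not estimates. The eukaryote
  intercept (a = 0.2) puts the median cohort genome near 200 loci,
  the observed eukaryote median; the prokaryote intercepts put mean
  counts near 60 (Bacteria) and 48 (Archaea). CN is floored at 20 and
  at one copy per sampled combination, so no sampled combination is
  ever dropped.
* **Repertoires** are Bernoulli draws from per-combination
  pervasiveness probabilities (`default_pervasiveness()`), a
  deterministic synthetic profile covering all universality patterns;
  remaining copies are distributed multinomially with weights
  proportional to pervasiveness squared, giving the skewed
  multiplicity real repertoires show.
* **Introns** are per-locus Bernoulli with domain probabilities
  0.2230 (Eukarya), 0.1899 (Archaea) and 0.0011 (Bacteria); intron
  lengths are normal (18 ± 4, 30 ± 8, 20 ± 5 nt respectively,
  clamped to fit inside the gene).
* **Gene lengths** are normal with means 84.70, 83.10 and 77.60 bp
  (sd 5, 5 and 2.5 bp); mature length is gene length minus intron
  length.
* **Pseudogenes** are emitted at rates 0.05/0.01/0.01 (synthetic
  choices consistent with pseudogenes being 1–2 orders of magnitude
  rarer than functional genes).
* **Protein-coding counts** follow a saturating curve
  `cap · size/(k + size)` with a eukaryote cap of 35,000 genes.

Each genome draws from its own RNG stream derived from the master
seed and genome index, so cohorts are byte-reproducible and could be
generated in parallel. What the generator does **not** emulate:
realistic tRNA sequence content (covariance-model scores are
placeholders), assembly artifacts, phylogenetic correlation between
genomes, and within-domain lineage structure. Tests that pass on
synthetic cohorts therefore validate the *bookkeeping and statistics*
of the pipeline, not biological conclusions about any particular
clade.

## Problem sizes used in validation

The packaged checks recover generator parameters from cohorts of 500
eukaryote genomes (~1.1 M pooled loci), 500 archaeal genomes (~26 k
loci) and 900 bacterial genomes (~58 k loci; also used for the
gene-length recovery at > 10,000 functional loci). Intron-fraction
recovery is binomial, so these sizes put the Monte-Carlo standard
error far inside the stated ±1 percentage-point (±0.05 for bacteria)
tolerances. Oracle-equivalence checks run on hundreds of randomized
miniature cohorts against independent brute-force implementations.

## Degenerate inputs and edge cases

An empty locus table yields an empty census, not an error; a species
whose minimum copy number is zero reports an undefined fold range with
a flag instead of dividing by zero; correlation of a constant series
is reported missing with a message; scaling pairs with fewer than
three points are skipped with a warning; and a domain with zero
genomes makes pervasiveness fail loudly with the domain named, since
a silent zero denominator would poison every downstream fraction.

## Known limitations

The package deliberately does not rerun tRNAscan-SE, scrape tRNA
databases, resolve taxonomy via web services, or model wobble-pairing
decoding coverage. Non-standard genetic codes are unsupported;
annotated isotypes from such organisms will surface as "unusual"
combinations, which is the intended behaviour. Published cohort-level
numbers from any specific database snapshot are
database-version-dependent and are not reproduction targets for the
synthetic pipeline.
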