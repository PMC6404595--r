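---
title: "Detecting C-to-U RNA editing sites from transcript alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting C-to-U RNA editing sites from transcript alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoedit)
```

## The problem

Plant organellar transcripts are post-transcriptionally edited by C-to-U
deamination at defined positions. When RNA-seq reads are mapped against
sense-strand CDS references, an editing site appears as a C reference
position at which a fraction of reads carry T; that fraction estimates the
*editing extent* — the proportion of transcript molecules edited at the
site. The statistical task is to separate genuine editing signals from
sequencing error, from reads of diverged homologous loci mapped to the
wrong gene, and from genomic C/T differences between the reference
individual and the sequenced individual.

`mitoedit` implements this analysis as composable, pipe-friendly functions
over tibbles: pileup construction, site calling, consequence annotation,
paralog flagging, cross-sample comparison, and genomic SNP classification,
plus a simulator that generates data with known truth.

## The calling model

At each C reference position with at least one T read, four filters are
evaluated, all inclusive (`>=`):

| filter | default | units | rationale |
|---|---|---|---|
| `min_coverage` | 10 | reads | below ~10 reads the extent estimate is too coarse to interpret |
| `min_count` | 3 | T reads | one or two T reads are compatible with error/artifacts |
| `min_frequency_percent` | 10 | % | extents reported for plant mitochondria run from ~10% upward; lower signals are indistinguishable from low-level noise |
| `min_probability` | 0.95 | probability | excludes counts explainable by sequencing error alone |

The frequency denominator is the full A+C+G+T coverage, not C+T only, so a
position with many non-reference, non-T bases (itself suspicious) is not
inflated.

The probability filter needs an explicit error model. We use the simplest
null with the right role: if the per-base error rate is $e$ and an error
substitutes uniformly among the three alternative bases, the number of T
reads at an unedited C position with coverage $n$ is
$X \sim \mathrm{Binomial}(n,\, e/3)$. The reported probability is

$$ 1 - P[X \ge k] $$

for $k$ observed T reads, compared against `min_probability`. With the
defaults ($e = 0.001$), 3 T reads in 10 reads give a tail around
$4\times10^{-9}$ and pass easily, whereas 3 T reads in 10{,}000 at $e=0.01$
are expected from error and fail. The default $e$ is deliberately
conservative for modern short-read data and is configurable
(`filter_config(sequencing_error_rate = ...)`). The model ignores
position-specific error and mapping artifacts; the paralog flag (below)
covers the dominant mapping failure mode.

`error_model_probability()` is a thin wrapper over the binomial CDF; the
test suite checks it against an independent brute-force enumeration of the
tail to $10^{-9}$ for all coverages up to 30.

## Coordinates, codons and translation

All CDS positions are 1-based inclusive, matching how editing sites are
conventionally printed (e.g. *nad6*-146). The codon position of a site is
`pos mod 3` with 0 mapped to 3, and translation uses the standard genetic
code with two exceptions relevant to plant mitochondria: `UGA` and `CGG`
both read as Trp. Stop gain/loss is judged against that same table, so a
C→U edit creating `UGA` is *not* a gained stop. Codons containing a base
outside A/C/G/T translate to `X` and yield no synonymy call. A site in an
incomplete terminal codon (possible for CDS whose length is not a multiple
of 3, which are accepted and logged as pseudogene candidates) keeps its
codon position but no amino-acid fields.

Percentages in `codon_position_distribution()` are rounded half-up to
integers — the convention under which counts of 118/189/48 over 355 sites
print as 33/53/14.

One numerical convention deserves a note: `interval_overlap()` returns
`min(end) − max(start)` *without* the `+1` that 1-based inclusive
coordinates would imply. Annotated overlaps of mitochondrial gene pairs are
conventionally printed under this boundary-difference convention (the
cox3/sdh4 pair at 246,064–246,861 / 246,789–247,184 is quoted as a 72-bp
overlap, not 73), so the package follows it; callers who need the inclusive
base count can add 1.

## Paralog flagging

Mitochondrial genes often have transcribed nuclear homologs a few percent
diverged ("dual transcription"). Their reads map unspecifically to the
mitochondrial CDS and create variant positions of *all* substitution
classes, whereas genuine editing can only create C-reference/T-read
signals on a sense-strand reference. `mismatch_profile()` therefore tests
every position for every alternative base with the same four filters and
flags a gene when at least one passing variant is not C-to-T (G-to-A
counts as non-C-to-T for the same reason). The threshold of one variant is
deliberately strict — historically such genes were discarded wholesale on
qualitative evidence — and configurable via `flag_threshold`.
`apply_validation()` removes all sites of flagged genes.

## Cross-sample comparison

`build_union()` keys sites by `(gene_id, cds_pos)` and fills per-sample
coverage and frequency from the pileups even where a sample did not call
the site. The coverage gate (default 10 reads, the same value as
`min_coverage`) applies to the *comparison*, not to re-calling: a site
called in one sample but under-covered in another is "not comparable"
rather than "not conserved", which prevents shallow samples from faking
editing-site losses. *Conserved* means comparable **and** called — i.e.
passing all four filters — in every sample. Densities in
`gene_summaries()` use the annotated CDS length and are rounded to one
decimal (sites/kb).

## Genomic C/T SNPs: loss and mimicry

`pairwise_cds_snps()` compares homologous CDS position-wise (collinear,
equal-length CDS assumed; unequal lengths are skipped with a warning —
alignment-based comparison is out of scope). `classify_site_fate()` emits
one row per SNP: a C→T SNP at a called editing site is a
`lost_by_thymidine_substitution` — the genome of the second individual
hard-codes the edited state, with the same codon consequence as full
editing (asserted in the tests by comparing the two `CodonChange`
records) — while a C→T SNP away from called sites is `potential_mimicry`:
mapping the second individual's reads to the first's reference would
fabricate an apparently fully edited site. Everything else is
`unaffected`.

## The simulator: what it emulates, and what it does not

`simulate_references()`/`simulate_reads()` generate the statistical
structure the analysis assumes:

- random CDS-like genes (default 300–600 bp, multiples of 3, `ATG`…`TAA`);
- editing sites on C positions with true extents drawn uniformly from
  0.1–1 by default, the range over which organellar editing extents are
  typically reported;
- reads of fixed length (default 100 bp) with start positions uniform over
  the CDS, at a target interior depth (default 50×);
- per-base sequencing errors at a uniform rate (default 0.001),
  substituting uniformly among the three alternatives;
- genomic-DNA contamination as a fraction of reads drawn from the genomic
  template, which never show editing — so the expected observed extent is
  `true_extent × (1 − f)`, the dilution mechanism that depresses extent
  estimates in RNA preparations with residual DNA;
- paralog reads copied from a diverged duplicate (e.g. 4% divergence, 30%
  of reads) and recorded against the target gene;
- a second species differing from the first at configured SNPs.

Everything is deterministic given `seed` (the reference and read stages use
distinct streams derived from it). Reads are emitted as SAM against CDS
coordinates, all forward strand, because the analysis consumes
transcript-space mappings; read mapping itself is out of scope.

Deliberately **not** modeled: fragment-length and GC biases, quality-score
structure, strand bleed-through, splicing, position-dependent error, and
coverage hotspots. Passing tests on this generator therefore demonstrate
the correctness of the counting, filtering and classification logic under
the stated statistical assumptions — not robustness to every artifact of
real libraries. The uniform read placement also means coverage thins
linearly toward CDS ends (a position closer to an end than one read length
sees proportionally fewer reads), which the tests account for by asserting
depth-dependent properties on interior positions.

## Problem sizes and reproducibility

The test suite and the acceptance script run, by design, at desk scale:
200 simulated sites across 8 genes of 450 bp for the filter-contract and
parameter-recovery checks (depth 50 and 1000 respectively), 10-site genes
at depth 500 for the contamination sweep, and 20 seeded replicates of a
two-gene paralog scenario at depth 100. At those sizes the whole suite
completes in well under a minute. Parameter recovery is checked against the
exact 99% binomial band of the true extent given the realized coverage;
with 200 sites roughly two are expected to fall in the 1% tail, and the
test requires at least 99% inside.

`scripts/acceptance.R --seed N --out FILE` recomputes, from scratch, the
minimum passing editing extent (over true extents spanning 1–100% at depth
50) and the minimum passing coverage (over per-gene depths 2–100 with fully
edited sites) and writes them as JSON.

## Interface conventions

Every stage takes a tibble (or paths to standard formats: FASTA via
`Biostrings`, GFF3 via `rtracklayer`, SAM/BAM via `Rsamtools`) and returns
a tibble, so the stages compose with the pipe; `run_pipeline()` wires them
together, writes TSV/JSON outputs plus a run manifest, and supports
`tidy()` (per-site comparison table), `glance()` (one-row totals) and
`autoplot()` (per-gene track: red extent bars over a blue coverage trace
clipped at 100 for display, raw values preserved in the exported TSV).
The package deliberately exposes these functions rather than a shell
entry point: an analysis session in R composes them more flexibly than a
subcommand CLI, and the acceptance script shows the scripted usage.

## Known limitations

- Only C-to-U editing on sense-strand references is considered; U-to-C
  editing and editing in non-coding RNAs are out of scope.
- The error model is a single global binomial rate; it does not capture
  motif- or cycle-dependent error.
- Paralog flagging is a proxy for homology searches against a nuclear
  assembly; it detects contamination by its variant signature, not its
  source locus.
- CDS pairs of unequal length are not aligned; indel-bearing comparisons
  are skipped.
- The comparison treats samples symmetrically; it does not model
  tissue-specific editing differences.
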