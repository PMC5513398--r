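---
title: "Standardized genome and gene-structure statistics: methods and design"
author: "genestats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized genome and gene-structure statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genestats)
```

## Why this package exists

Comparative studies of gene and genome structure depend on descriptive
parameters — assembly size, GC content, exon and intron lengths, coding
amount — that are published inconsistently or not at all. Two recurring
problems motivate the design here:

1. **Undefined or drifting definitions.** "Gene count" may or may not count
   alternative transcripts; "GC content" may or may not be distorted by runs
   of N; "exon" and "CDS" are conflated although exons can contain
   untranslated regions. Every parameter this package reports has exactly one
   definition, stated below and in the function documentation.
2. **Means for skewed data.** Exon and intron lengths within a genome are
   strongly right-skewed, so a mean and a median can differ by a factor of
   two or more. Comparing a genome summarized by a mean against one
   summarized by a median is not a comparison. The package therefore computes
   *both* at every aggregation level, including means and medians of
   per-transcript medians.

The analysis consumes a genome assembly (FASTA of scaffold-or-contig
sequences, SCSs) and its protein-coding gene annotation (GFF3 with at least
`gene`, `mRNA` and `exon` features, optionally `CDS`), and emits complete
primary-data tables plus summary statistics, so that downstream analyses are
never limited to the summaries.

## The analysis model

### Feature hierarchy and introns

GFF3 rows are linked `gene -> mRNA -> exon/CDS` through `ID`/`Parent`
attributes. Genes without an mRNA child (non-coding genes) are skipped and
counted. Introns are rarely annotated by gene predictors, so they are
*inferred*: for adjacent exons $e_i$, $e_{i+1}$ with a gap of at least 1 bp
the intron is $[\mathrm{end}(e_i)+1,\ \mathrm{start}(e_{i+1})-1]$. A zero
gap emits no intron and is logged. Coordinates are 1-based inclusive
throughout (GFF3 native) and every length is $\mathrm{end}-\mathrm{start}+1$,
which makes the conservation identity

$$\text{genomic span} = \sum \text{exon lengths} + \sum \text{intron lengths}$$

hold exactly on every transcript; the test suite asserts it on every fixture.

### One representative transcript per gene

Counting every isoform would pseudo-replicate genes, so exactly one
representative transcript per gene is analyzed: the **longest** by default,
optionally the shortest or the median-length one. "Length" here is the
spliced mRNA length (summed exon length), not the genomic span — robust to a
single enormous intron. For an even number of isoforms the median mode picks
the lower-middle element (it must return an actual transcript), and all ties
break to the lexicographically smallest transcript ID so reruns are
deterministic. Note the deliberate contrast with medians of *metric values*,
which are interpolated (mean of the two middle values): two median
conventions for two different jobs.

The gene's length is the genomic span of its representative transcript
(introns included). Where a `gene` row's coordinates disagree (e.g., they
cover a longer isoform), the representative span wins; the overview reports
both the spliced (`transcript_length_*`) and genomic (`gene_length_*`)
medians so either convention can be compared against.

### Composition metrics

**GC content** is computed two ways, and the difference matters for
comparability:

- *strict* (ambiguity-aware): $100\,(G+C+S)\,/\,(L - \#\{N,R,Y,K,M,B,D,H,V\})$.
  `S` (G or C) is unambiguously GC and counts in both numerator and
  denominator; `W` (A or T) is unambiguously AT and stays in the
  denominator. This value does not change when an assembly gains or loses
  runs of N.
- *naive*: $100\,(G+C)/L$ — the historically common value, reported for
  comparability but dependent on assembly quality.

When a sequence is entirely ambiguous the strict value is undefined and
reported `NA`.

**CpG observed/expected** uses the classical normalization by the separate C
and G counts of the same region:

$$\mathrm{o/e} = \frac{\#\mathrm{CG} \cdot L}{\#C \cdot \#G},$$

undefined when the region has no C or no G. Because CG is its own reverse
complement the statistic is strand-invariant, which the suite checks as a
property. Values well below 1 indicate CpG depletion.

### Contiguity and gene-space contiguity

`Nx`/`Lx` (x ∈ {50, 75, 90}) follow assembly convention: sort lengths
descending, accumulate until the running sum reaches x% of the total; Nx is
the length at which that happens (always a member of the input, never
interpolated) and Lx the number of sequences consumed. **L90pcG** transfers
the idea to gene space: the number of SCSs, taken in decreasing order of
gene content, needed to harbor at least $\lceil 0.9\,\cdot\,\text{gene
count}\rceil$ genes — "cover 90%" must be met with whole genes, hence the
ceiling. An assembly can have a respectable N50 and still scatter its genes
across hundreds of fragments; L90pcG exposes that.

### Density, coverage, strandedness, distributions

- **Density** is number-wise containment: count of contained features per bp
  of container — e.g. intron density of a gene = intron count / gene length.
  Density is related to gene length rather than protein length because
  proteins and mature mRNAs are intron-free. Reported per bp exactly, with a
  per-kb convenience column.
- **Coverage** is length-wise containment: summed contained length /
  container length. Exon coverage + intron coverage = 1 for every
  representative transcript (asserted to 1e-12).
- **Strandedness** partitions transcripts and features into plus / minus /
  unknown.
- The **intron length distribution** uses half-open decade bins
  [1, 10), [10, 100), ... with a final overflow bin; the edges are
  user-configurable, and a value equal to an edge falls in the bin it opens.

### Aggregation and the NA policy

`summary_stats()` produces count/total/min/max/mean/median at every level
(per transcript, per SCS, per assembly). Any aggregate over an empty set is
`NA`, never 0 — a genome with no annotated introns has an *absent* median
intron length, not a zero one, and conflating the two is precisely the kind
of missing-data ambiguity that breaks meta-analyses. Single-exon transcripts
therefore have intron count 0, intron density 0, but `NA` mean/median intron
length.

### Translation

Protein sequences for the representative transcripts are translated from
their CDS segments concatenated in translation order (ascending coordinate
on plus, descending on minus, each segment reverse-complemented as needed).
Only the first segment's phase is honored — downstream phases are validated
against the cumulative frame and warned about on mismatch, since annotation
phases are frequently inconsistent in the wild. Translation is codon-wise
under the standard genetic code; codons containing ambiguity codes are
expanded over their IUPAC meanings and translate to the unique amino acid if
one exists, otherwise `X`. A trailing incomplete codon is dropped, one
terminal stop is trimmed, internal stops stay as `*` with a warning.

## Output files

A run writes 21 numbered files; all except the protein FASTA (00) and the
command file (20) are TSV with a single header row, rows ordered by feature
ID, `NA` for missing values:

| files | content |
|---|---|
| 00 | protein FASTA of the analyzed (representative) transcripts |
| 01 | assembly overview: the standardized parameter set |
| 02–03 | per-SCS data and summary |
| 04–05 | per-transcript data and summary |
| 06–07 | per-CDS-segment data and summary |
| 08–09 | per-exon data and summary |
| 10–11 | per-intron data and summary |
| 12 | intron length distribution |
| 13 | component sizes (coding/exon/intron amounts, remainder) |
| 14–19 | batch TSVs: one line per analyzed genome (general, SCS means/medians, transcript means/medians, component sizes) |
| 20 | ready-made shell commands (e.g., a BUSCO completeness check of file 00) |

Per-run files live in `<out>/<label>/`; the batch files live in `<out>`
itself and gain one line per analyzed genome, so several runs into the same
directory are directly comparable. Appending refuses a batch file whose
header does not match, rather than silently mixing schemas. A machine-readable
run manifest (inputs, MD5 checksums, package version, transcript-choice mode,
date) and a log of skipped features are always written under
`<out>/<label>/logs/` — reporting *what was skipped and why* is part of the
output contract. The overview always contains, at minimum: assembly size with
and without Ns, strict and naive GC, gene count, median transcript length,
median CDS length/count/coverage, coding amount, intron count/length/density/
coverage medians, intron amount, Nx/Lx and L90pcG.

File generation is individually switchable (`outputs =` a set of file
numbers), and output is UTF-8 with Unix line endings; a rerun on identical
input into a fresh directory is byte-identical, which the suite verifies.

## The synthetic genome generator

`generate_fixture()` builds assemblies with exactly known truth so that
every kernel and every roll-up can be validated without downloading a
genome. It emulates the structural features the analysis measures:
multi-scaffold assemblies with N runs and ambiguity codes, multi-transcript
genes on both strands, multi-exon transcripts whose CDS is a
contiguous-in-splice-space, UTR-trimmed subset of the exons with valid
phases, and non-coding genes that must be skipped. Alternative isoforms are
exon-skipping subsets and hence strictly shorter than the full-length
transcript, which makes the identity of the "longest" representative known
at generation time. It does *not* emulate codon bias, repeats, homology, or
overlapping genes — so passing its tests demonstrates metric correctness,
not robustness to every annotation pathology in the wild.

The defaults are the package's study conditions: 8 scaffolds of 400–700 kb,
200 genes, 1–3 transcripts per gene, 1–12 exons per transcript, exon lengths
lognormal (meanlog 5, sdlog 0.6 log-bp, floored at 30 bp; median ≈ 150 bp),
intron lengths lognormal (meanlog 6, sdlog 1 log-bp; median ≈ 400 bp,
mean ≈ 660 bp), GC 0.35, ambiguity rate 10⁻³, N-run rate 5×10⁻⁴, 40% of
genes on the minus strand. The lognormal skew is deliberate: on such data
the mean of per-transcript mean intron lengths strictly exceeds the mean of
per-transcript medians, reproducing the mean-vs-median divergence the
package is built to expose; the suite asserts the inequality.

Ground truth is computed during generation by independent naive counting —
`table()` over the final sequence characters, prefix scans for Nx/Lx and
L90pcG, base sums and medians over the recorded structure lists — never by
calling the analysis code. The test suite then demands exact agreement
(integers) or 1e-9 (ratios) between analysis and truth for every overview
parameter.

`worked_micro_genome()` is the hand-auditable complement: 2 scaffolds
(100 bp and 60 bp), 3 coding genes, 1 non-coding gene. Every expected value
is frozen from hand arithmetic, e.g.: assembly 160 bp with Ns, 150 bp
without; strict GC $100\cdot 80/150 = 53.33$; N50 = 100 with L50 = 1;
genes split 2/1 across scaffolds so L90pcG = 2 (cumulative 2, 3 ≥
⌈0.9·3⌉ = 3); coding amount 43 bp; intron amount 22 bp; median intron
length 6 bp.

## Numerical and degenerate-input choices

- Cumulative-fraction targets are compared with a 1e-9 slack
  (`running ≥ f·total − 1e-9`) because `0.9 * 10` is not exactly 9 in
  floating point; without the slack L90 of ten equal scaffolds would need an
  eleventh.
- CpG counting promotes to double before multiplying: `#C · #G` overflows
  32-bit integers on scaffold-scale regions.
- GC of an all-ambiguous region, CpG of a C-less or G-less region, and every
  aggregate over an empty set are `NA`; densities of an empty set are 0 only
  when the container exists (a real transcript with no introns).
- Empty annotation on a valid assembly still produces full assembly-level
  statistics, with all gene-level aggregates `NA`.
- Transcripts whose exons span multiple scaffolds or strands, duplicated
  (discontinuous) `gene` IDs, overlapping exons, and coverage exceeding its
  container are rejected with named errors rather than absorbed.

## Problem sizes used in the checks

The validation suite runs entirely on generated data: the 200-gene
lognormal genome above (~4 Mb assembly, analyzed in a few seconds), a
handful of 2-scaffold/4–8-gene fixtures for I/O and batch contracts, the
micro genome, and 1 000 random small inputs per metric kernel against
brute-force oracles. These sizes were chosen so the full suite exercises
every code path while remaining quick to run; the pipeline itself has no
size-dependent logic and handles genome-scale input (hundreds of Mb) the
same way, only slower.

## Known limitations

- UTR analysis is out of scope; exon vs CDS differences are reported, but
  UTRs are not delineated.
- Non-coding genes are counted and skipped, not characterized.
- Only `mRNA` children mark a gene as protein-coding; predictors emitting
  `transcript` rows for coding genes need a rename pass first.
- Repeat/TE content, k-mer spectra and codon usage are not computed.
- The standard genetic code is assumed; organelle/alternative codes are not
  supported.
- Partial genes and pseudogenes are analyzed exactly as annotated.
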