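# genestats

Standardized descriptive statistics for genome assemblies and their
protein-coding gene annotations.

## The problem

Publishing a genome means publishing numbers — assembly size, GC content,
gene count, exon and intron lengths, coding amount — but those numbers are
rarely defined the same way twice. Gene counts silently include alternative
isoforms; GC content shrinks when an assembly gains runs of N; "exon" and
"CDS" get conflated although exons can carry untranslated regions; and
strongly right-skewed length distributions get summarized by a mean in one
paper and a median in the next. Meta-analyses built on such tables inherit
all of that noise plus a large fraction of missing values.

`genestats` computes one standardized, fully defined parameter set from two
inputs — a FASTA assembly of scaffold-or-contig sequences (SCSs) and a GFF3
annotation containing at least `gene`, `mRNA` and `exon` features — and
writes both the summary statistics *and* the complete primary data tables,
so downstream analyses are never limited to the summaries.

Core definitions (details and formulas in the vignette,
`vignettes/genome-annotation-statistics.Rmd`):

- **One representative transcript per gene** (longest spliced length by
  default; `shortest`/`median` selectable) — no isoform pseudo-replication.
  Gene length = genomic span of that transcript, introns included.
- **Introns inferred** from exon coordinates: adjacent exons with a gap ≥
  1 bp delimit an intron; span = Σ exons + Σ introns holds exactly.
- **GC two ways**: strict, ambiguity-aware
  100·(G+C+S)/(L − #{N,R,Y,K,M,B,D,H,V}), independent of assembly quality;
  and the naive G+C over total length, for comparability.
- **CpG o/e** = #CG·L/(#C·#G), the classical C·G-normalized depletion
  statistic; strand-invariant.
- **Contiguity**: N50/L50, N75/L75, N90/L90 over SCS lengths, plus
  **L90pcG** — the number of SCSs, in decreasing order of gene content,
  needed to harbor ≥ 90% of all protein-coding genes.
- **Density** (count per bp of container, e.g. introns per bp of gene) and
  **coverage** (summed contained length per container length; exon +
  intron coverage = 1 per transcript).
- **Means *and* medians at every level**, including means/medians of
  per-transcript medians; aggregates over empty sets are `NA`, never 0.

## Worked example

The package ships a hand-auditable micro genome (2 scaffolds, 3 coding
genes, 1 non-coding gene) whose every value is documented in the vignette:

```r
library(genestats)
g <- worked_micro_genome(tempfile("micro"))
res <- run_single(g$fasta, g$gff3, label = "micro", out_dir = "demo_out")
res$analysis
#> <genome_analysis>
#>   assembly: 2 SCSs, 160 bp (150 bp without Ns), GC 53.33% (strict) / 50.00% (naive)
#>   contiguity: N50 100 (L50 1), N90 60 (L90 2), L90pcG 2
#>   genes: 3 analyzed (1 without mRNA skipped), representative = longest transcript
#>   features: 6 exons, 3 introns, 5 CDS segments; coding amount 43 bp
```

Reading the printout: the 160 bp assembly contains a 10 bp N run, so the
strict GC (53.33%, computed on the 150 unambiguous bases) differs from the
naive one (50.00%); the three genes sit 2/1 on the two scaffolds, so 2 SCSs
already harbor ⌈0.9·3⌉ = 3 genes (L90pcG = 2); and the gene without an mRNA
child was skipped, not silently dropped.

The run directory holds the numbered report suite (21 files; all TSV except
the protein FASTA `00` and the shell-command file `20`). The overview begins:

```
parameter	value
scs_count	2
assembly_size_with_n	160
assembly_size_without_n	150
...
exon_amount	68
coding_amount	43
intron_amount	22
```

and the component-size table partitions the assembly exactly:

```
component	length_bp
coding_amount	43
exon_amount	68
intron_amount	22
remainder	70
assembly_size	160
```

Per-feature primary data live in files `02`–`11` (one row per SCS,
transcript, CDS segment, exon, intron), e.g. the transcript table:

```
gene_id  transcript_id  strand  exon_count  intron_count  exon_length_added  intron_length_mean ...
g1       g1.t1          +       2           1             20                 10
g2       g2.t1          -       1           0             20                 NA
```

Note `NA`, not 0, for the intron length mean of the intron-less gene.

Batch mode compares genomes: `run_batch("manifest.tsv", "out/")` processes a
3-column manifest (label, fasta, gff3) serially and appends one line per
genome to the shared batch TSVs (`14`–`19`). A command-line wrapper is
installed at `inst/cli/genestats.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/genestats.R", package="genestats"))')" \
  --fasta asm.fa --gff ann.gff3 --name mygenome --out results/
```

## Synthetic genomes with known truth

`generate_fixture(fixture_spec(...))` writes a structurally realistic
assembly + annotation (multi-scaffold, N runs, IUPAC ambiguity, both
strands, multi-exon/multi-isoform genes with phased CDS) together with
ground-truth values for every overview parameter, computed during
generation by independent naive counting. The lognormal length draws make
per-transcript means exceed medians — the skew that motivates reporting
both.

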