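Package: genestats
Title: Standardized Descriptive Statistics for Genome Assemblies and
    Protein-Coding Gene Annotations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a standardized, fully defined set of genome and
    gene-structure parameters from a genome assembly (FASTA) and its
    protein-coding gene annotation (GFF3): assembly contiguity (N50/L50,
    N75/L75, N90/L90, L90pcG), ambiguity-aware GC content, CpG
    observed/expected ratios, exon/intron/CDS length statistics with both
    means and medians at every aggregation level, feature densities and
    coverages, and strandedness. Introns are inferred from exon
    coordinates, one representative transcript per gene is analyzed, and
    results are written as a numbered suite of TSV report files plus a
    protein FASTA, with a batch mode for cross-genome comparison. A
    synthetic genome generator with independently computed ground truth
    supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
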