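# Shared genome fixtures, memoized so the expensive lognormal genome is
# generated and analyzed once per test run.

.cache <- new.env(parent = emptyenv())

# study-condition fixture: 200 genes, lognormal exon/intron lengths,
# ambiguity codes and N runs, 3 non-coding genes to exercise skipping
big_fixture <- function() {
  if (is.null(.cache$big)) {
    fx <- generate_fixture(
      fixture_spec(noncoding_gene_count = 3, rng_seed = 20260920),
      tempfile("bigfx"))
    .cache$big <- list(fx = fx, an = analyze_genome(fx$fasta, fx$gff3))
  }
  .cache$big
}

micro_run <- function() {
  if (is.null(.cache$micro)) {
    g <- worked_micro_genome(tempfile("micro"))
    .cache$micro <- list(g = g, an = analyze_genome(g$fasta, g$gff3))
  }
  .cache$micro
}

small_fixture <- function(seed = 7, genes = 6) {
  generate_fixture(
    fixture_spec(scs_count = 2, scs_length_range = c(40000, 60000),
                 gene_count = genes, exons_per_transcript_range = c(1, 5),
                 intron_length_meanlog = 5, rng_seed = seed),
    tempfile("smallfx"))
}

# write a GFF3 from row strings, prefixing the version directive
write_gff <- function(rows, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

write_fasta <- function(named_seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(named_seqs), function(id) {
    c(paste0(">", id), named_seqs[[id]])
  })), path)
  path
}

# a bare transcript model for kernel-level tests
make_transcript <- function(id = "t1", seqid = "s1", strand = "+",
                            exons, cds = NULL) {
  tr <- list(id = id, gene_id = "g1", seqid = seqid, strand = strand,
             exons = exons, cds = cds, introns = NULL)
  infer_introns(tr, warn = FALSE)
}
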