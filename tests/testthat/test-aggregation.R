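test_that("summary bundle computes count/total/min/max/mean/median with NA policy", {
  s <- summary_stats(c(1, 2, 3, 4))
  expect_equal(s[c("count", "total", "mean", "median")],
               list(count = 4L, total = 10, mean = 2.5, median = 2.5))
  s <- summary_stats(5)
  expect_true(all(unlist(s[c("min", "max", "mean", "median")]) == 5))
  s <- summary_stats(numeric(0))
  expect_equal(s$count, 0L)
  expect_true(all(is.na(unlist(s[-1]))))
  # NA values are dropped, not propagated and not counted
  expect_equal(summary_stats(c(1, NA, 3))$count, 2L)
  expect_equal(summary_stats(c(1, NA, 3))$mean, 2)
})

test_that("per-transcript rollup reports lengths, densities and coverages", {
  m <- micro_run()
  tt <- m$an$tables$transcript
  g3 <- tt[tt$gene_id == "g3", ]
  expect_equal(g3$exon_count, 3)
  expect_equal(g3$exon_length_added, 28)
  expect_equal(g3$exon_length_mean, 28 / 3)
  expect_equal(g3$exon_length_median, 10)
  expect_equal(g3$intron_count, 2)
  expect_equal(g3$intron_length_added, 12)
  expect_equal(g3$gene_length, 40)
  expect_equal(g3$intron_density, 2 / 40)
  expect_equal(g3$cds_coverage, 14 / 40)
  expect_equal(g3$protein_length, 4)

  # single-exon transcript: zero intron count, NA means, zero density
  g2 <- tt[tt$gene_id == "g2", ]
  expect_equal(g2$intron_count, 0)
  expect_true(is.na(g2$intron_length_mean))
  expect_true(is.na(g2$intron_length_median))
  expect_equal(g2$intron_density, 0)
  expect_equal(g2$exon_coverage, 1)
  expect_equal(g2$intron_coverage, 0)
})

test_that("a transcript with exon lengths 100/200/300 rolls up by hand arithmetic", {
  fa <- parse_fasta(write_fasta(list(s1 = strrep("ACGT", 200))))
  tr <- make_transcript(exons = data.frame(start = c(1, 111, 321),
                                           end = c(100, 310, 620)))
  row <- per_transcript_rollup(tr, fa)
  expect_equal(row$exon_length_mean, 200)
  expect_equal(row$exon_length_median, 200)
  expect_equal(row$exon_length_added, 600)
  expect_true(is.na(row$cds_count))
  expect_true(is.na(row$cds_coverage))
})

test_that("exon and intron coverage partition every representative transcript", {
  b <- big_fixture()
  tt <- b$an$tables$transcript
  expect_true(all(abs(tt$exon_coverage + tt$intron_coverage - 1) < 1e-12))
})

test_that("assembly size splits into totals with and without Ns", {
  m <- micro_run()
  expect_equal(m$an$overview$assembly_size_with_n, 160)
  expect_equal(m$an$overview$assembly_size_without_n, 150)
  b <- big_fixture()
  expect_equal(b$an$overview$assembly_size_with_n -
               b$an$overview$assembly_size_without_n,
               b$an$overview$assembly_n_count)
})

test_that("coding amount <= exon amount <= assembly size", {
  for (run in list(micro_run()$an, big_fixture()$an)) {
    ov <- run$overview
    expect_lte(ov$coding_amount, ov$exon_amount)
    expect_lte(ov$exon_amount, ov$assembly_size_with_n)
  }
})

test_that("per-SCS gene counts sum to the assembly gene count", {
  for (run in list(micro_run()$an, big_fixture()$an)) {
    expect_equal(sum(run$tables$scs$gene_count), run$overview$gene_count)
  }
})

test_that("mean of means equals mean of medians on symmetric exon lengths", {
  # two genes, each with symmetric exon lengths (10, 20, 30)
  rows <- unlist(lapply(c(1, 1001), function(off) {
    s <- function(x) off + x
    c(sprintf("s1\tt\tgene\t%d\t%d\t.\t+\t.\tID=g%d", s(0), s(99), off),
      sprintf("s1\tt\tmRNA\t%d\t%d\t.\t+\t.\tID=g%d.t1;Parent=g%d",
              s(0), s(99), off, off),
      sprintf("s1\tt\texon\t%d\t%d\t.\t+\t.\tParent=g%d.t1", s(0), s(9), off),
      sprintf("s1\tt\texon\t%d\t%d\t.\t+\t.\tParent=g%d.t1", s(20), s(39), off),
      sprintf("s1\tt\texon\t%d\t%d\t.\t+\t.\tParent=g%d.t1", s(50), s(79), off))
  }))
  fa <- write_fasta(list(s1 = strrep("ACGT", 500)))
  an <- analyze_genome(fa, write_gff(rows))
  expect_equal(an$overview$per_transcript_mean_exon_length_mean,
               an$overview$per_transcript_median_exon_length_mean,
               tolerance = 1e-9)
})

test_that("empty protein-coding annotation still yields assembly statistics", {
  fa <- write_fasta(list(s1 = strrep("ACGTN", 20)))
  gff <- write_gff("s1\tt\tgene\t10\t40\t.\t+\t.\tID=nc1")  # no mRNA
  an <- analyze_genome(fa, gff)
  ov <- an$overview
  expect_equal(ov$gene_count, 0)
  expect_equal(ov$gene_skipped_count, 1)
  expect_equal(ov$assembly_size_with_n, 100)
  expect_equal(ov$n50, 100)
  expect_true(is.na(ov$exon_amount))
  expect_true(is.na(ov$transcript_length_median))
  expect_true(is.na(ov$l90pcg))
})
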