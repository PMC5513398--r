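minimal_rows <- c(
  "s1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
  "s1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
  "s1\tsrc\texon\t100\t200\t.\t+\t.\tID=g1.t1.e1;Parent=g1.t1"
)

test_that("a minimal gene/mRNA/exon hierarchy parses", {
  gs <- parse_gff3(write_gff(minimal_rows))
  expect_s3_class(gs, "gene_set")
  expect_length(gs$genes, 1L)
  expect_equal(gs$skipped_gene_count, 0L)
  tr <- gs$genes$g1$transcripts$g1.t1
  expect_equal(nrow(tr$exons), 1L)
  expect_null(tr$cds)
  expect_equal(nrow(infer_introns(tr)$introns), 0L)
})

test_that("genes without an mRNA child are skipped and counted", {
  gs <- parse_gff3(write_gff(c(minimal_rows,
                               "s1\tsrc\tgene\t300\t400\t.\t+\t.\tID=g2")))
  expect_length(gs$genes, 1L)
  expect_equal(gs$skipped_gene_count, 1L)
  expect_equal(gs$skipped_gene_ids, "g2")
})

test_that("structural errors are reported with names and line numbers", {
  # wrong column count, naming the offending line
  bad <- write_gff(c(minimal_rows, "s1\tsrc\tgene\t1\t2"))
  expect_error(parse_gff3(bad), "line 5")

  # orphan mRNA
  orphan <- write_gff(c(minimal_rows[1],
                        "s1\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=tx;Parent=ghost"))
  expect_error(parse_gff3(orphan), "absent")

  # exon on a different SCS than its mRNA
  wrong_seq <- write_gff(c(minimal_rows[1:2],
                           "s2\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t1"))
  expect_error(parse_gff3(wrong_seq), "s2")

  # duplicated (discontinuous) gene IDs
  dup <- write_gff(c(minimal_rows, minimal_rows[1]))
  expect_error(parse_gff3(dup), "discontinuous|duplicated")
})

test_that("introns are inferred from exon gaps", {
  tr <- list(id = "t", gene_id = "g", seqid = "s1", strand = "+",
             exons = data.frame(start = c(1, 21), end = c(10, 30)),
             cds = NULL, introns = NULL)
  out <- infer_introns(tr)
  expect_equal(out$introns, data.frame(start = 11, end = 20))
  expect_equal(out$introns$end - out$introns$start + 1, 10)

  single <- infer_introns(make_transcript(exons = data.frame(start = 5, end = 50)))
  expect_equal(nrow(single$introns), 0L)

  zero_gap <- list(id = "tz", gene_id = "g", seqid = "s1", strand = "+",
                   exons = data.frame(start = c(1, 11), end = c(10, 20)),
                   cds = NULL, introns = NULL)
  expect_warning(out <- infer_introns(zero_gap), "zero-gap")
  expect_equal(nrow(out$introns), 0L)

  overlapping <- list(id = "tov", gene_id = "g", seqid = "s1", strand = "+",
                      exons = data.frame(start = c(1, 5), end = c(10, 20)),
                      cds = NULL, introns = NULL)
  expect_error(infer_introns(overlapping), "tov")
})

test_that("representative selection uses spliced length with ID tie-break", {
  mk_gene <- function(lens, ids) {
    trs <- lapply(seq_along(lens), function(i) {
      list(id = ids[i], gene_id = "g", seqid = "s1", strand = "+",
           exons = data.frame(start = 1, end = lens[i]), cds = NULL,
           introns = NULL)
    })
    list(id = "g", transcripts = stats::setNames(trs, ids))
  }
  g <- mk_gene(c(300, 500), c("a", "b"))
  expect_equal(select_representative(g, "longest")$id, "b")
  expect_equal(select_representative(g, "shortest")$id, "a")

  # lower-middle median for even transcript counts
  g <- mk_gene(c(100, 200, 300, 400), c("a", "b", "c", "d"))
  expect_equal(select_representative(g, "median")$id, "b")

  # equal lengths: lexicographically smallest ID wins
  g <- mk_gene(c(250, 250), c("mRNA-b", "mRNA-a"))
  expect_equal(select_representative(g, "longest")$id, "mRNA-a")
})

test_that("parser totals on a generated fixture equal generator truth", {
  fx <- small_fixture(seed = 11, genes = 8)
  gs <- parse_gff3(fx$gff3)
  expect_length(gs$genes, fx$truth$gene_count)
  an <- analyze_genome(fx$fasta, gs)
  expect_equal(an$overview$exon_count, fx$truth$exon_count)
  expect_equal(an$overview$intron_count, fx$truth$intron_count)
  # exactly one representative transcript per analyzed gene
  expect_equal(nrow(an$tables$transcript), length(gs$genes))
})

test_that("genomic span equals summed exon plus intron length on all fixtures", {
  b <- big_fixture()
  tt <- b$an$tables$transcript
  expect_true(all(tt$gene_length ==
                  tt$exon_length_added + tt$intron_length_added))
})
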