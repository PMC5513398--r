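test_that("FASTA parsing handles wrapping, case, U and validation", {
  fa <- parse_fasta(write_fasta(list(s1 = "ACGT")))
  expect_length(fa, 1L)
  expect_equal(unname(Biostrings::width(fa)), 4L)

  fa <- parse_fasta(write_fasta(list(s1 = c("AC", "GT"), s2 = "NNNN")))
  expect_equal(unname(Biostrings::width(fa)), c(4L, 4L))

  # soft-masked lowercase and U are normalized
  fa <- parse_fasta(write_fasta(list(s1 = "acgu")))
  expect_equal(as.character(fa[["s1"]]), "ACGT")

  # header is trimmed at the first whitespace
  p <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 Homo something", "ACGT"), p)
  expect_equal(names(parse_fasta(p)), "chr1")

  expect_error(parse_fasta(write_fasta(list(s1 = "ACGT", s1 = "GGGG"))),
               "duplicate")
  expect_error(parse_fasta(write_fasta(list(s1 = "ACXT"))), "position 3")
  p2 <- tempfile(fileext = ".fa")
  writeLines(c(">s1", ">s2", "ACGT"), p2)
  expect_error(parse_fasta(p2), "empty")
})

test_that("fixture assembly ids and lengths equal generator truth", {
  fx <- small_fixture(seed = 21, genes = 4)
  fa <- parse_fasta(fx$fasta)
  expect_equal(names(fa), fx$detail$scs_ids)
  expect_equal(unname(Biostrings::width(fa)), fx$detail$scs_len)
})

test_that("subsequence extraction is 1-based inclusive and strand-aware", {
  fa <- parse_fasta(write_fasta(list(s1 = "ACGTACGT")))
  expect_equal(extract_sequence(fa, "s1", 3, 5, "+"), "GTA")
  expect_equal(extract_sequence(fa, "s1", 3, 5, "-"), "TAC")
  expect_equal(extract_sequence(fa, "s1", 1, 8, "+"), "ACGTACGT")
  expect_error(extract_sequence(fa, "s1", 5, 9, "+"), "exceeds")
  expect_error(extract_sequence(fa, "s2", 1, 2, "+"), "not present")
})

test_that("reverse complement is an IUPAC-aware involution", {
  expect_equal(reverse_complement("RYKMSWBDHVN"),
               oracle_revcomp("RYKMSWBDHVN"))
  set.seed(201)
  for (i in 1:100) {
    s <- rand_seq(sample(1:40, 1), IUPAC)
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
    expect_equal(nchar(reverse_complement(s)), nchar(s))
  }
})

test_that("CDS translation honors phase, strand and stop conventions", {
  fa <- parse_fasta(write_fasta(list(s1 = "ATGAAATGA")))
  tr <- make_transcript(exons = data.frame(start = 1, end = 9),
                        cds = data.frame(start = 1, end = 9, phase = 0))
  expect_equal(translate_cds(tr, fa), "MK")  # terminal stop trimmed

  fa2 <- parse_fasta(write_fasta(list(s1 = "ATGGGT")))
  tr0 <- make_transcript(exons = data.frame(start = 1, end = 6),
                         cds = data.frame(start = 1, end = 6, phase = 0))
  expect_equal(translate_cds(tr0, fa2), "MG")
  tr1 <- make_transcript(exons = data.frame(start = 1, end = 6),
                         cds = data.frame(start = 1, end = 6, phase = 1))
  expect_equal(translate_cds(tr1, fa2), "W")  # TGG, trailing 2 bases dropped

  # minus strand: the plus-strand reverse complement reads ATGAAATGA
  fa3 <- parse_fasta(write_fasta(list(s1 = reverse_complement("ATGAAATGA"))))
  tr3 <- make_transcript(strand = "-",
                         exons = data.frame(start = 1, end = 9),
                         cds = data.frame(start = 1, end = 9, phase = 0))
  expect_equal(translate_cds(tr3, fa3), "MK")

  # internal stop is kept as * with a warning
  fa4 <- parse_fasta(write_fasta(list(s1 = "ATGTGAAAA")))
  tr4 <- make_transcript(exons = data.frame(start = 1, end = 9),
                         cds = data.frame(start = 1, end = 9, phase = 0))
  expect_warning(aa <- translate_cds(tr4, fa4), "internal stop")
  expect_equal(aa, "M*K")

  # shorter than one codon after phase trim
  tr5 <- make_transcript(exons = data.frame(start = 1, end = 3),
                         cds = data.frame(start = 1, end = 3, phase = 2))
  expect_error(translate_cds(tr5, fa4), "shorter")
  expect_error(translate_cds(make_transcript(
    exons = data.frame(start = 1, end = 9)), fa4), "no CDS")
})

test_that("protein length follows floor((CDS - phase)/3) minus trimmed stop", {
  b <- big_fixture()
  tt <- b$an$tables$transcript
  with_cds <- tt[!is.na(tt$cds_count), ]
  # phases of first segments are 0 in the fixture annotation
  exp_codons <- floor(with_cds$cds_length_added / 3)
  expect_true(all(with_cds$protein_length %in%
                  c(exp_codons, exp_codons - 1L)))
})
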