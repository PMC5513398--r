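test_that("GC content handles ambiguity codes in numerator and denominator", {
  r <- gc_content("GCGC")
  expect_equal(r$gc_strict, 100)
  expect_equal(r$gc_naive, 100)

  # S counts as G/C in both strict terms; N leaves the strict denominator
  r <- gc_content("GCSN")
  expect_equal(r$gc_strict, 100)
  expect_equal(r$gc_naive, 50)
  expect_equal(r$denominator_strict, 3)
  expect_equal(r$denominator_total, 4)

  # W is unambiguous for GC status and stays in the strict denominator
  r <- gc_content("ATWN")
  expect_equal(r$gc_strict, 0)
  expect_equal(r$denominator_strict, 3)
  expect_equal(r$gc_naive, 0)

  expect_true(is.na(gc_content("NNNN")$gc_strict))
  expect_error(gc_content(""), "empty")
})

test_that("GC content matches character-scan oracle on random IUPAC strings", {
  set.seed(101)
  for (i in 1:300) {
    s <- rand_seq(sample(1:60, 1), IUPAC)
    got <- gc_content(s)
    want <- oracle_gc(s)
    expect_equal(got$gc_strict, want$strict, tolerance = 1e-12)
    expect_equal(got$gc_naive, want$naive, tolerance = 1e-12)
  }
  # clean limit: no ambiguity codes -> the two calculations coincide
  for (i in 1:100) {
    s <- rand_seq(sample(1:60, 1))
    r <- gc_content(s)
    expect_identical(r$gc_strict, r$gc_naive)
  }
})

test_that("CpG o/e follows the C*G normalization and handles degenerate input", {
  expect_equal(cpg_oe("CGCG"), 2.0)
  expect_equal(cpg_oe("CCGG"), 1.0)
  expect_true(is.na(cpg_oe("AAAA")))
  expect_true(is.na(cpg_oe("CCCC")))  # no G
  expect_error(cpg_oe(""), "empty")
})

test_that("CpG o/e matches enumeration oracle and is revcomp-invariant", {
  set.seed(102)
  for (i in 1:300) {
    s <- rand_seq(sample(2:50, 1))
    expect_equal(cpg_oe(s), oracle_cpg(s), tolerance = 1e-12)
    expect_equal(cpg_oe(reverse_complement(s)), cpg_oe(s), tolerance = 1e-12)
  }
})

test_that("Nx/Lx agree with the cumulative-sum definition", {
  r <- nx_lx(c(10, 8, 5, 3, 2), 0.5)
  expect_equal(r$n, 8)
  expect_equal(r$l, 2)
  r <- nx_lx(c(10, 8, 5, 3, 2), 0.9)
  expect_equal(r$n, 3)
  expect_equal(r$l, 4)
  r <- nx_lx(7, 0.5)
  expect_equal(r$n, 7)
  expect_equal(r$l, 1)
  expect_error(nx_lx(numeric(0), 0.5), "empty")
  expect_error(nx_lx(c(1, 2), 1.5), "fraction")

  set.seed(103)
  for (i in 1:200) {
    lens <- sample(1:500, sample(1:100, 1), replace = TRUE)
    f <- sample(c(0.5, 0.75, 0.9), 1)
    got <- nx_lx(lens, f)
    want <- oracle_nx(lens, f)
    expect_equal(got$n, unname(want["n"]))
    expect_equal(got$l, unname(want["l"]))
    # Nx is a member of the input multiset
    expect_true(got$n %in% lens)
  }
})

test_that("N50 >= N75 >= N90 and L50 <= L75 <= L90", {
  set.seed(104)
  for (i in 1:50) {
    lens <- sample(1:1000, sample(2:50, 1), replace = TRUE)
    n <- vapply(c(0.5, 0.75, 0.9), function(f) nx_lx(lens, f)$n, numeric(1))
    l <- vapply(c(0.5, 0.75, 0.9), function(f) nx_lx(lens, f)$l, numeric(1))
    expect_true(all(diff(n) <= 0))
    expect_true(all(diff(l) >= 0))
  }
})

test_that("L90pcG counts gene-bearing SCSs needed for 90% of the genes", {
  expect_equal(l90pcg(c(5, 3, 2)), 3)   # target ceil(9) reached at 3rd SCS
  expect_equal(l90pcg(10), 1)
  expect_equal(l90pcg(c(4, 4, 1, 1, 0)), 3)
  expect_error(l90pcg(c(0, 0)), "undefined")

  set.seed(105)
  for (i in 1:200) {
    counts <- sample(0:30, sample(1:40, 1), replace = TRUE)
    if (sum(counts) == 0) counts <- c(counts, 1)
    got <- l90pcg(counts)
    expect_equal(got, oracle_l90(counts))
    # zero-gene SCSs are never needed
    expect_lte(got, sum(counts > 0))
  }
})

test_that("increasing one SCS's share of a fixed gene total cannot raise L90pcG", {
  set.seed(106)
  for (i in 1:50) {
    counts <- sample(1:20, 6, replace = TRUE)
    before <- l90pcg(counts)
    # move genes from the smallest onto the largest SCS, total unchanged
    j <- which.max(counts); k <- which.min(counts)
    if (j == k) next
    moved <- counts
    moved[j] <- moved[j] + moved[k]
    moved[k] <- 0
    if (sum(moved) == 0) next
    expect_lte(l90pcg(moved), before)
  }
})

test_that("density and coverage implement number-wise and length-wise ratios", {
  expect_equal(feature_density(4, 1000), 0.004)
  expect_equal(feature_density(0, 123), 0)
  expect_equal(feature_density(1, 500), 0.002)
  expect_error(feature_density(1, 0), "zero-length")

  expect_equal(feature_coverage(300, 1000), 0.3)
  expect_equal(feature_coverage(0, 10), 0)
  expect_equal(feature_coverage(10, 10), 1)
  expect_error(feature_coverage(11, 10), "exceeds")
  expect_error(feature_coverage(1, 0), "zero-length")
})

test_that("strandedness partitions features into plus/minus/unknown", {
  expect_equal(strandedness(c("+", "+", "-")),
               c(plus = 2, minus = 1, unknown = 0))
  expect_equal(strandedness(character(0)), c(plus = 0, minus = 0, unknown = 0))
  expect_equal(strandedness(c("+", ".", NA, "-")),
               c(plus = 1, minus = 1, unknown = 2))
  set.seed(107)
  s <- sample(c("+", "-", "."), 50, replace = TRUE)
  expect_equal(sum(strandedness(s)), 50)
})

test_that("length histogram uses half-open decade bins with overflow", {
  h <- length_histogram(c(5, 50, 500), bin_edges = c(1, 10, 100))
  expect_equal(h$count, c(1, 1, 1))
  expect_equal(h$bin_end, c(10, 100, Inf))

  # a value equal to an edge falls into the bin that edge opens
  h <- length_histogram(10, bin_edges = c(1, 10, 100))
  expect_equal(h$count, c(0, 1, 0))

  set.seed(108)
  lens <- ceiling(rlnorm(1000, 6, 1))
  h <- length_histogram(lens)
  expect_equal(sum(h$count), 1000)

  expect_error(length_histogram(5, bin_edges = c(10, 1)), "increasing")
  expect_error(length_histogram(0.5, bin_edges = c(1, 10)), "below")
})
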