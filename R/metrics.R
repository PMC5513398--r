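# Pure metric kernels: composition, contiguity, density/coverage,
# strandedness, length histograms. Each is a total function over a sequence
# or a collection of lengths/counts; no file I/O here.

letter_counts <- function(seq) {
  x <- if (is.character(seq)) Biostrings::DNAString(seq) else seq
  counts <- Biostrings::letterFrequency(x, IUPAC_LETTERS, OR = 0)
  stats::setNames(as.numeric(counts), IUPAC_LETTERS)
}

#' GC content, strict (ambiguity-aware) and naive
#'
#' Two percentages are computed. The strict variant counts G, C and S in the
#' numerator and excludes every base ambiguous with respect to G/C status
#' (N, R, Y, K, M, B, D, H, V) from the denominator; W and A/T stay in the
#' denominator. The naive variant is G+C over total length and depends on
#' assembly quality (it shrinks with N content), which is why the strict
#' variant is preferred for genome comparison.
#'
#' @param seq A non-empty IUPAC nucleotide string.
#' @return A list with `gc_strict` (percent, `NA` when no unambiguous base
#'   remains), `gc_naive` (percent), `denominator_strict` and
#'   `denominator_total` (bp).
#' @examples
#' gc_content("GCSN") # strict 100, naive 50
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) {
    stop("GC content is undefined for an empty sequence", call. = FALSE)
  }
  cnt <- letter_counts(seq)
  total <- nchar(seq)
  strict_den <- total - sum(cnt[GC_AMBIGUOUS])
  strict_num <- cnt[["G"]] + cnt[["C"]] + cnt[["S"]]
  list(
    gc_strict = if (strict_den > 0) 100 * strict_num / strict_den else NA_real_,
    gc_naive = 100 * (cnt[["G"]] + cnt[["C"]]) / total,
    denominator_strict = strict_den,
    denominator_total = total
  )
}

#' CpG observed/expected ratio
#'
#' Observed is the count of CG dinucleotides over all adjacent positions;
#' expected follows the classical normalization by the separate C and G
#' counts of the same region: o/e = observed * L / (#C * #G). Values well
#' below 1 indicate CpG depletion (e.g., through methylation-driven
#' deamination). Undefined (`NA`) when the region has no C or no G.
#'
#' @param seq A non-empty nucleotide string.
#' @return A single number, or `NA` when undefined.
#' @examples
#' cpg_oe("CGCG") # 2.0
#' @export
cpg_oe <- function(seq) {
  if (!nzchar(seq)) {
    stop("CpG o/e is undefined for an empty sequence", call. = FALSE)
  }
  x <- Biostrings::DNAString(seq)
  obs <- Biostrings::countPattern("CG", x, fixed = TRUE)
  cnt <- Biostrings::letterFrequency(x, c("C", "G"), OR = 0)
  if (cnt[[1L]] == 0 || cnt[[2L]] == 0) {
    return(NA_real_)
  }
  as.numeric(obs) * length(x) / (as.numeric(cnt[[1L]]) * cnt[[2L]])
}

#' Nx / Lx contiguity statistics
#'
#' Sorts the lengths in decreasing order and accumulates until the running sum
#' reaches `fraction` of the total. Nx is the length at which that happens (a
#' member of the input, not interpolated); Lx is the number of sequences
#' consumed.
#'
#' @param lengths Non-empty vector of positive lengths (bp).
#' @param fraction Fraction in (0, 1), e.g. 0.5 for N50/L50.
#' @return A list with elements `n` (bp) and `l` (count).
#' @examples
#' nx_lx(c(10, 8, 5, 3, 2), 0.5) # N50 = 8, L50 = 2
#' @export
nx_lx <- function(lengths, fraction) {
  if (length(lengths) == 0L) {
    stop("Nx/Lx is undefined for an empty length set", call. = FALSE)
  }
  if (any(lengths <= 0)) {
    stop("all lengths must be positive", call. = FALSE)
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  o <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(o)
  target <- fraction * sum(o)
  i <- which(cs >= target - 1e-9)[1L]
  list(n = o[i], l = i)
}

#' L90pcG: SCSs needed to harbor 90\% of the genes
#'
#' The number of scaffold-or-contig sequences, taken in decreasing order of
#' gene content, needed so that their cumulative gene count reaches at least
#' `ceiling(fraction * total)` genes. A gene-centric complement to L90: it
#' measures how concentrated the annotated protein-coding gene repertoire is
#' on the assembly.
#'
#' @param genes_per_scs Vector of per-SCS gene counts (>= 0, total > 0).
#' @param fraction Fraction of genes to cover (default 0.9).
#' @return The number of SCSs (integer).
#' @examples
#' l90pcg(c(5, 3, 2)) # 3
#' @export
l90pcg <- function(genes_per_scs, fraction = 0.9) {
  if (length(genes_per_scs) == 0L || sum(genes_per_scs) <= 0) {
    stop("L90pcG is undefined when no genes are annotated", call. = FALSE)
  }
  if (any(genes_per_scs < 0)) {
    stop("gene counts must be non-negative", call. = FALSE)
  }
  o <- sort(genes_per_scs, decreasing = TRUE)
  target <- ceiling(fraction * sum(o) - 1e-9)
  which(cumsum(o) >= target)[1L]
}

#' Feature density (number-wise containment)
#'
#' Count of contained features divided by the container length, reported per
#' bp — e.g. the intron density of a gene is its intron count divided by the
#' gene length.
#'
#' @param count Number of contained features (>= 0).
#' @param container_length Container length in bp (> 0).
#' @return Density per bp.
#' @export
feature_density <- function(count, container_length) {
  if (container_length <= 0) {
    stop("density is undefined for a zero-length container", call. = FALSE)
  }
  count / container_length
}

#' Feature coverage (length-wise containment)
#'
#' Summed length of contained features divided by the container length. For a
#' representative transcript, exon coverage and intron coverage sum to 1.
#'
#' @param covered_length Summed length of the contained features (bp).
#' @param container_length Container length in bp (> 0).
#' @return Ratio in \[0, 1\].
#' @export
feature_coverage <- function(covered_length, container_length) {
  if (container_length <= 0) {
    stop("coverage is undefined for a zero-length container", call. = FALSE)
  }
  if (covered_length > container_length) {
    stop(sprintf(
      "covered length (%s bp) exceeds container length (%s bp): corrupt coordinates?",
      format(covered_length), format(container_length)), call. = FALSE)
  }
  covered_length / container_length
}

#' Strand tallies
#'
#' Partitions strand labels into plus, minus and unknown counts.
#'
#' @param strands Character vector of strand labels; `"+"` and `"-"` are
#'   counted as such, anything else (including `"."` and `NA`) as unknown.
#' @return Named integer vector `c(plus =, minus =, unknown =)`.
#' @export
strandedness <- function(strands) {
  strands <- as.character(strands)
  plus <- sum(strands == "+", na.rm = TRUE)
  minus <- sum(strands == "-", na.rm = TRUE)
  c(plus = plus, minus = minus,
    unknown = length(strands) - plus - minus)
}

#' Length histogram with half-open bins
#'
#' Bins are `[e_i, e_{i+1})` with a final overflow bin `[e_k, Inf)`; a value
#' equal to an edge falls in the bin that edge opens. Default edges are decade
#' boundaries, suited to intron length distributions.
#'
#' @param lengths Positive lengths (bp); each must be >= the first edge.
#' @param bin_edges Strictly increasing bin edges (bp).
#' @return A data.frame with `bin_start`, `bin_end` (Inf for the overflow
#'   bin) and `count`; counts sum to `length(lengths)`.
#' @export
length_histogram <- function(lengths,
                             bin_edges = c(1, 10, 100, 1000, 10000, 100000)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (length(lengths) > 0L && any(lengths < bin_edges[1L])) {
    stop("length below the first bin edge", call. = FALSE)
  }
  idx <- findInterval(lengths, bin_edges)
  data.frame(
    bin_start = bin_edges,
    bin_end = c(bin_edges[-1L], Inf),
    count = tabulate(idx, nbins = length(bin_edges))
  )
}
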