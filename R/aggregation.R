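# Roll-ups of metric values along the structural hierarchy
# (feature -> transcript -> SCS -> assembly). Both means and medians are
# produced everywhere: many gene-structure features are strongly skewed, so
# the mean alone is a misleading summary. Aggregates over empty sets are NA,
# never 0 — absent and zero must stay distinguishable.

#' Count/total/min/max/mean/median bundle
#'
#' The summary bundle used at every aggregation level. `NA` elements are
#' dropped first; an empty (or all-`NA`) input yields count 0 and `NA` for
#' every other field. Medians of even-sized inputs are interpolated (mean of
#' the two middle values) — note this is a different convention from
#' representative-transcript selection, which must return an actual
#' transcript.
#'
#' @param values Numeric vector (may be empty or contain `NA`).
#' @return A list with `count`, `total`, `min`, `max`, `mean`, `median`.
#' @export
summary_stats <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) {
    return(list(count = 0L, total = NA_real_, min = NA_real_, max = NA_real_,
                mean = NA_real_, median = NA_real_))
  }
  list(count = length(v), total = sum(v), min = min(v), max = max(v),
       mean = mean(v), median = stats::median(v))
}

# mean/median that return NA (not NaN / error) on empty or all-NA input
mean_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}
median_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}

#' Per-transcript metric row for a representative transcript
#'
#' Computes the full per-transcript metric set for one gene's representative
#' transcript: feature counts, length statistics, added lengths, intron
#' density (intron count per bp of gene), exon/intron/CDS coverages of the
#' genomic span, strict and naive GC and CpG o/e of the spliced transcript
#' and of its concatenated introns, and the protein length. CDS columns are
#' `NA` when the transcript has no annotated CDS.
#'
#' @param transcript A transcript model with introns inferred (see
#'   [infer_introns()]).
#' @param scaffolds A named [Biostrings::DNAStringSet].
#' @param n_transcripts Number of annotated transcripts of the parent gene.
#' @param protein Optional pre-computed protein sequence (character); when
#'   `NULL` and the transcript has a CDS, the translation is performed here.
#' @return A one-row data.frame.
#' @export
per_transcript_rollup <- function(transcript, scaffolds, n_transcripts = 1L,
                                  protein = NULL) {
  ex_len <- transcript$exons$end - transcript$exons$start + 1L
  in_len <- if (nrow(transcript$introns) > 0L) {
    transcript$introns$end - transcript$introns$start + 1L
  } else numeric(0)
  cds_len <- if (!is.null(transcript$cds)) {
    transcript$cds$end - transcript$cds$start + 1L
  } else numeric(0)
  has_cds <- length(cds_len) > 0L
  span <- genomic_span(transcript)
  gene_length <- span[["end"]] - span[["start"]] + 1L

  # concatenation in transcript orientation: ascending-coordinate splice,
  # then one reverse complement for minus-strand transcripts
  minus <- identical(transcript$strand, "-")
  concat <- function(df) {
    set <- Biostrings::DNAStringSet(
      scaffolds[rep(transcript$seqid, nrow(df))],
      start = df$start, end = df$end)
    s <- paste(as.character(set), collapse = "")
    if (minus) reverse_complement(s) else s
  }
  spliced <- concat(transcript$exons)
  intron_seq <- if (length(in_len) > 0L) concat(transcript$introns) else ""

  gc_mrna <- gc_content(spliced)
  gc_intron <- if (nzchar(intron_seq)) gc_content(intron_seq) else NULL
  protein_length <- if (!has_cds) {
    NA_integer_
  } else if (!is.null(protein)) {
    nchar(protein)
  } else {
    nchar(suppressWarnings(translate_cds(transcript, scaffolds)))
  }

  data.frame(
    gene_id = transcript$gene_id,
    transcript_id = transcript$id,
    seqid = transcript$seqid,
    strand = transcript$strand,
    n_transcripts = n_transcripts,
    exon_count = length(ex_len),
    cds_count = if (has_cds) length(cds_len) else NA_integer_,
    intron_count = length(in_len),
    exon_length_added = sum(ex_len),
    exon_length_mean = mean_na(ex_len),
    exon_length_median = median_na(ex_len),
    intron_length_added = if (length(in_len) > 0L) sum(in_len) else 0,
    intron_length_mean = mean_na(in_len),
    intron_length_median = median_na(in_len),
    cds_length_added = if (has_cds) sum(cds_len) else NA_real_,
    cds_length_mean = mean_na(cds_len),
    cds_length_median = median_na(cds_len),
    transcript_length = sum(ex_len),
    gene_length = gene_length,
    intron_density = feature_density(length(in_len), gene_length),
    intron_density_per_kb = 1000 * feature_density(length(in_len), gene_length),
    exon_coverage = feature_coverage(sum(ex_len), gene_length),
    intron_coverage = feature_coverage(
      if (length(in_len) > 0L) sum(in_len) else 0, gene_length),
    cds_coverage = if (has_cds) {
      feature_coverage(sum(cds_len), gene_length)
    } else NA_real_,
    gc_strict_mrna = gc_mrna$gc_strict,
    gc_naive_mrna = gc_mrna$gc_naive,
    cpg_oe_mrna = cpg_oe(spliced),
    gc_strict_introns = if (is.null(gc_intron)) NA_real_ else gc_intron$gc_strict,
    gc_naive_introns = if (is.null(gc_intron)) NA_real_ else gc_intron$gc_naive,
    cpg_oe_introns = if (nzchar(intron_seq)) cpg_oe(intron_seq) else NA_real_,
    protein_length = protein_length,
    stringsAsFactors = FALSE
  )
}

# assembly-level overview: the standardized minimum parameter set plus
# contiguity, strandedness and the grand mean/median-of-medians statistics.
# transcripts: per-transcript table; scs: per-SCS table; exons/introns/cds:
# per-feature tables (representative transcripts only).
build_overview <- function(scs, transcripts, exons, cds, introns,
                           skipped_gene_count, assembly_counts) {
  n_genes <- nrow(transcripts)
  have_genes <- n_genes > 0L
  strand_tab <- strandedness(if (have_genes) transcripts$strand else character(0))

  total_len <- sum(scs$length)
  n_count <- assembly_counts[["N"]]
  amb_count <- sum(assembly_counts[GC_AMBIGUOUS])
  strict_den <- total_len - amb_count
  gc_num_strict <- assembly_counts[["G"]] + assembly_counts[["C"]] +
    assembly_counts[["S"]]

  nx <- lapply(c(0.5, 0.75, 0.9), function(f) nx_lx(scs$length, f))

  ov <- list(
    scs_count = nrow(scs),
    assembly_size_with_n = total_len,
    assembly_size_without_n = total_len - n_count,
    assembly_n_count = n_count,
    assembly_ambiguity_count = amb_count,
    assembly_gc_strict = if (strict_den > 0) 100 * gc_num_strict / strict_den else NA_real_,
    assembly_gc_naive = 100 * (assembly_counts[["G"]] + assembly_counts[["C"]]) / total_len,
    n50 = nx[[1L]]$n, l50 = nx[[1L]]$l,
    n75 = nx[[2L]]$n, l75 = nx[[2L]]$l,
    n90 = nx[[3L]]$n, l90 = nx[[3L]]$l,
    l90pcg = if (have_genes) l90pcg(scs$gene_count) else NA_real_,
    gene_count = n_genes,
    gene_skipped_count = skipped_gene_count,
    transcript_count = n_genes,
    transcripts_plus = strand_tab[["plus"]],
    transcripts_minus = strand_tab[["minus"]],
    transcripts_unknown = strand_tab[["unknown"]],
    exon_count = if (have_genes) sum(transcripts$exon_count) else NA_real_,
    cds_count = if (have_genes) sum(transcripts$cds_count, na.rm = TRUE) else NA_real_,
    intron_count = if (have_genes) sum(transcripts$intron_count) else NA_real_,
    exon_amount = if (have_genes) sum(transcripts$exon_length_added) else NA_real_,
    coding_amount = if (have_genes && any(!is.na(transcripts$cds_length_added)))
      sum(transcripts$cds_length_added, na.rm = TRUE) else NA_real_,
    intron_amount = if (have_genes) sum(transcripts$intron_length_added) else NA_real_,
    transcript_length_mean = mean_na(transcripts$transcript_length),
    transcript_length_median = median_na(transcripts$transcript_length),
    gene_length_mean = mean_na(transcripts$gene_length),
    gene_length_median = median_na(transcripts$gene_length),
    exon_length_mean = mean_na(exons$length),
    exon_length_median = median_na(exons$length),
    intron_length_mean = mean_na(introns$length),
    intron_length_median = median_na(introns$length),
    cds_length_mean = mean_na(cds$length),
    cds_length_median = median_na(cds$length),
    cds_count_per_transcript_mean = mean_na(transcripts$cds_count),
    cds_count_per_transcript_median = median_na(transcripts$cds_count),
    intron_count_per_transcript_mean = mean_na(transcripts$intron_count),
    intron_count_per_transcript_median = median_na(transcripts$intron_count),
    cds_coverage_mean = mean_na(transcripts$cds_coverage),
    cds_coverage_median = median_na(transcripts$cds_coverage),
    exon_coverage_mean = mean_na(transcripts$exon_coverage),
    exon_coverage_median = median_na(transcripts$exon_coverage),
    intron_coverage_mean = mean_na(transcripts$intron_coverage),
    intron_coverage_median = median_na(transcripts$intron_coverage),
    intron_density_mean = mean_na(transcripts$intron_density),
    intron_density_median = median_na(transcripts$intron_density),
    per_transcript_mean_exon_length_mean = mean_na(transcripts$exon_length_mean),
    per_transcript_median_exon_length_mean = mean_na(transcripts$exon_length_median),
    per_transcript_median_exon_length_median = median_na(transcripts$exon_length_median),
    per_transcript_mean_intron_length_mean = mean_na(transcripts$intron_length_mean),
    per_transcript_median_intron_length_mean = mean_na(transcripts$intron_length_median),
    per_transcript_median_intron_length_median = median_na(transcripts$intron_length_median),
    protein_length_mean = mean_na(transcripts$protein_length),
    protein_length_median = median_na(transcripts$protein_length)
  )
  if (!have_genes) {
    na_keys <- c("exon_count", "cds_count", "intron_count", "exon_amount",
                 "intron_amount")
    ov[na_keys] <- NA_real_
  }
  ov
}
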