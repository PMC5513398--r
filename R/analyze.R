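# End-to-end single-genome analysis: parse -> link -> infer introns ->
# select representatives -> metric kernels -> aggregation. The result object
# carries all per-feature level tables, the assembly overview and the
# translated proteins; report writing lives in reports.R.

#' Analyze a genome assembly and its gene annotation
#'
#' Runs the full analysis pipeline on a FASTA assembly and a GFF3
#' protein-coding gene annotation. Exactly one representative transcript per
#' gene is analyzed (the longest spliced transcript by default); introns are
#' inferred from exon coordinates. Produces per-SCS, per-transcript, per-CDS,
#' per-exon and per-intron tables plus an assembly-level overview containing
#' the standardized minimum parameter set (assembly size with and without Ns,
#' strict/naive GC, gene count, length medians, densities, coverages, coding
#' and intron amounts, Nx/Lx, L90pcG, strandedness).
#'
#' @param fasta Path to a FASTA file, or a named [Biostrings::DNAStringSet].
#' @param gff3 Path to a GFF3 file, or a `gene_set` from [parse_gff3()].
#' @param transcript_choice Representative-transcript selection mode:
#'   `"longest"` (default), `"shortest"` or `"median"` spliced length.
#' @return An object of class `genome_analysis`: a list with `scaffolds`,
#'   `genes`, `tables` (`scs`, `transcript`, `cds`, `exon`, `intron`),
#'   `overview` (named list), `proteins` ([Biostrings::AAStringSet]),
#'   `transcript_choice` and `log` (skipped/warning tallies).
#' @examples
#' g <- worked_micro_genome(tempfile("micro"))
#' an <- analyze_genome(g$fasta, g$gff3)
#' an$overview$gene_count
#' @export
analyze_genome <- function(fasta, gff3,
                           transcript_choice = c("longest", "shortest",
                                                 "median")) {
  transcript_choice <- match.arg(transcript_choice)
  scaffolds <- if (is.character(fasta)) parse_fasta(fasta) else fasta
  gs <- if (is.character(gff3)) parse_gff3(gff3) else gff3

  gene_seqids <- unique(vapply(gs$genes, function(g) g$seqid, character(1)))
  missing_scs <- setdiff(gene_seqids, names(scaffolds))
  if (length(missing_scs) > 0L) {
    stop("annotation references sequence(s) absent from the assembly: ",
         paste(missing_scs, collapse = ", "), call. = FALSE)
  }

  zero_gap_junctions <- 0L
  genes <- gs$genes[order(names(gs$genes))]
  tr_rows <- vector("list", length(genes))
  proteins <- character(0)
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    g$transcripts <- lapply(g$transcripts, function(tr) {
      withCallingHandlers(
        infer_introns(tr),
        warning = function(w) {
          if (grepl("zero-gap", conditionMessage(w))) {
            zero_gap_junctions <<- zero_gap_junctions + 1L
            invokeRestart("muffleWarning")
          }
        })
    })
    rep_tr <- select_representative(g, transcript_choice)
    g$representative <- rep_tr$id
    span <- genomic_span(rep_tr)
    g$gene_length <- span[["end"]] - span[["start"]] + 1L
    genes[[k]] <- g
    aa <- if (!is.null(rep_tr$cds) && nrow(rep_tr$cds) > 0L) {
      suppressWarnings(translate_cds(rep_tr, scaffolds))
    } else NULL
    tr_rows[[k]] <- per_transcript_rollup(rep_tr, scaffolds,
                                          n_transcripts = length(g$transcripts),
                                          protein = aa)
    if (!is.null(aa)) {
      proteins[paste0(g$id, " transcript=", rep_tr$id)] <- aa
    }
  }
  transcripts <- if (length(tr_rows) > 0L) {
    do.call(rbind, tr_rows)
  } else {
    per_transcript_skeleton()
  }

  feature_tabs <- build_feature_tables(genes, transcripts, scaffolds)
  scs <- build_scs_table(scaffolds, transcripts)
  assembly_counts <- stats::setNames(as.numeric(colSums(
    Biostrings::letterFrequency(scaffolds, IUPAC_LETTERS, OR = 0))),
    IUPAC_LETTERS)

  out <- list(
    scaffolds = scaffolds,
    genes = genes,
    tables = c(list(scs = scs, transcript = transcripts), feature_tabs),
    overview = build_overview(scs, transcripts, feature_tabs$exon,
                              feature_tabs$cds, feature_tabs$intron,
                              gs$skipped_gene_count, assembly_counts),
    proteins = Biostrings::AAStringSet(proteins),
    transcript_choice = transcript_choice,
    log = list(skipped_gene_count = gs$skipped_gene_count,
               skipped_gene_ids = gs$skipped_gene_ids,
               zero_gap_junctions = zero_gap_junctions)
  )
  class(out) <- "genome_analysis"
  out
}

# 0-row transcript table with the full column set (degenerate annotation)
per_transcript_skeleton <- function() {
  cols <- c("gene_id", "transcript_id", "seqid", "strand")
  num <- c("n_transcripts", "exon_count", "cds_count", "intron_count",
           "exon_length_added", "exon_length_mean", "exon_length_median",
           "intron_length_added", "intron_length_mean", "intron_length_median",
           "cds_length_added", "cds_length_mean", "cds_length_median",
           "transcript_length", "gene_length", "intron_density",
           "intron_density_per_kb", "exon_coverage", "intron_coverage",
           "cds_coverage", "gc_strict_mrna", "gc_naive_mrna", "cpg_oe_mrna",
           "gc_strict_introns", "gc_naive_introns", "cpg_oe_introns",
           "protein_length")
  df <- c(stats::setNames(rep(list(character(0)), length(cols)), cols),
          stats::setNames(rep(list(numeric(0)), length(num)), num))
  as.data.frame(df, stringsAsFactors = FALSE)
}

# per-CDS / per-exon / per-intron tables over representative transcripts,
# each row one feature with composition metrics, ordered by feature id.
# Composition is computed in one vectorized pass per feature kind; GC and
# CpG o/e are invariant under reverse complement, so plus-strand extraction
# is sufficient for these columns.
build_feature_tables <- function(genes, transcripts, scaffolds) {
  coord_rows <- list(cds = list(), exon = list(), intron = list())
  for (g in genes) {
    tr <- g$transcripts[[g$representative]]
    mk <- function(df, kind) {
      if (is.null(df) || nrow(df) == 0L) return(NULL)
      data.frame(
        feature_id = paste0(tr$id, ".", kind, seq_len(nrow(df))),
        transcript_id = tr$id, gene_id = g$id, seqid = tr$seqid,
        strand = tr$strand, start = df$start, end = df$end,
        length = df$end - df$start + 1L,
        phase = if (kind == "cds") df$phase else NA_integer_,
        stringsAsFactors = FALSE)
    }
    coord_rows$exon[[tr$id]] <- mk(tr$exons, "exon")
    coord_rows$cds[[tr$id]] <- mk(tr$cds, "cds")
    coord_rows$intron[[tr$id]] <- mk(tr$introns, "intron")
  }
  empty <- data.frame(feature_id = character(0), transcript_id = character(0),
                      gene_id = character(0), seqid = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      phase = integer(0), gc_strict = numeric(0),
                      gc_naive = numeric(0), cpg_oe = numeric(0),
                      stringsAsFactors = FALSE)
  lapply(coord_rows, function(rows) {
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    seqs <- Biostrings::DNAStringSet(scaffolds[out$seqid],
                                     start = out$start, end = out$end)
    lf <- Biostrings::letterFrequency(seqs, IUPAC_LETTERS, OR = 0)
    strict_den <- out$length - rowSums(lf[, GC_AMBIGUOUS, drop = FALSE])
    strict_num <- lf[, "G"] + lf[, "C"] + lf[, "S"]
    out$gc_strict <- ifelse(strict_den > 0, 100 * strict_num / strict_den,
                            NA_real_)
    out$gc_naive <- 100 * (lf[, "G"] + lf[, "C"]) / out$length
    obs <- Biostrings::vcountPattern("CG", seqs, fixed = TRUE)
    out$cpg_oe <- ifelse(lf[, "C"] > 0 & lf[, "G"] > 0,
                         as.numeric(obs) * out$length /
                           (as.numeric(lf[, "C"]) * lf[, "G"]),
                         NA_real_)
    out[order(out$feature_id), , drop = FALSE]
  })[c("cds", "exon", "intron")]
}

# per-SCS table: length, composition, and gene content of each scaffold
build_scs_table <- function(scaffolds, transcripts) {
  ids <- names(scaffolds)
  rows <- lapply(ids, function(id) {
    seq <- as.character(scaffolds[[id]])
    cnt <- letter_counts(seq)
    gc <- gc_content(seq)
    on_scs <- transcripts[!is.na(match(transcripts$seqid, id)), , drop = FALSE]
    n_genes <- nrow(on_scs)
    len <- nchar(seq)
    data.frame(
      scs_id = id, length = len,
      n_count = cnt[["N"]],
      ambiguity_count = sum(cnt[GC_AMBIGUOUS]),
      length_without_n = len - cnt[["N"]],
      gc_strict = gc$gc_strict, gc_naive = gc$gc_naive,
      cpg_oe = cpg_oe(seq),
      gene_count = n_genes,
      gene_density = feature_density(n_genes, len),
      gene_density_per_mb = 1e6 * feature_density(n_genes, len),
      gene_coverage = feature_coverage(
        if (n_genes > 0L) sum(on_scs$gene_length) else 0, len),
      exon_count = if (n_genes > 0L) sum(on_scs$exon_count) else 0L,
      intron_count = if (n_genes > 0L) sum(on_scs$intron_count) else 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$scs_id), , drop = FALSE]
}

#' @export
print.genome_analysis <- function(x, ...) {
  ov <- x$overview
  cat("<genome_analysis>\n")
  cat(sprintf("  assembly: %d SCSs, %s bp (%s bp without Ns), GC %.2f%% (strict) / %.2f%% (naive)\n",
              ov$scs_count, format(ov$assembly_size_with_n, big.mark = ","),
              format(ov$assembly_size_without_n, big.mark = ","),
              ov$assembly_gc_strict, ov$assembly_gc_naive))
  cat(sprintf("  contiguity: N50 %s (L50 %d), N90 %s (L90 %d), L90pcG %s\n",
              format(ov$n50, big.mark = ","), ov$l50,
              format(ov$n90, big.mark = ","), ov$l90,
              format(ov$l90pcg)))
  cat(sprintf("  genes: %d analyzed (%d without mRNA skipped), representative = %s transcript\n",
              ov$gene_count, ov$gene_skipped_count, x$transcript_choice))
  if (ov$gene_count > 0) {
    cat(sprintf("  features: %d exons, %d introns, %d CDS segments; coding amount %s bp\n",
                ov$exon_count, ov$intron_count, ov$cds_count,
                format(ov$coding_amount, big.mark = ",")))
  }
  invisible(x)
}
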