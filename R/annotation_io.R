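# GFF3 parsing: gene -> mRNA -> exon/CDS hierarchy, intron inference, and
# representative-transcript selection.
#
# A transcript model is a plain list:
#   id, gene_id, seqid, strand,
#   exons:   data.frame(start, end)        sorted by start, non-overlapping
#   cds:     data.frame(start, end, phase) or NULL when un-annotated
#   introns: data.frame(start, end)        derived, see infer_introns()
# A gene model is a list: id, seqid, strand, transcripts (named list),
# representative (transcript id, once selected), gene_length.

#' Parse a GFF3 protein-coding gene annotation
#'
#' Builds the gene/mRNA/exon(/CDS) hierarchy from a GFF3 file. Only genes
#' possessing at least one `mRNA` child are analyzed; genes without mRNA
#' (non-coding genes) are counted and reported as skipped. Exon and CDS rows
#' are attached to their mRNA via the `Parent` attribute and sorted by
#' coordinate. Transcripts whose exons span multiple SCSs or strands are
#' rejected, as are duplicated (discontinuous) `gene` IDs.
#'
#' @param path Path to a GFF3 file (9 tab-separated columns; `##` directives
#'   allowed; `ID`/`Parent` attributes link the hierarchy).
#' @return An object of class `gene_set`: a list with elements `genes` (named
#'   list of gene models), `skipped_gene_count` and `skipped_gene_ids`.
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated columns, found %d",
                 lineno, path, nfield[which(nfield != 9L)[1L]]), call. = FALSE)
  }
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "type", "start", "end",
                                          "strand", "phase"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  gff$seqid <- as.character(gff$seqid)
  gff$type <- as.character(gff$type)
  gff$strand <- as.character(gff$strand)
  gff$strand[is.na(gff$strand) | !gff$strand %in% c("+", "-")] <- "unknown"

  is_gene <- gff$type == "gene"
  gene_ids <- gff$ID[is_gene]
  if (anyNA(gene_ids)) {
    stop("gene feature without an ID attribute in '", path, "'",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ID(s) (discontinuous genes are not supported): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  gene_rows <- gff[is_gene, , drop = FALSE]
  rownames(gene_rows) <- gene_rows$ID

  is_mrna <- gff$type == "mRNA"
  mrna_rows <- gff[is_mrna, , drop = FALSE]
  if (nrow(mrna_rows) > 0L && anyNA(mrna_rows$ID)) {
    stop("mRNA feature without an ID attribute in '", path, "'",
         call. = FALSE)
  }
  mrna_parent <- vapply(mrna_rows$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  orphan <- which(is.na(mrna_parent) | !mrna_parent %in% gene_ids)
  if (length(orphan) > 0L) {
    stop("mRNA '", mrna_rows$ID[orphan[1L]],
         "' references a gene that is absent from the file", call. = FALSE)
  }

  # exon / CDS children, replicated per parent mRNA (exons may be shared)
  child <- gff[gff$type %in% c("exon", "CDS"), , drop = FALSE]
  child_parents <- child$Parent
  rep_idx <- rep(seq_len(nrow(child)), lengths(child_parents))
  child <- child[rep_idx, , drop = FALSE]
  child$parent_id <- as.character(unlist(child_parents, use.names = FALSE))
  child <- child[child$parent_id %in% mrna_rows$ID, , drop = FALSE]

  mrna_seqid <- stats::setNames(mrna_rows$seqid, mrna_rows$ID)
  mrna_strand <- stats::setNames(mrna_rows$strand, mrna_rows$ID)
  bad_seq <- child$seqid != mrna_seqid[child$parent_id]
  if (any(bad_seq)) {
    i <- which(bad_seq)[1L]
    stop(sprintf("%s of transcript '%s' lies on '%s' but its mRNA is on '%s'",
                 child$type[i], child$parent_id[i], child$seqid[i],
                 mrna_seqid[child$parent_id[i]]), call. = FALSE)
  }
  bad_str <- child$strand != mrna_strand[child$parent_id]
  if (any(bad_str)) {
    i <- which(bad_str)[1L]
    stop("strand of ", child$type[i], " features disagrees with mRNA '",
         child$parent_id[i], "' (trans-spliced models are not supported)",
         call. = FALSE)
  }

  child_split <- split(child, child$parent_id)
  genes <- vector("list", length(gene_ids))
  names(genes) <- gene_ids
  for (k in seq_len(nrow(mrna_rows))) {
    tid <- mrna_rows$ID[k]
    gid <- mrna_parent[k]
    kids <- child_split[[tid]]
    if (is.null(kids) || !any(kids$type == "exon")) {
      stop("mRNA '", tid, "' has no exon features", call. = FALSE)
    }
    ex <- kids[kids$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    exons <- data.frame(start = ex$start, end = ex$end)
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    cds <- NULL
    if (nrow(cd) > 0L) {
      cd <- cd[order(cd$start), , drop = FALSE]
      cds <- data.frame(start = cd$start, end = cd$end,
                        phase = ifelse(is.na(cd$phase), 0L,
                                       as.integer(cd$phase)))
    }
    tr <- list(id = tid, gene_id = gid, seqid = mrna_rows$seqid[k],
               strand = mrna_rows$strand[k], exons = exons, cds = cds,
               introns = NULL)
    if (is.null(genes[[gid]])) {
      genes[[gid]] <- list(id = gid, seqid = gene_rows[gid, "seqid"],
                           strand = gene_rows[gid, "strand"],
                           transcripts = list(), representative = NULL,
                           gene_length = NA_integer_)
    }
    genes[[gid]]$transcripts[[tid]] <- tr
  }

  analyzed <- !vapply(genes, is.null, logical(1))
  out <- list(genes = genes[analyzed],
              skipped_gene_count = sum(!analyzed),
              skipped_gene_ids = gene_ids[!analyzed])
  class(out) <- "gene_set"
  out
}

#' @export
print.gene_set <- function(x, ...) {
  n_tr <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat("<gene_set>", length(x$genes), "protein-coding genes,", n_tr,
      "transcripts;", x$skipped_gene_count, "gene(s) without mRNA skipped\n")
  invisible(x)
}

#' Infer introns from exon coordinates
#'
#' For each pair of adjacent exons with a gap of at least 1 bp, emits the
#' intron `[end_i + 1, start_{i+1} - 1]` on the transcript's strand. Adjacent
#' exons with a zero gap produce no intron (with a warning). Overlapping exons
#' within one transcript are a consistency error.
#'
#' @param transcript A transcript model.
#' @param warn Emit a warning for zero-gap adjacent exons (default `TRUE`).
#' @return The transcript with its `introns` data.frame filled in.
#' @export
infer_introns <- function(transcript, warn = TRUE) {
  ex <- transcript$exons[order(transcript$exons$start), , drop = FALSE]
  n <- nrow(ex)
  if (n > 1L && any(ex$start[-1L] <= ex$end[-n])) {
    stop("overlapping exons in transcript '", transcript$id, "'",
         call. = FALSE)
  }
  if (n <= 1L) {
    transcript$introns <- data.frame(start = integer(0), end = integer(0))
    return(transcript)
  }
  gap_start <- ex$end[-n] + 1L
  gap_end <- ex$start[-1L] - 1L
  keep <- gap_end >= gap_start
  if (warn && any(!keep)) {
    warning("zero-gap adjacent exons in transcript '", transcript$id,
            "'; no intron emitted for ", sum(!keep), " junction(s)",
            call. = FALSE)
  }
  transcript$introns <- data.frame(start = gap_start[keep],
                                   end = gap_end[keep])
  transcript
}

# spliced mRNA length: summed exon length
spliced_length <- function(transcript) {
  sum(transcript$exons$end - transcript$exons$start + 1L)
}

# genomic span of a transcript (first exon start .. last exon end)
genomic_span <- function(transcript) {
  c(start = min(transcript$exons$start), end = max(transcript$exons$end))
}

#' Select the representative transcript of a gene
#'
#' One transcript per gene is analyzed. The length criterion is the spliced
#' mRNA length (summed exon length). `longest` (the default elsewhere) picks
#' the maximum, `shortest` the minimum, and `median` the transcript whose
#' length is the lower-middle element of the sorted lengths for even counts.
#' Ties are broken deterministically by the lexicographically smallest
#' transcript ID.
#'
#' @param gene A gene model with at least one transcript.
#' @param mode One of `"longest"`, `"shortest"`, `"median"`.
#' @return The selected transcript model.
#' @export
select_representative <- function(gene,
                                  mode = c("longest", "shortest", "median")) {
  mode <- match.arg(mode)
  trs <- gene$transcripts
  if (length(trs) == 0L) {
    stop("gene '", gene$id, "' has no transcripts", call. = FALSE)
  }
  lens <- vapply(trs, spliced_length, numeric(1))
  ids <- names(trs)
  ord <- order(lens, ids)  # ascending length, then lexicographic id
  pick <- switch(mode,
    shortest = ord[1L],
    longest = {
      mx <- max(lens)
      cand <- ids[lens == mx]
      which(ids == min(cand))
    },
    median = ord[(length(ord) - 1L) %/% 2L + 1L])
  trs[[pick]]
}
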