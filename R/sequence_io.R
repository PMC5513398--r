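# FASTA parsing, coordinate-based subsequence extraction and CDS translation.
# All coordinates are 1-based inclusive (GFF3 native); lengths are end - start + 1.

# IUPAC nucleotide alphabet accepted on input (U is mapped to T).
IUPAC_LETTERS <- c("A", "C", "G", "T", "N", "R", "Y", "K", "M", "S", "W",
                   "B", "D", "H", "V")

# Codes excluded from the strict GC denominator: ambiguous with respect to
# G/C status. S (G or C) and W (A or T) are unambiguous for GC and stay in.
GC_AMBIGUOUS <- c("N", "R", "Y", "K", "M", "B", "D", "H", "V")

#' Read a genome assembly FASTA
#'
#' Reads a (possibly line-wrapped) nucleotide FASTA of scaffold-or-contig
#' sequences (SCSs). Sequences are uppercased, `U` is mapped to `T`, and every
#' character must belong to the IUPAC nucleotide alphabet. Record identifiers
#' are the header tokens up to the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per SCS.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT", ">s2", "NNNN"), fa)
#' scaffolds <- parse_fasta(fa)
#' Biostrings::width(scaffolds)
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA record identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- which(Biostrings::width(raw) == 0L)
  if (length(empty) > 0L) {
    stop("empty sequence under FASTA header: ", ids[empty[1L]], call. = FALSE)
  }
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  bad_re <- sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = ""))
  bad <- regexpr(bad_re, seqs)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop(sprintf(
      "invalid character '%s' at position %d of record '%s' (not IUPAC)",
      substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity-aware: R<->Y, K<->M, B<->V, D<->H; S, W and N map to themselves.
#'
#' @param seq A nucleotide character string.
#' @return The reverse complement as a character string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a feature subsequence from a scaffold
#'
#' Returns the subsequence of `scaffolds[[seqid]]` between `start` and `end`
#' (1-based inclusive). For `strand = "-"` the reverse complement is returned,
#' so the result always reads 5' to 3' on the feature's own strand.
#'
#' @param scaffolds A named [Biostrings::DNAStringSet] as returned by
#'   [parse_fasta()].
#' @param seqid SCS identifier.
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @param strand `"+"`, `"-"`, or anything else (treated as `"+"` with the
#'   orientation unknown).
#' @return A character string of length `end - start + 1`.
#' @export
extract_sequence <- function(scaffolds, seqid, start, end, strand = "+") {
  if (!seqid %in% names(scaffolds)) {
    stop("sequence '", seqid, "' not present in the assembly", call. = FALSE)
  }
  s <- scaffolds[[seqid]]
  if (start < 1L || end < start) {
    stop(sprintf("invalid interval %d..%d on '%s'", start, end, seqid),
         call. = FALSE)
  }
  if (end > length(s)) {
    stop(sprintf("interval %d..%d exceeds length %d of '%s'",
                 start, end, length(s), seqid), call. = FALSE)
  }
  x <- Biostrings::subseq(s, start, end)
  if (identical(strand, "-")) {
    x <- Biostrings::reverseComplement(x)
  }
  as.character(x)
}

#' Translate the CDS of a transcript
#'
#' Concatenates the CDS segments of a transcript in translation order
#' (ascending genomic coordinate on the plus strand, descending on the minus
#' strand, each segment strand-extracted), skips the first segment's phase,
#' and translates with the standard genetic code. A trailing incomplete codon
#' is dropped; one terminal stop, if present, is trimmed from the protein.
#' Internal stops are kept as `*` with a warning. Codons containing
#' unresolvable ambiguity translate to `X`.
#'
#' Only the first segment's phase is honored; downstream phases are checked
#' against the cumulative CDS length and a mismatch triggers a warning.
#'
#' @param transcript A transcript model (see [parse_gff3()]) with at least one
#'   CDS segment.
#' @param scaffolds A named [Biostrings::DNAStringSet].
#' @return The amino-acid sequence as a character string.
#' @export
translate_cds <- function(transcript, scaffolds) {
  cds <- transcript$cds
  if (is.null(cds) || nrow(cds) == 0L) {
    stop("transcript '", transcript$id, "' has no CDS segments",
         call. = FALSE)
  }
  minus <- identical(transcript$strand, "-")
  ord <- order(cds$start, decreasing = minus)
  cds <- cds[ord, , drop = FALSE]
  phases <- cds$phase
  if (is.null(phases)) phases <- rep(0L, nrow(cds))
  phases[is.na(phases)] <- 0L
  lens <- cds$end - cds$start + 1L
  # expected phase of segment i: bases to skip so that translation stays in
  # frame given the cumulative coding length upstream of it
  cum <- cumsum(c(0L, lens[-length(lens)])) - phases[1L]
  expected <- (3L - (cum %% 3L)) %% 3L
  if (nrow(cds) > 1L && any(phases[-1L] != expected[-1L])) {
    warning("inconsistent CDS phases in transcript '", transcript$id,
            "'; using the first segment's phase only", call. = FALSE)
  }
  parts <- vapply(seq_len(nrow(cds)), function(i) {
    extract_sequence(scaffolds, transcript$seqid, cds$start[i], cds$end[i],
                     transcript$strand)
  }, character(1))
  coding <- paste(parts, collapse = "")
  if (phases[1L] > 0L) {
    coding <- substr(coding, phases[1L] + 1L, nchar(coding))
  }
  n_codon <- nchar(coding) %/% 3L
  if (n_codon < 1L) {
    stop("CDS of transcript '", transcript$id,
         "' is shorter than one codon after phase trimming", call. = FALSE)
  }
  coding <- substr(coding, 1L, n_codon * 3L)
  aa <- translate_codons(coding)
  if (substr(aa, nchar(aa), nchar(aa)) == "*") {
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  }
  if (grepl("*", aa, fixed = TRUE)) {
    warning("internal stop codon(s) in transcript '", transcript$id, "'",
            call. = FALSE)
  }
  aa
}

# codon-wise translation under the standard genetic code; a codon with
# ambiguity codes is resolved by IUPAC expansion and becomes X unless every
# expansion encodes the same amino acid
translate_codons <- function(coding) {
  n <- nchar(coding) %/% 3L
  idx <- seq_len(n)
  codons <- substring(coding, 3L * idx - 2L, 3L * idx)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  for (i in which(is.na(aa))) {
    opts <- lapply(strsplit(codons[i], "")[[1L]], function(ch) {
      strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1L]]
    })
    combos <- apply(expand.grid(opts, stringsAsFactors = FALSE), 1L,
                    paste, collapse = "")
    u <- unique(unname(code[combos]))
    aa[i] <- if (length(u) == 1L) u else "X"
  }
  paste(aa, collapse = "")
}
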