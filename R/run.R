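# Single-genome and batch drivers. One genome is analyzed at a time; a batch
# manifest (3-column TSV: label, fasta, gff3) is processed serially in
# manifest order, sharing one set of batch files so per-genome lines are
# directly comparable. A thin command-line wrapper over these functions is
# installed under inst/cli/.

#' Run the full pipeline on one genome
#'
#' Parses the assembly and annotation, analyzes the genome (see
#' [analyze_genome()]) and writes the numbered report-file suite (see
#' [write_reports()]).
#'
#' @param fasta_path Path to the assembly FASTA.
#' @param gff3_path Path to the GFF3 annotation.
#' @param label Genome label; names the run directory and batch lines.
#' @param out_dir Output directory.
#' @param transcript_choice `"longest"` (default), `"shortest"` or
#'   `"median"`.
#' @param outputs `"all"` or a vector of report-file numbers (0-20).
#' @return Invisibly, a list with `analysis` (the `genome_analysis`) and
#'   `reports` (the `report_set`).
#' @export
run_single <- function(fasta_path, gff3_path, label, out_dir,
                       transcript_choice = "longest", outputs = "all") {
  for (p in c(fasta_path, gff3_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  analysis <- analyze_genome(fasta_path, gff3_path, transcript_choice)
  reports <- write_reports(analysis, out_dir, label, outputs = outputs,
                           fasta_path = fasta_path, gff3_path = gff3_path)
  invisible(list(analysis = analysis, reports = reports))
}

#' Run the pipeline on a batch of genomes
#'
#' The manifest is a header-less 3-column TSV with one genome per line:
#' label, FASTA path, GFF3 path. Genomes are processed serially in manifest
#' order. A failing genome is logged and skipped; the batch continues, and
#' the batch TSVs end up with one line per successfully analyzed genome.
#'
#' @param manifest Path to the batch manifest TSV.
#' @param out_dir Output directory shared by all runs.
#' @param transcript_choice,outputs Passed to [run_single()].
#' @return A data.frame with one row per manifest line: `label`, `status`
#'   (`"ok"`/`"failed"`) and `message`.
#' @export
run_batch <- function(manifest, out_dir, transcript_choice = "longest",
                      outputs = "all") {
  if (!file.exists(manifest)) {
    stop("batch manifest not found: ", manifest, call. = FALSE)
  }
  rows <- utils::read.table(manifest, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            col.names = c("label", "fasta", "gff3"),
                            colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(rows) == 0L) {
    stop("batch manifest is empty: ", manifest, call. = FALSE)
  }
  results <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    res <- tryCatch({
      run_single(r$fasta, r$gff3, r$label, out_dir,
                 transcript_choice = transcript_choice, outputs = outputs)
      list(status = "ok", message = "")
    }, error = function(e) {
      message("genome '", r$label, "' failed: ", conditionMessage(e))
      list(status = "failed", message = conditionMessage(e))
    })
    data.frame(label = r$label, status = res$status, message = res$message,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, results)
}
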