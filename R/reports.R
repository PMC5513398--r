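# Numbered report-file suite. A default run writes 21 files:
#   00  protein FASTA (analyzed representative transcripts)
#   01  overview TSV (parameter/value)
#   02/03  per-SCS data + summary          08/09  per-exon data + summary
#   04/05  per-transcript data + summary   10/11  per-intron data + summary
#   06/07  per-CDS data + summary          12  intron length distribution
#   13  component sizes                    20  ready-made bash commands
#   14-19  batch TSVs (one line per analyzed genome, shared across runs)
# All except 00 and 20 are TSV. Per-run files live in <out_dir>/<label>/,
# batch files in <out_dir> so several runs can be compared directly; a run
# manifest and log are written under <out_dir>/<label>/logs/.

REPORT_FILES <- c(
  "00" = "00_protein.fasta",
  "01" = "01_overview.tsv",
  "02" = "02_scs_data.tsv",
  "03" = "03_scs_summary.tsv",
  "04" = "04_transcript_data.tsv",
  "05" = "05_transcript_summary.tsv",
  "06" = "06_cds_data.tsv",
  "07" = "07_cds_summary.tsv",
  "08" = "08_exon_data.tsv",
  "09" = "09_exon_summary.tsv",
  "10" = "10_intron_data.tsv",
  "11" = "11_intron_summary.tsv",
  "12" = "12_intron_length_distribution.tsv",
  "13" = "13_component_sizes.tsv",
  "14" = "14_batch_general.tsv",
  "15" = "15_batch_scs_means.tsv",
  "16" = "16_batch_scs_medians.tsv",
  "17" = "17_batch_transcript_means.tsv",
  "18" = "18_batch_transcript_medians.tsv",
  "19" = "19_batch_component_sizes.tsv",
  "20" = "20_bash_commands.txt"
)

# fixed numeric formatting: integers unpadded; percentages and length
# means/medians with 2 decimals; ratios (coverage, o/e, density) with more
# precision so per-bp densities survive the rounding; NA printed as "NA"
format_value <- function(x, name = "") {
  if (is.character(x) || is.factor(x)) {
    out <- as.character(x)
    out[is.na(out)] <- "NA"
    return(out)
  }
  vapply(seq_along(x), function(i) {
    v <- x[i]
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return("Inf")
    if (abs(v - round(v)) < 1e-9) {
      return(format(round(v), scientific = FALSE, trim = TRUE))
    }
    if (grepl("density", name)) return(sprintf("%.6f", v))
    if (grepl("coverage|cpg_oe|ratio", name)) return(sprintf("%.4f", v))
    sprintf("%.2f", v)
  }, character(1))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    out[[j]] <- format_value(out[[j]], names(out)[j])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8", eol = "\n")
}

# summary TSV: one row per numeric column of a data table
summarize_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  metrics <- names(df)[num]
  rows <- lapply(metrics, function(m) {
    s <- summary_stats(df[[m]])
    data.frame(metric = m, count = s$count, total = s$total, min = s$min,
               max = s$max, mean = s$mean, median = s$median,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(metric = character(0), count = integer(0),
                      total = numeric(0), min = numeric(0), max = numeric(0),
                      mean = numeric(0), median = numeric(0)))
  }
  do.call(rbind, rows)
}

overview_df <- function(overview) {
  data.frame(parameter = names(overview),
             value = vapply(seq_along(overview), function(i) {
               format_value(overview[[i]], names(overview)[i])
             }, character(1)),
             stringsAsFactors = FALSE)
}

component_sizes_df <- function(overview) {
  asm <- overview$assembly_size_with_n
  exon <- overview$exon_amount
  intron <- overview$intron_amount
  remainder <- if (is.na(exon) || is.na(intron)) NA_real_ else
    asm - exon - intron
  data.frame(
    component = c("coding_amount", "exon_amount", "intron_amount",
                  "remainder", "assembly_size"),
    length_bp = c(overview$coding_amount, exon, intron, remainder, asm),
    stringsAsFactors = FALSE)
}

#' Write the component-size overview
#'
#' Added lengths (bp) of all coding sequences, exons and introns of the
#' analyzed gene set, plus the remainder (assembly size minus exon and intron
#' amounts) and the assembly size itself. Exons, introns and the remainder
#' partition the assembly exactly.
#'
#' @param analysis A `genome_analysis` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_component_sizes <- function(analysis, path) {
  write_tsv(component_sizes_df(analysis$overview), path)
  invisible(path)
}

#' Write the ready-made shell command file
#'
#' Emits template shell lines for a downstream completeness assessment of the
#' analyzed protein set (a BUSCO invocation referencing the protein FASTA).
#' Nothing is executed; paths are quoted for shell safety.
#'
#' @param path Output text file path.
#' @param protein_fasta Path of the written protein FASTA.
#' @param label Genome label used for output naming in the commands.
#' @return The path, invisibly.
#' @export
write_commands <- function(path, protein_fasta, label = "genome") {
  lines <- c(
    "#!/bin/sh",
    "# Ready-made commands for downstream analyses of the analyzed protein set.",
    "# Review and adapt (lineage database, threads) before running.",
    "",
    "# Gene-set completeness assessment with BUSCO (proteins mode):",
    sprintf("busco -i %s -m proteins -l <lineage_odb10> -c 4 -o %s",
            shQuote(protein_fasta), shQuote(paste0(label, "_busco"))),
    "",
    "# Quick protein count:",
    sprintf("grep -c '^>' %s", shQuote(protein_fasta))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Append one genome's summary line to a batch TSV
#'
#' Batch files hold one line per analyzed genome so that several runs can be
#' compared directly. A missing file is created with a header; an existing
#' file must carry exactly the same header, otherwise nothing is appended and
#' a versioning error is raised.
#'
#' @param values Named list (or one-row data.frame) of column values.
#' @param path Batch TSV path.
#' @return The path, invisibly.
#' @export
append_batch <- function(values, path) {
  if (is.data.frame(values)) values <- as.list(values)
  header <- paste(names(values), collapse = "\t")
  line <- paste(vapply(seq_along(values), function(i) {
    format_value(values[[i]], names(values)[i])
  }, character(1)), collapse = "\t")
  if (file.exists(path)) {
    existing <- readLines(path, n = 1L, warn = FALSE)
    if (!identical(existing, header)) {
      stop("batch file '", path,
           "' has an incompatible header; not appending", call. = FALSE)
    }
    cat(line, "\n", file = path, sep = "", append = TRUE)
  } else {
    cat(header, "\n", line, "\n", file = path, sep = "")
  }
  invisible(path)
}

# batch line builders ------------------------------------------------------

batch_general_row <- function(label, overview) {
  keep <- c("assembly_size_with_n", "assembly_size_without_n",
            "assembly_gc_strict", "assembly_gc_naive", "scs_count",
            "n50", "l50", "n75", "l75", "n90", "l90", "l90pcg",
            "gene_count", "gene_skipped_count", "exon_count", "cds_count",
            "intron_count", "exon_amount", "coding_amount", "intron_amount",
            "transcript_length_mean", "transcript_length_median",
            "gene_length_mean", "gene_length_median",
            "exon_length_mean", "exon_length_median",
            "intron_length_mean", "intron_length_median",
            "cds_length_mean", "cds_length_median",
            "cds_count_per_transcript_median",
            "intron_count_per_transcript_median",
            "cds_coverage_median", "intron_coverage_median",
            "intron_density_median")
  c(list(genome = label), overview[keep])
}

batch_stat_row <- function(label, df, stat) {
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  vals <- lapply(num, function(m) {
    if (stat == "mean") mean_na(df[[m]]) else median_na(df[[m]])
  })
  c(list(genome = label), stats::setNames(vals, paste0(num, "_", stat)))
}

batch_component_row <- function(label, overview) {
  df <- component_sizes_df(overview)
  c(list(genome = label),
    stats::setNames(as.list(df$length_bp), df$component))
}

#' Write the numbered report-file suite for one analyzed genome
#'
#' Writes the per-run files (00-13 and 20) into `<out_dir>/<label>/` and
#' appends one line per batch file (14-19) in `out_dir`. File generation is
#' individually switchable through `outputs`. A machine-readable run manifest
#' (inputs, checksums, package version, transcript-choice mode, date) and a
#' run log are always written under `<out_dir>/<label>/logs/`.
#'
#' @param analysis A `genome_analysis` object.
#' @param out_dir Output directory (created if missing).
#' @param label Genome label; names the run directory and batch lines.
#' @param outputs `"all"` (default) or a vector of file numbers (0-20,
#'   integers or zero-padded strings) selecting which files to write.
#' @param fasta_path,gff3_path Input paths recorded in the run manifest.
#' @return An object of class `report_set`: list with `run_dir`, `files`
#'   (named by file number) and `label`.
#' @export
write_reports <- function(analysis, out_dir, label, outputs = "all",
                          fasta_path = NA_character_,
                          gff3_path = NA_character_) {
  stopifnot(inherits(analysis, "genome_analysis"))
  enabled <- if (identical(outputs, "all")) {
    names(REPORT_FILES)
  } else {
    sprintf("%02d", as.integer(outputs))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  run_dir <- file.path(out_dir, label)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(run_dir, "logs"), showWarnings = FALSE)

  ov <- analysis$overview
  tabs <- analysis$tables
  files <- character(0)
  path_of <- function(num) {
    dir <- if (num %in% sprintf("%02d", 14:19)) out_dir else run_dir
    file.path(dir, REPORT_FILES[[num]])
  }
  emit <- function(num, fn) {
    if (!num %in% enabled) return(invisible(NULL))
    p <- path_of(num)
    fn(p)
    files[[num]] <<- p
  }

  emit("00", function(p) Biostrings::writeXStringSet(analysis$proteins, p))
  emit("01", function(p) write_tsv(overview_df(ov), p))
  emit("02", function(p) write_tsv(tabs$scs, p))
  emit("03", function(p) write_tsv(summarize_table(tabs$scs), p))
  emit("04", function(p) write_tsv(tabs$transcript, p))
  emit("05", function(p) write_tsv(summarize_table(tabs$transcript), p))
  emit("06", function(p) write_tsv(tabs$cds, p))
  emit("07", function(p) write_tsv(summarize_table(tabs$cds), p))
  emit("08", function(p) write_tsv(tabs$exon, p))
  emit("09", function(p) write_tsv(summarize_table(tabs$exon), p))
  emit("10", function(p) write_tsv(tabs$intron, p))
  emit("11", function(p) write_tsv(summarize_table(tabs$intron), p))
  emit("12", function(p) write_tsv(length_histogram(tabs$intron$length), p))
  emit("13", function(p) write_tsv(component_sizes_df(ov), p))
  emit("14", function(p) append_batch(batch_general_row(label, ov), p))
  emit("15", function(p) append_batch(batch_stat_row(label, tabs$scs, "mean"), p))
  emit("16", function(p) append_batch(batch_stat_row(label, tabs$scs, "median"), p))
  emit("17", function(p) append_batch(batch_stat_row(label, tabs$transcript, "mean"), p))
  emit("18", function(p) append_batch(batch_stat_row(label, tabs$transcript, "median"), p))
  emit("19", function(p) append_batch(batch_component_row(label, ov), p))
  # file 20 sits next to file 00, so a run-dir-relative reference keeps the
  # command file valid wherever the run directory is moved
  emit("20", function(p) write_commands(p, REPORT_FILES[["00"]], label))

  manifest <- data.frame(
    key = c("tool", "version", "date", "label", "fasta", "fasta_md5",
            "gff3", "gff3_md5", "transcript_choice", "genes_analyzed",
            "genes_skipped_no_mrna", "zero_gap_exon_junctions",
            "files_written"),
    value = c("genestats",
              as.character(utils::packageVersion("genestats")),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
              label,
              fasta_path,
              if (is.na(fasta_path)) NA else unname(tools::md5sum(fasta_path)),
              gff3_path,
              if (is.na(gff3_path)) NA else unname(tools::md5sum(gff3_path)),
              analysis$transcript_choice,
              ov$gene_count,
              analysis$log$skipped_gene_count,
              analysis$log$zero_gap_junctions,
              paste(basename(unlist(files)), collapse = ",")),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(run_dir, "logs", "run_manifest.tsv"))
  log_lines <- c(
    sprintf("analyzed %d protein-coding genes (%s transcript per gene)",
            ov$gene_count, analysis$transcript_choice),
    sprintf("skipped %d gene(s) without mRNA%s",
            analysis$log$skipped_gene_count,
            if (analysis$log$skipped_gene_count > 0)
              paste0(": ", paste(analysis$log$skipped_gene_ids, collapse = ", "))
            else ""),
    sprintf("zero-gap exon junctions (no intron emitted): %d",
            analysis$log$zero_gap_junctions))
  writeLines(log_lines, file.path(run_dir, "logs", "run.log"))

  structure(list(run_dir = run_dir, files = files, label = label),
            class = "report_set")
}
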