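# Synthetic genome + annotation generator with exactly known ground truth.
# Every structural quantity reported in the truth bundle is computed here by
# straightforward, naive counting over the generated structures and final
# sequence characters -- never by calling the analysis kernels -- so the
# generator can serve as an independent oracle for the whole pipeline.
#
# Length draws are lognormal (skewed), so per-transcript means exceed
# medians, the situation in which reporting only means misleads genome
# comparisons.

#' Specification for a synthetic genome fixture
#'
#' Defaults describe a small but structurally realistic genome: a handful of
#' scaffolds, a few hundred genes with 1-3 transcripts each, lognormal exon
#' (median ~150 bp) and intron (median ~400 bp) lengths, a light sprinkling
#' of Ns and IUPAC ambiguity codes, and a 60/40 plus/minus strand split.
#'
#' @param scs_count Number of scaffolds.
#' @param scs_length_range Min/max scaffold length (bp).
#' @param gene_count Number of protein-coding genes.
#' @param transcripts_per_gene_range Min/max transcripts per gene
#'   (alternatives are exon-skipping isoforms, hence strictly shorter than
#'   the full-length representative).
#' @param exons_per_transcript_range Min/max exons of the full-length
#'   transcript.
#' @param exon_length_meanlog,exon_length_sdlog Lognormal parameters of exon
#'   lengths (log-bp); draws are rounded up and floored at 30 bp.
#' @param intron_length_meanlog,intron_length_sdlog Lognormal parameters of
#'   intron lengths (log-bp).
#' @param gc_target Target GC fraction of the random background sequence.
#' @param ambiguity_rate Per-base probability of an IUPAC ambiguity code.
#' @param n_run_rate Fraction of assembly bases overwritten by N runs.
#' @param minus_strand_fraction Probability that a gene lies on the minus
#'   strand.
#' @param noncoding_gene_count Number of `gene` features without an mRNA
#'   child (skipped by the analysis).
#' @param rng_seed Seed; a fixed seed yields byte-identical fixture files.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(scs_count = 8,
                         scs_length_range = c(400000, 700000),
                         gene_count = 200,
                         transcripts_per_gene_range = c(1, 3),
                         exons_per_transcript_range = c(1, 12),
                         exon_length_meanlog = 5.0,
                         exon_length_sdlog = 0.6,
                         intron_length_meanlog = 6.0,
                         intron_length_sdlog = 1.0,
                         gc_target = 0.35,
                         ambiguity_rate = 0.001,
                         n_run_rate = 5e-4,
                         minus_strand_fraction = 0.4,
                         noncoding_gene_count = 0,
                         rng_seed = 1) {
  spec <- as.list(environment())
  stopifnot(spec$scs_count >= 1, spec$gene_count >= 1,
            spec$ambiguity_rate >= 0, spec$ambiguity_rate < 1,
            spec$n_run_rate >= 0, spec$n_run_rate < 1,
            spec$minus_strand_fraction >= 0, spec$minus_strand_fraction <= 1,
            spec$gc_target > 0, spec$gc_target < 1)
  class(spec) <- "fixture_spec"
  spec
}

# naive prefix-scan oracles, deliberately dumb --------------------------------

oracle_nx_lx <- function(lengths, fraction) {
  o <- sort(lengths, decreasing = TRUE)
  total <- sum(o)
  for (k in seq_along(o)) {
    if (sum(o[seq_len(k)]) >= fraction * total - 1e-9) {
      return(list(n = o[k], l = k))
    }
  }
}

oracle_l90pcg <- function(counts, fraction = 0.9) {
  o <- sort(counts, decreasing = TRUE)
  target <- ceiling(fraction * sum(o) - 1e-9)
  for (k in seq_along(o)) {
    if (sum(o[seq_len(k)]) >= target) return(k)
  }
}

mean2 <- function(x) { x <- x[!is.na(x)]; if (!length(x)) NA_real_ else sum(x) / length(x) }
median2 <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else (x[n %/% 2L] + x[n %/% 2L + 1L]) / 2
}

#' Generate a synthetic genome fixture with ground truth
#'
#' Writes a FASTA assembly and a GFF3 annotation realizing `spec`, together
#' with a `ground_truth.tsv` sidecar, and returns the ground-truth values of
#' every assembly-overview parameter. The truth is computed by independent
#' naive enumeration during generation, by construction of the placed
#' features and a character-level tally of the final sequences.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created).
#' @return A list with `fasta`, `gff3`, `truth_tsv` (paths), `truth` (named
#'   list keyed like the analysis overview) and `detail` (per-gene structure
#'   records).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$rng_seed)

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(rng[1]:rng[2], 1L)

  # --- gene structures (lengths first, coordinates after placement) ---------
  genes <- vector("list", spec$gene_count)
  for (g in seq_len(spec$gene_count)) {
    n_ex <- rint(spec$exons_per_transcript_range)
    ex <- pmax(30L, as.integer(ceiling(stats::rlnorm(
      n_ex, spec$exon_length_meanlog, spec$exon_length_sdlog))))
    ins <- if (n_ex > 1L) pmax(1L, as.integer(ceiling(stats::rlnorm(
      n_ex - 1L, spec$intron_length_meanlog, spec$intron_length_sdlog))))
      else integer(0)
    strand <- if (stats::runif(1) < spec$minus_strand_fraction) "-" else "+"
    n_tr <- rint(spec$transcripts_per_gene_range)
    if (n_ex < 2L) n_tr <- 1L
    # CDS: a contiguous-in-splice-space exon run, UTR-trimmed at both ends
    ci <- sample.int(n_ex, 1L)
    cj <- if (ci == n_ex) n_ex else sample(ci:n_ex, 1L)
    d1 <- sample(0:10, 1L)
    d2 <- sample(0:10, 1L)
    # alternative (exon-skipping) isoforms keep a strict subset of exons
    alt_keep <- if (n_tr > 1L) lapply(seq_len(n_tr - 1L), function(a) {
      drop_n <- sample.int(n_ex - 1L, 1L)
      sort(sample.int(n_ex, n_ex - drop_n))
    }) else list()
    genes[[g]] <- list(id = sprintf("g%04d", g), n_ex = n_ex, ex = ex,
                       ins = ins, strand = strand, ci = ci, cj = cj,
                       d1 = d1, d2 = d2, alt_keep = alt_keep,
                       span = sum(ex) + sum(ins))
  }
  nc_spans <- if (spec$noncoding_gene_count > 0L)
    vapply(seq_len(spec$noncoding_gene_count),
           function(i) sample(200:400, 1L), integer(1)) else integer(0)

  # --- placement: non-overlapping genes, scaffold with most room first ------
  scs_len <- vapply(seq_len(spec$scs_count),
                    function(i) rint(as.integer(spec$scs_length_range)),
                    integer(1))
  scs_ids <- sprintf("scf%02d", seq_len(spec$scs_count))
  cursor <- rep(1L, spec$scs_count)
  place <- function(span) {
    gap <- sample(200:2000, 1L)
    ord <- order(scs_len - cursor, decreasing = TRUE)
    for (s in ord) {
      start <- cursor[s] + gap
      if (start + span - 1L <= scs_len[s] - 200L) {
        cursor[s] <<- start + span
        return(list(scs = s, start = start))
      }
    }
    stop("fixture genes do not fit on the specified scaffolds; ",
         "increase scs_length_range or scs_count", call. = FALSE)
  }
  for (g in seq_along(genes)) {
    p <- place(genes[[g]]$span)
    genes[[g]]$scs <- p$scs
    genes[[g]]$start <- p$start
    # exon coordinates from cumulative exon/intron lengths
    ge <- genes[[g]]
    starts <- integer(ge$n_ex); ends <- integer(ge$n_ex)
    pos <- ge$start
    for (k in seq_len(ge$n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + ge$ex[k] - 1L
      pos <- ends[k] + 1L + if (k < ge$n_ex) ge$ins[k] else 0L
    }
    genes[[g]]$ex_start <- starts
    genes[[g]]$ex_end <- ends
  }
  nc_pos <- lapply(nc_spans, place)

  # --- sequences ------------------------------------------------------------
  gc <- spec$gc_target
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  amb_codes <- c("R", "Y", "K", "M", "S", "W", "B", "D", "H", "V")
  scaffold_chars <- vector("list", spec$scs_count)
  for (s in seq_len(spec$scs_count)) {
    L <- scs_len[s]
    chars <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
    total_n <- round(spec$n_run_rate * L)
    placed <- 0L
    while (placed < total_n) {
      run <- min(sample(50:300, 1L), total_n - placed)
      pos <- sample.int(L - run, 1L)
      chars[pos:(pos + run - 1L)] <- "N"
      placed <- placed + run
    }
    n_amb <- stats::rbinom(1L, L, spec$ambiguity_rate)
    if (n_amb > 0L) {
      chars[sample.int(L, n_amb)] <- sample(amb_codes, n_amb, replace = TRUE)
    }
    scaffold_chars[[s]] <- chars
  }

  # --- write FASTA ----------------------------------------------------------
  fasta <- file.path(dir, "assembly.fasta")
  con <- file(fasta, "w")
  for (s in seq_len(spec$scs_count)) {
    writeLines(paste0(">", scs_ids[s]), con)
    seq <- paste(scaffold_chars[[s]], collapse = "")
    writeLines(substring(seq, seq(1, nchar(seq), 70),
                         pmin(seq(1, nchar(seq), 70) + 69, nchar(seq))), con)
  }
  close(con)

  # --- write GFF3 -----------------------------------------------------------
  cds_segments <- function(ge, keep) {
    idx <- intersect(ge$ci:ge$cj, keep)
    if (length(idx) == 0L) return(NULL)
    st <- ge$ex_start[idx]; en <- ge$ex_end[idx]
    if (idx[1L] == ge$ci) st[1L] <- st[1L] + ge$d1
    if (idx[length(idx)] == ge$cj) en[length(en)] <- en[length(en)] - ge$d2
    lens <- en - st + 1L
    if (sum(lens) < 6L) return(NULL)
    # phase = coding bases upstream of the segment in translation order,
    # folded into the 0/1/2 frame; the first translated segment has phase 0
    cum0 <- if (ge$strand == "-") rev(cumsum(c(0L, rev(lens)[-length(lens)])))
            else cumsum(c(0L, lens[-length(lens)]))
    phases <- (3L - (cum0 %% 3L)) %% 3L
    data.frame(start = st, end = en, phase = phases)
  }
  gff_lines <- character(0)
  gff_add <- function(seqid, type, start, end, strand, phase, attrs) {
    sprintf("%s\tgenestats_fixture\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seqid, type, start, end, strand, phase, attrs)
  }
  all_rows <- list()
  for (ge in genes) {
    seqid <- scs_ids[ge$scs]
    rows <- gff_add(seqid, "gene", ge$start, max(ge$ex_end), ge$strand, ".",
                    paste0("ID=", ge$id))
    keeps <- c(list(seq_len(ge$n_ex)), ge$alt_keep)
    for (t in seq_along(keeps)) {
      keep <- keeps[[t]]
      tid <- sprintf("%s.t%d", ge$id, t)
      rows <- c(rows, gff_add(seqid, "mRNA", min(ge$ex_start[keep]),
                              max(ge$ex_end[keep]), ge$strand, ".",
                              paste0("ID=", tid, ";Parent=", ge$id)))
      for (k in seq_along(keep)) {
        rows <- c(rows, gff_add(seqid, "exon", ge$ex_start[keep[k]],
                                ge$ex_end[keep[k]], ge$strand, ".",
                                paste0("ID=", tid, ".exon", k, ";Parent=", tid)))
      }
      cds <- cds_segments(ge, keep)
      if (!is.null(cds)) {
        for (k in seq_len(nrow(cds))) {
          rows <- c(rows, gff_add(seqid, "CDS", cds$start[k], cds$end[k],
                                  ge$strand, as.character(cds$phase[k]),
                                  paste0("ID=", tid, ".cds", k, ";Parent=", tid)))
        }
      }
    }
    all_rows[[ge$id]] <- list(scs = ge$scs, start = ge$start, rows = rows)
  }
  nc_ids <- character(0)
  if (length(nc_pos) > 0L) {
    for (i in seq_along(nc_pos)) {
      id <- sprintf("ncgene%03d", i)
      nc_ids <- c(nc_ids, id)
      all_rows[[id]] <- list(
        scs = nc_pos[[i]]$scs, start = nc_pos[[i]]$start,
        rows = gff_add(scs_ids[nc_pos[[i]]$scs], "gene", nc_pos[[i]]$start,
                       nc_pos[[i]]$start + nc_spans[i] - 1L, "+", ".",
                       paste0("ID=", id)))
    }
  }
  ord <- order(vapply(all_rows, `[[`, integer(1), "scs"),
               vapply(all_rows, `[[`, integer(1), "start"))
  gff3 <- file.path(dir, "annotation.gff3")
  writeLines(c("##gff-version 3",
               unlist(lapply(all_rows[ord], `[[`, "rows"))), gff3)

  # --- independent ground truth --------------------------------------------
  rep_cds <- lapply(genes, function(ge) cds_segments(ge, seq_len(ge$n_ex)))
  cds_lens <- lapply(rep_cds, function(x) if (is.null(x)) numeric(0) else
    x$end - x$start + 1)
  ex_all <- unlist(lapply(genes, `[[`, "ex"))
  in_all <- unlist(lapply(genes, `[[`, "ins"))
  spliced <- vapply(genes, function(ge) sum(ge$ex), numeric(1))
  spans <- vapply(genes, `[[`, numeric(1), "span")
  strands <- vapply(genes, `[[`, character(1), "strand")
  genes_per_scs <- tabulate(vapply(genes, `[[`, integer(1), "scs"),
                            nbins = spec$scs_count)
  tallies <- lapply(scaffold_chars, function(ch)
    table(factor(ch, levels = IUPAC_LETTERS)))
  total_counts <- Reduce(`+`, tallies)
  total_len <- sum(scs_len)
  n_count <- as.numeric(total_counts[["N"]])
  amb_count <- sum(as.numeric(total_counts[GC_AMBIGUOUS]))
  gcs <- as.numeric(total_counts[["G"]] + total_counts[["C"]])
  gcs_strict <- gcs + as.numeric(total_counts[["S"]])
  nx50 <- oracle_nx_lx(scs_len, 0.5)
  nx75 <- oracle_nx_lx(scs_len, 0.75)
  nx90 <- oracle_nx_lx(scs_len, 0.9)

  per_tr <- list(
    exon_mean = vapply(genes, function(ge) mean2(ge$ex), numeric(1)),
    exon_median = vapply(genes, function(ge) median2(ge$ex), numeric(1)),
    intron_mean = vapply(genes, function(ge) mean2(ge$ins), numeric(1)),
    intron_median = vapply(genes, function(ge) median2(ge$ins), numeric(1)),
    intron_count = vapply(genes, function(ge) length(ge$ins), numeric(1)),
    cds_count = vapply(cds_lens, function(x)
      if (length(x)) length(x) else NA_real_, numeric(1)),
    cds_added = vapply(cds_lens, function(x)
      if (length(x)) sum(x) else NA_real_, numeric(1))
  )
  cds_cov <- per_tr$cds_added / spans
  exon_cov <- spliced / spans
  intron_cov <- vapply(genes, function(ge) sum(ge$ins), numeric(1)) / spans
  intron_dens <- per_tr$intron_count / spans

  truth <- list(
    scs_count = spec$scs_count,
    assembly_size_with_n = total_len,
    assembly_size_without_n = total_len - n_count,
    assembly_n_count = n_count,
    assembly_ambiguity_count = amb_count,
    assembly_gc_strict = 100 * gcs_strict / (total_len - amb_count),
    assembly_gc_naive = 100 * gcs / total_len,
    n50 = nx50$n, l50 = nx50$l, n75 = nx75$n, l75 = nx75$l,
    n90 = nx90$n, l90 = nx90$l,
    l90pcg = oracle_l90pcg(genes_per_scs),
    gene_count = spec$gene_count,
    gene_skipped_count = spec$noncoding_gene_count,
    transcript_count = spec$gene_count,
    transcripts_plus = sum(strands == "+"),
    transcripts_minus = sum(strands == "-"),
    transcripts_unknown = 0L,
    exon_count = length(ex_all),
    cds_count = sum(lengths(cds_lens)),
    intron_count = length(in_all),
    exon_amount = sum(ex_all),
    coding_amount = sum(unlist(cds_lens)),
    intron_amount = sum(in_all),
    transcript_length_mean = mean2(spliced),
    transcript_length_median = median2(spliced),
    gene_length_mean = mean2(spans),
    gene_length_median = median2(spans),
    exon_length_mean = mean2(ex_all),
    exon_length_median = median2(ex_all),
    intron_length_mean = mean2(in_all),
    intron_length_median = median2(in_all),
    cds_length_mean = mean2(unlist(cds_lens)),
    cds_length_median = median2(unlist(cds_lens)),
    cds_count_per_transcript_mean = mean2(per_tr$cds_count),
    cds_count_per_transcript_median = median2(per_tr$cds_count),
    intron_count_per_transcript_mean = mean2(per_tr$intron_count),
    intron_count_per_transcript_median = median2(per_tr$intron_count),
    cds_coverage_mean = mean2(cds_cov),
    cds_coverage_median = median2(cds_cov),
    exon_coverage_mean = mean2(exon_cov),
    exon_coverage_median = median2(exon_cov),
    intron_coverage_mean = mean2(intron_cov),
    intron_coverage_median = median2(intron_cov),
    intron_density_mean = mean2(intron_dens),
    intron_density_median = median2(intron_dens),
    per_transcript_mean_exon_length_mean = mean2(per_tr$exon_mean),
    per_transcript_median_exon_length_mean = mean2(per_tr$exon_median),
    per_transcript_median_exon_length_median = median2(per_tr$exon_median),
    per_transcript_mean_intron_length_mean = mean2(per_tr$intron_mean),
    per_transcript_median_intron_length_mean = mean2(per_tr$intron_median),
    per_transcript_median_intron_length_median = median2(per_tr$intron_median)
  )

  truth_tsv <- file.path(dir, "ground_truth.tsv")
  utils::write.table(
    data.frame(parameter = names(truth),
               value = vapply(truth, function(v) format(v, digits = 15),
                              character(1))),
    truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  list(fasta = fasta, gff3 = gff3, truth_tsv = truth_tsv, truth = truth,
       detail = list(genes = genes, scs_len = scs_len, scs_ids = scs_ids,
                     genes_per_scs = genes_per_scs,
                     noncoding_ids = nc_ids))
}

#' A fixed, hand-auditable micro genome
#'
#' Writes a 2-scaffold, 3-gene genome (plus one non-coding gene that the
#' analysis must skip) whose every overview value is small enough to verify
#' by hand; the expected values are returned alongside and documented in the
#' package vignette. Used as the worked example and as a golden end-to-end
#' test.
#'
#' Layout: scaffold s1 (100 bp, incl. a 10 bp N run) carries g1 (2 exons,
#' plus strand) and g2 (single exon, minus strand); scaffold s2 (60 bp)
#' carries g3 (3 exons, plus strand) and the mRNA-less gene ncg1.
#'
#' @param dir Output directory (created).
#' @return A list with `fasta`, `gff3` (paths) and `expected` (named list of
#'   overview values).
#' @export
worked_micro_genome <- function(dir = tempfile("micro_genome")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s1 <- paste0(strrep("ACGT", 20), strrep("N", 10), "GGGGGCCCCC")  # 100 bp
  s2 <- paste0(strrep("ACGT", 10), strrep("AT", 5), strrep("CG", 5))  # 60 bp
  fasta <- file.path(dir, "micro.fasta")
  writeLines(c(">s1 micro scaffold 1", s1, ">s2 micro scaffold 2", s2), fasta)

  rows <- c(
    "##gff-version 3",
    "s1\tmicro\tgene\t1\t30\t.\t+\t.\tID=g1",
    "s1\tmicro\tmRNA\t1\t30\t.\t+\t.\tID=g1.t1;Parent=g1",
    "s1\tmicro\texon\t1\t10\t.\t+\t.\tID=g1.t1.exon1;Parent=g1.t1",
    "s1\tmicro\texon\t21\t30\t.\t+\t.\tID=g1.t1.exon2;Parent=g1.t1",
    "s1\tmicro\tCDS\t3\t10\t.\t+\t0\tID=g1.t1.cds1;Parent=g1.t1",
    "s1\tmicro\tCDS\t21\t26\t.\t+\t1\tID=g1.t1.cds2;Parent=g1.t1",
    "s1\tmicro\tgene\t41\t60\t.\t-\t.\tID=g2",
    "s1\tmicro\tmRNA\t41\t60\t.\t-\t.\tID=g2.t1;Parent=g2",
    "s1\tmicro\texon\t41\t60\t.\t-\t.\tID=g2.t1.exon1;Parent=g2.t1",
    "s1\tmicro\tCDS\t43\t57\t.\t-\t0\tID=g2.t1.cds1;Parent=g2.t1",
    "s2\tmicro\tgene\t5\t44\t.\t+\t.\tID=g3",
    "s2\tmicro\tmRNA\t5\t44\t.\t+\t.\tID=g3.t1;Parent=g3",
    "s2\tmicro\texon\t5\t14\t.\t+\t.\tID=g3.t1.exon1;Parent=g3.t1",
    "s2\tmicro\texon\t21\t28\t.\t+\t.\tID=g3.t1.exon2;Parent=g3.t1",
    "s2\tmicro\texon\t35\t44\t.\t+\t.\tID=g3.t1.exon3;Parent=g3.t1",
    "s2\tmicro\tCDS\t21\t28\t.\t+\t0\tID=g3.t1.cds1;Parent=g3.t1",
    "s2\tmicro\tCDS\t35\t40\t.\t+\t1\tID=g3.t1.cds2;Parent=g3.t1",
    "s2\tmicro\tgene\t50\t55\t.\t+\t.\tID=ncg1"
  )
  gff3 <- file.path(dir, "micro.gff3")
  writeLines(rows, gff3)

  # hand-computed expectations (see the methods vignette for the arithmetic)
  expected <- list(
    scs_count = 2,
    assembly_size_with_n = 160,
    assembly_size_without_n = 150,
    assembly_n_count = 10,
    assembly_ambiguity_count = 10,
    assembly_gc_strict = 100 * 80 / 150,
    assembly_gc_naive = 50,
    n50 = 100, l50 = 1, n75 = 60, l75 = 2, n90 = 60, l90 = 2,
    l90pcg = 2,
    gene_count = 3,
    gene_skipped_count = 1,
    transcript_count = 3,
    transcripts_plus = 2,
    transcripts_minus = 1,
    transcripts_unknown = 0,
    exon_count = 6,
    cds_count = 5,
    intron_count = 3,
    exon_amount = 68,
    coding_amount = 43,
    intron_amount = 22,
    transcript_length_mean = 68 / 3,
    transcript_length_median = 20,
    gene_length_mean = 30,
    gene_length_median = 30,
    exon_length_mean = 68 / 6,
    exon_length_median = 10,
    intron_length_mean = 22 / 3,
    intron_length_median = 6,
    cds_length_mean = 43 / 5,
    cds_length_median = 8,
    cds_count_per_transcript_mean = 5 / 3,
    cds_count_per_transcript_median = 2,
    intron_count_per_transcript_mean = 1,
    intron_count_per_transcript_median = 1,
    cds_coverage_mean = (14 / 30 + 15 / 20 + 14 / 40) / 3,
    cds_coverage_median = 14 / 30,
    exon_coverage_mean = (20 / 30 + 1 + 28 / 40) / 3,
    exon_coverage_median = 28 / 40,
    intron_coverage_mean = (10 / 30 + 0 + 12 / 40) / 3,
    intron_coverage_median = 12 / 40,
    intron_density_mean = (1 / 30 + 0 + 2 / 40) / 3,
    intron_density_median = 1 / 30,
    per_transcript_mean_exon_length_mean = (10 + 20 + 28 / 3) / 3,
    per_transcript_median_exon_length_mean = (10 + 20 + 10) / 3,
    per_transcript_median_exon_length_median = 10,
    per_transcript_mean_intron_length_mean = (10 + 6) / 2,
    per_transcript_median_intron_length_mean = 8,
    per_transcript_median_intron_length_median = 8,
    protein_length_mean = (4 + 5 + 4) / 3,
    protein_length_median = 4
  )
  list(fasta = fasta, gff3 = gff3, expected = expected, dir = dir)
}
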