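# Independent brute-force oracles for the metric kernels, written as plain
# character/vector scans so they share no code path with the package.

AMBIG <- c("N", "R", "Y", "K", "M", "B", "D", "H", "V")
IUPAC <- c("A", "C", "G", "T", "N", "R", "Y", "K", "M", "S", "W",
           "B", "D", "H", "V")

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  den <- sum(!ch %in% AMBIG)
  list(
    strict = if (den > 0) 100 * sum(ch %in% c("G", "C", "S")) / den else NA_real_,
    naive = 100 * sum(ch %in% c("G", "C")) / length(ch)
  )
}

oracle_cpg <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  obs <- 0L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (ch[i] == "C" && ch[i + 1L] == "G") obs <- obs + 1L
    }
  }
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  if (nc == 0L || ng == 0L) NA_real_ else obs * n / (nc * ng)
}

# exhaustive prefix scan over the descending sort
oracle_nx <- function(lengths, fraction) {
  o <- sort(lengths, decreasing = TRUE)
  for (k in seq_along(o)) {
    if (sum(o[1:k]) >= fraction * sum(o) - 1e-9) {
      return(c(n = o[k], l = k))
    }
  }
}

oracle_l90 <- function(counts, fraction = 0.9) {
  o <- sort(counts, decreasing = TRUE)
  target <- ceiling(fraction * sum(o) - 1e-9)
  for (k in seq_along(o)) {
    if (sum(o[1:k]) >= target) return(k)
  }
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# hand-rolled reverse complement over the full IUPAC alphabet
oracle_revcomp <- function(seq) {
  ch <- rev(strsplit(seq, "")[[1L]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R",
            K = "M", M = "K", S = "S", W = "W", B = "V", V = "B", D = "H",
            H = "D")
  paste(comp[ch], collapse = "")
}
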