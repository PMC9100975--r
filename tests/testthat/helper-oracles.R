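# Independent brute-force oracles. These deliberately re-derive results by
# direct enumeration / full scans, sharing no code path with the package
# implementations they check.

# all end-to-end placements of `read` on `genome_chr` (single character
# string) within `mm` substitutions, on both strands; full scan
oracle_scan_genome <- function(read, genome_chr, mm = 0L) {
  g <- strsplit(genome_chr, "")[[1]]
  G <- length(g)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read else {
      chartr("ACGT", "TGCA", paste(rev(strsplit(read, "")[[1]]), collapse = ""))
    }
    p <- strsplit(pat, "")[[1]]
    L <- length(p)
    if (G < L) next
    for (off in 1:(G - L + 1)) {
      d <- sum(g[off:(off + L - 1)] != p)
      if (d <= mm) {
        out[[length(out) + 1]] <- data.frame(start = off, end = off + L - 1,
                                             strand = strand, mismatches = d,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0))
}

# TRUE iff `read` sits within `mm` substitutions of some window of some
# reference sequence, either strand
oracle_is_contaminant <- function(read, ref_seqs, mm = 1L) {
  for (rs in ref_seqs) {
    if (nrow(oracle_scan_genome(read, rs, mm)) > 0) return(TRUE)
  }
  FALSE
}

# literal transcription of the category rule, written against a plain
# counts vector
oracle_categorize <- function(counts, pos) {
  c0 <- counts[pos]
  if (c0 == 0) return(NA_integer_)
  if (c0 == 1) return(4L)
  mx <- max(counts)
  if (c0 == mx && sum(counts == mx) == 1) return(0L)
  if (c0 == mx) return(1L)
  nz <- counts[counts > 0]
  if (c0 > sum(nz) / length(nz)) return(2L)
  3L
}

# exact hypergeometric upper tail by direct combinatorial summation
oracle_hyper_upper <- function(k, K, N, n) {
  js <- max(k, 0):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# median-of-ratios size factors, written independently
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  m2 <- m[keep, , drop = FALSE]
  gm <- apply(m2, 1, function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(m2)), function(j) median(m2[, j] / gm))
}

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}
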