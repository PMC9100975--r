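# Low-level sequence helpers shared across modules. All user-facing I/O of
# FASTA/FASTQ goes through Biostrings; these helpers only wrap it into the
# plain data.frame representation the QC and simulation code works on.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA sequences
#'
#' Independent uniform draws over A/C/G/T. Used by the simulator for genome
#' background, loops, padding, and decoy material.
#'
#' @param n number of sequences.
#' @param len length of each sequence (recycled against `n`).
#' @return character vector of length `n`.
#' @keywords internal
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse-complement character sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Leftmost occurrence (1-based) of `seed` in each of `seqs` allowing up to
# `max_mismatch` substitutions; NA when absent. Vectorized across reads:
# one pass per candidate offset over a position x read character matrix.
leftmost_seed_match <- function(seqs, seed, max_mismatch = 1) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  k <- nchar(seed)
  seed_chars <- strsplit(seed, "")[[1]]
  lens <- nchar(seqs)
  maxlen <- max(lens)
  # char matrix, maxlen x n, padded with "" beyond each read's end
  mat <- matrix("", nrow = maxlen, ncol = n)
  sp <- strsplit(seqs, "")
  for (i in seq_len(n)) mat[seq_len(lens[i]), i] <- sp[[i]]
  out <- rep(NA_integer_, n)
  for (off in seq_len(max(0L, maxlen - k + 1L))) {
    open <- is.na(out) & lens >= off + k - 1L
    if (!any(open)) break
    block <- mat[off:(off + k - 1L), open, drop = FALSE]
    mm <- colSums(block != seed_chars)
    hit <- which(open)[mm <= max_mismatch]
    out[hit] <- off
  }
  out
}

#' Read a FASTQ file into a read table
#'
#' Parses FASTQ (Phred+33, optionally gzip-compressed) via Biostrings and
#' returns the plain representation used throughout the package.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(if (nrow(reads)) reads$seq else character(0))
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(if (nrow(reads)) reads$qual else character(0)),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read FASTA into a DNAStringSet
#' @param path FASTA file path.
#' @return `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write named sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Phred+33 helpers -----------------------------------------------------------

# integer Phred scores for a vector of quality strings (list of int vectors)
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_qual <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}
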