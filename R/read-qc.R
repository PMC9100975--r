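# Read QC: 3' adapter inference, trimming, and the six-way read filter with
# exact conservation accounting. Every raw read lands in exactly one
# category (fixed test order), so the report's integer identity
#   raw == clean + low_quality + high_n + five_prime_adapter
#          + no_three_prime_adapter + poly_nt + length_out_of_range
# holds on every input.

#' QC filter parameters
#'
#' @param max_low_qual_frac a read is low-quality when the fraction of bases
#'   with Phred score below `min_base_quality` exceeds this (default 0.30).
#' @param min_base_quality Phred threshold for a "low" base call (default 20).
#' @param max_n_frac maximum tolerated fraction of N bases (default 0.10).
#' @param poly_frac a trimmed read is a homopolymer artifact when a single
#'   base makes up at least this fraction of it (default 0.80).
#' @param min_len,max_len post-trimming insert length window (default 18-30).
#' @param adapter5 optional explicit 5' adapter; by default the last 10 nt of
#'   the reverse complement of the 3' adapter is used as the 5'-contamination
#'   marker.
#' @return list of parameters.
#' @export
qc_params <- function(max_low_qual_frac = 0.30, min_base_quality = 20L,
                      max_n_frac = 0.10, poly_frac = 0.80,
                      min_len = 18L, max_len = 30L, adapter5 = NULL) {
  stopifnot(max_low_qual_frac >= 0, max_n_frac >= 0, poly_frac > 0,
            min_len >= 1, max_len >= min_len)
  list(max_low_qual_frac = max_low_qual_frac,
       min_base_quality = as.integer(min_base_quality),
       max_n_frac = max_n_frac, poly_frac = poly_frac,
       min_len = as.integer(min_len), max_len = as.integer(max_len),
       adapter5 = adapter5)
}

#' Construct and validate a filter report
#'
#' Enforces the exact conservation identity: the raw count must equal the
#' clean count plus the six discard categories.
#'
#' @param raw,clean,low_quality,high_n,five_prime_adapter,
#'   no_three_prime_adapter,poly_nt,length_out_of_range integer counts.
#' @param q20_fraction,q30_fraction,gc_fraction base-level summary fractions.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(raw, clean, low_quality = 0L, high_n = 0L,
                          five_prime_adapter = 0L, no_three_prime_adapter = 0L,
                          poly_nt = 0L, length_out_of_range = 0L,
                          q20_fraction = NA_real_, q30_fraction = NA_real_,
                          gc_fraction = NA_real_) {
  counts <- c(raw = raw, clean = clean, low_quality = low_quality,
              high_n = high_n, five_prime_adapter = five_prime_adapter,
              no_three_prime_adapter = no_three_prime_adapter,
              poly_nt = poly_nt, length_out_of_range = length_out_of_range)
  if (any(counts < 0)) stop("filter report counts must be non-negative")
  if (raw != clean + low_quality + high_n + five_prime_adapter +
      no_three_prime_adapter + poly_nt + length_out_of_range) {
    stop("filter report does not balance: raw != clean + discards")
  }
  structure(c(as.list(counts),
              list(q20_fraction = q20_fraction, q30_fraction = q30_fraction,
                   gc_fraction = gc_fraction)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Read filter report\n")
  cat(sprintf("  raw: %d  clean: %d\n", x$raw, x$clean))
  for (cat_ in DEFECT_CATEGORIES) cat(sprintf("  %-24s %d\n", cat_, x[[cat_]]))
  cat(sprintf("  Q20 %.4f  Q30 %.4f  GC %.4f\n",
              x$q20_fraction, x$q30_fraction, x$gc_fraction))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(metric = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Infer the 3' adapter from read suffixes
#'
#' A most-frequent-k-mer consensus: k-mers are collected at all offsets in
#' the expected adapter-start window (insert lengths `min_len` to `max_len`)
#' and the k-mer seen in the largest fraction of reads wins, provided it
#' reaches `min_frequency`. A user-supplied adapter bypasses the scan.
#'
#' @param reads read data.frame (columns `id`, `seq`, `qual`) or character
#'   vector of sequences.
#' @param k k-mer length (default 10).
#' @param adapter optional known adapter; returned unchanged without a scan.
#' @param min_frequency consensus threshold (default 0.25).
#' @param insert_range offsets scanned: adapter starts after an insert of
#'   this length range (default 18-30 nt, the plant small-RNA window).
#' @return inferred k-mer (the adapter's first `k` nt), or the supplied
#'   adapter.
#' @export
infer_adapter3 <- function(reads, k = 10L, adapter = NULL,
                           min_frequency = 0.25, insert_range = c(18L, 30L)) {
  if (!is.null(adapter)) return(toupper(adapter))
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) < 100) stop("need at least 100 reads to infer an adapter")
  offs <- (insert_range[1] + 1L):(insert_range[2] + 1L)
  # frequency = fraction of reads containing the k-mer anywhere in the window
  per_read <- lapply(offs, function(o) substr(seqs, o, o + k - 1L))
  tab <- table(unlist(lapply(seq_along(seqs), function(i) {
    unique(vapply(per_read, `[[`, character(1), i))
  })))
  tab <- tab[nchar(names(tab)) == k & !grepl("N", names(tab))]
  if (length(tab) == 0) stop("no adapter consensus")
  if (max(tab) / length(seqs) < min_frequency) stop("no adapter consensus")
  # every k-mer inside the adapter is near-tied in frequency; walk the
  # overlap chain of near-maximal k-mers to its upstream-most member, which
  # is the adapter's first k nt
  cands <- names(tab)[tab >= 0.9 * max(tab)]
  upstream <- cands[vapply(cands, function(x) {
    !any(substr(setdiff(cands, x), 2, k) == substr(x, 1, k - 1))
  }, logical(1))]
  if (length(upstream) == 0) upstream <- cands
  upstream[which.max(tab[upstream])]
}

#' Trim reads at the 3' adapter
#'
#' Truncates each sequence at the leftmost occurrence of the adapter's first
#' 10 nt, allowing one mismatch in the seed. Reads in which the seed is not
#' found keep their full sequence and are flagged; a full-length read without
#' an adapter hit is a `no_three_prime_adapter` discard candidate, while a
#' read already short enough to be a trimmed insert passes through (making
#' re-filtering of clean output a no-op).
#'
#' @param reads read data.frame with `id`, `seq`, `qual`.
#' @param adapter3 adapter sequence, length >= 10.
#' @param max_len inserts longer than this flag missing adapters (see above).
#' @return `reads` with extra columns `insert`, `insert_qual`, `trim_pos`
#'   (NA when the adapter was absent) and logical `adapter_missing`.
#' @export
trim_reads <- function(reads, adapter3, max_len = 30L) {
  if (nchar(adapter3) < 10) stop("adapter3 must be at least 10 nt")
  seed10 <- substr(adapter3, 1, 10)
  pos <- leftmost_seed_match(reads$seq, seed10, 1L)
  insert <- ifelse(is.na(pos), reads$seq, substr(reads$seq, 1, pos - 1L))
  insert_qual <- ifelse(is.na(pos), reads$qual, substr(reads$qual, 1, pos - 1L))
  reads$insert <- insert
  reads$insert_qual <- insert_qual
  reads$trim_pos <- pos
  reads$adapter_missing <- is.na(pos) & nchar(reads$seq) > max_len
  reads
}

#' Filter reads into clean output plus six discard categories
#'
#' Applies, in fixed order, the tests: low quality (fraction of sub-Q20
#' bases above 30% of the whole read), high N (above 10% of the read),
#' 5' adapter contamination (read starts with the 5'-adapter marker,
#' one mismatch allowed), missing 3' adapter, poly A/T/C/G homopolymer
#' (>= 80% one base in the trimmed insert), and insert length outside the
#' 18-30 nt window. Each read is counted in exactly one category; a read
#' passing every test is clean.
#'
#' @param reads read data.frame (`id`, `seq`, `qual`).
#' @param adapter3 3' adapter (>= 10 nt).
#' @param params a [qc_params()] list.
#' @return list with `clean` (trimmed clean reads: `id`, `seq`, `qual` hold
#'   the insert), `report` (a [filter_report()]), and `category` (per-read
#'   assignment, in input order).
#' @export
filter_reads <- function(reads, adapter3, params = qc_params()) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- which(nchar(reads$seq) != nchar(reads$qual))[1]
    stop("malformed read record at index ", bad,
         ": sequence and quality lengths differ")
  }
  n <- nrow(reads)
  if (n == 0) {
    rep0 <- filter_report(0L, 0L)
    return(list(clean = reads[, c("id", "seq", "qual")], report = rep0,
                category = character(0)))
  }
  lens <- nchar(reads$seq)

  scores <- phred_scores(reads$qual)
  lowq_frac <- vapply(scores, function(s) mean(s < params$min_base_quality), numeric(1))
  q20 <- vapply(scores, function(s) mean(s >= 20), numeric(1))
  q30 <- vapply(scores, function(s) mean(s >= 30), numeric(1))
  nN <- lens - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  gc <- (nchar(gsub("[^GC]", "", reads$seq)) ) / pmax(1L, lens - nN)

  is_lowq <- lowq_frac > params$max_low_qual_frac
  is_highn <- nN / lens > params$max_n_frac

  marker5 <- if (!is.null(params$adapter5)) {
    substr(params$adapter5, 1, 10)
  } else {
    rc <- revcomp(adapter3)
    substr(rc, nchar(rc) - 9L, nchar(rc))
  }
  first10 <- leftmost_seed_match(substr(reads$seq, 1, 10), marker5, 1L)
  is_5p <- !is.na(first10) & first10 == 1L & lens >= 10L

  trimmed <- trim_reads(reads, adapter3, max_len = params$max_len)
  is_no3p <- trimmed$adapter_missing

  ins <- trimmed$insert
  ins_len <- nchar(ins)
  base_max <- vapply(seq_len(n), function(i) {
    if (ins_len[i] == 0) return(0)
    max(vapply(DNA_BASES, function(b) {
      ins_len[i] - nchar(gsub(b, "", ins[i], fixed = TRUE))
    }, numeric(1))) / ins_len[i]
  }, numeric(1))
  is_poly <- base_max >= params$poly_frac & ins_len > 0
  is_badlen <- ins_len < params$min_len | ins_len > params$max_len

  category <- rep("clean", n)
  category[is_badlen] <- "length_out_of_range"
  category[is_poly] <- "poly_nt"
  category[is_no3p] <- "no_three_prime_adapter"
  category[is_5p] <- "five_prime_adapter"
  category[is_highn] <- "high_n"
  category[is_lowq] <- "low_quality"

  keep <- category == "clean"
  clean <- data.frame(id = reads$id[keep], seq = ins[keep],
                      qual = trimmed$insert_qual[keep], stringsAsFactors = FALSE)
  tab <- table(factor(category, levels = c("clean", DEFECT_CATEGORIES)))
  report <- filter_report(
    raw = n, clean = as.integer(tab["clean"]),
    low_quality = as.integer(tab["low_quality"]),
    high_n = as.integer(tab["high_n"]),
    five_prime_adapter = as.integer(tab["five_prime_adapter"]),
    no_three_prime_adapter = as.integer(tab["no_three_prime_adapter"]),
    poly_nt = as.integer(tab["poly_nt"]),
    length_out_of_range = as.integer(tab["length_out_of_range"]),
    q20_fraction = mean(q20), q30_fraction = mean(q30),
    gc_fraction = mean(gc)
  )
  list(clean = clean, report = report, category = category)
}
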