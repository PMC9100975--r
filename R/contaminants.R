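# Contaminant removal: ungapped end-to-end matching of short reads against
# rRNA/tRNA/organelle references, both strands, with a substitution budget.

#' Construct a reference sequence set
#'
#' @param name reference set label.
#' @param kind one of `rRNA`, `tRNA`, `organelle`, `genome`, `transcriptome`,
#'   `known_miRNA`.
#' @param sequences named `DNAStringSet` (or named character vector).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(name, kind, sequences) {
  kind <- match.arg(kind, c("rRNA", "tRNA", "organelle", "genome",
                            "transcriptome", "known_miRNA"))
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reference sequences must carry unique ids")
  }
  structure(list(name = name, kind = kind, sequences = sequences),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set '%s' (%s): %d sequences, %d nt total\n",
              x$name, x$kind, length(x$sequences),
              sum(Biostrings::width(x$sequences))))
  invisible(x)
}

#' Remove reads matching contaminant references
#'
#' A read is removed iff it aligns end-to-end (ungapped, substitutions
#' only) to a subsequence of any reference, on either strand, with at most
#' `max_mismatch` mismatches. A read is attributed to the first reference
#' set (in input order) that matches it.
#'
#' @param reads read data.frame (`id`, `seq`, ...) or character vector.
#' @param refs non-empty list of [reference_set()] objects.
#' @param max_mismatch substitution budget (default 1).
#' @return list with `kept`, `removed` (same type as input), and
#'   `counts` (named removals per reference kind).
#' @export
filter_contaminants <- function(reads, refs, max_mismatch = 1L) {
  if (length(refs) == 0) stop("reference set is empty; refusing to pass reads through unchecked")
  if (inherits(refs, "reference_set")) refs <- list(refs)
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)

  uniq <- unique(seqs)
  kinds <- vapply(refs, function(r) r$kind, character(1))
  hit_kind <- setNames(rep(NA_character_, length(uniq)), uniq)
  for (i in seq_along(uniq)) {
    s <- uniq[i]
    pats <- c(s, revcomp(s))
    for (r in seq_along(refs)) {
      found <- FALSE
      for (p in pats) {
        if (any(Biostrings::vcountPattern(p, refs[[r]]$sequences,
                                          max.mismatch = max_mismatch,
                                          fixed = TRUE) > 0)) {
          found <- TRUE
          break
        }
      }
      if (found) {
        hit_kind[i] <- kinds[r]
        break
      }
    }
  }
  removed_mask <- !is.na(hit_kind[seqs])
  counts <- table(factor(hit_kind[seqs][removed_mask], levels = unique(kinds)))
  keep_sub <- function(x, mask) if (is.data.frame(x)) x[mask, , drop = FALSE] else x[mask]
  list(
    kept = keep_sub(reads, !removed_mask),
    removed = keep_sub(reads, removed_mask),
    counts = setNames(as.integer(counts), names(counts))
  )
}
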