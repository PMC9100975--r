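# Hairpin duplex evaluation. A candidate mature sequence is aligned against
# the reverse complement of the opposite arm of its precursor window; the
# plant annotation criteria (duplex mismatch budget, loop-region budget, no
# large loop, mature length, canonical 2-nt 3' overhangs, precursor cap) are
# audited on that alignment.

# Substitution matrix for aligning the mature (pattern) against the reverse
# complement of the window (subject). Under that transformation a
# Watson-Crick pair becomes an identity; the two G:U wobbles become
# (pattern G, subject A) and (pattern T, subject C). The matrix is
# deliberately asymmetric: wobble is directional.
duplex_submat <- local({
  let <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(let, let))
  diag(m) <- 2
  m["N", "N"] <- -3
  m["G", "A"] <- 1
  m["T", "C"] <- 1
  m
})

#' Extract a candidate precursor window around a read stack
#'
#' Extends a stack of mapped reads upstream and downstream by `flank`
#' nucleotides (default 150 nt each side), clipped to the contig bounds.
#' Minus-strand windows are reverse-complemented so that the mature read is
#' in sense orientation within the returned sequence.
#'
#' @param stack a list or one-row data.frame with `seq_id`, `strand`,
#'   `start`, `end` (1-based, closed).
#' @param genome a named `DNAStringSet`.
#' @param flank extension on each side in nt.
#' @return list with `seq` (window sequence, sense orientation), `seq_id`,
#'   `strand`, `start`, `end` (window coordinates on the plus strand,
#'   1-based closed).
#' @export
extract_precursor_window <- function(stack, genome, flank = 150L) {
  seq_id <- as.character(stack$seq_id)
  if (!seq_id %in% names(genome)) {
    stop("stack contig '", seq_id, "' not found in genome")
  }
  contig_len <- Biostrings::nchar(genome[[seq_id]])
  w_start <- max(1L, as.integer(stack$start) - as.integer(flank))
  w_end <- min(contig_len, as.integer(stack$end) + as.integer(flank))
  s <- as.character(Biostrings::subseq(genome[[seq_id]], w_start, w_end))
  if (identical(as.character(stack$strand), "-")) s <- revcomp(s)
  list(seq = s, seq_id = seq_id, strand = as.character(stack$strand),
       start = w_start, end = w_end)
}

#' Evaluate a miRNA/miRNA* duplex within a precursor window
#'
#' Locates the mature sequence in the window, aligns it against the reverse
#' complement of the rest of the window (global in the mature, local in the
#' window) with a wobble-aware scoring scheme, and audits the plant miRNA
#' annotation criteria:
#' * at most `max_mismatch` total duplex mismatches (substitutions plus
#'   gapped positions),
#' * at most `max_loop_mismatch` of them at bulge/internal-loop (gapped)
#'   positions,
#' * no large loop: no single internal loop longer than `max_bulge` nt on
#'   one strand, and a distinct, non-overlapping star arm must exist,
#' * mature length within `mature_len_range`,
#' * star inferred with the canonical 2-nt 3' overhang, inside the window,
#' * trimmed precursor (mature through star, plus up to `precursor_flank` nt
#'   on each side) no longer than `max_precursor` nt.
#'
#' G:U wobbles count as paired.
#'
#' @param mature mature candidate sequence (sense orientation).
#' @param window precursor window sequence containing `mature`.
#' @param max_mismatch total duplex mismatch budget.
#' @param max_loop_mismatch budget for bulge/internal-loop positions.
#' @param max_bulge largest tolerated single internal loop (nt, one strand).
#' @param mature_len_range allowed mature length, inclusive.
#' @param max_precursor precursor length cap in nt.
#' @param precursor_flank flank added on each side of the duplex span.
#' @return an object of class `duplex_evaluation`: a list with `mature`,
#'   `star`, `total_mismatches`, `loop_region_mismatches`, `overhang_5p`,
#'   `overhang_3p`, `large_loop`, `passed`, `fail_reasons`, plus window-local
#'   1-based ranges `mature_range`, `star_range`, `precursor_range` and the
#'   `precursor` sequence.
#' @export
evaluate_duplex <- function(mature, window,
                            max_mismatch = 5L,
                            max_loop_mismatch = 3L,
                            max_bulge = 5L,
                            mature_len_range = c(20L, 24L),
                            max_precursor = 300L,
                            precursor_flank = 15L) {
  mature <- toupper(mature)
  window <- toupper(window)
  L <- nchar(window)
  m1 <- as.integer(regexpr(mature, window, fixed = TRUE))
  if (m1 < 0) stop("mature sequence not found in window")
  m2 <- m1 + nchar(mature) - 1L

  fail <- character(0)
  mlen <- nchar(mature)
  if (mlen < mature_len_range[1] || mlen > mature_len_range[2]) {
    fail <- c(fail, sprintf("mature length %d outside [%d,%d]",
                            mlen, mature_len_range[1], mature_len_range[2]))
  }

  rcw <- revcomp(window)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(mature), Biostrings::DNAString(rcw),
    type = "global-local", substitutionMatrix = duplex_submat,
    gapOpening = 4, gapExtension = 1
  )
  rs <- Biostrings::start(Biostrings::subject(aln))
  re <- Biostrings::end(Biostrings::subject(aln))
  # map the matched range in revcomp coordinates back onto the window
  a1 <- L - re + 1L
  a2 <- L - rs + 1L

  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  paired <- !gap & (pa == sa | (pa == "G" & sa == "A") | (pa == "T" & sa == "C"))
  subs <- sum(!gap & !paired)
  gapcols <- sum(gap)
  runs <- rle(gap)
  max_gap_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L

  total_mismatches <- subs + gapcols
  loop_mismatches <- gapcols

  large_loop <- FALSE
  if (max_gap_run > max_bulge) {
    large_loop <- TRUE
    fail <- c(fail, sprintf("internal loop of %d nt exceeds %d", max_gap_run, max_bulge))
  }
  # the star arm must be a distinct region of the hairpin, not the mature's
  # own footprint: overlap means no terminal loop could form
  if (a1 <= m2 && a2 >= m1) {
    large_loop <- TRUE
    fail <- c(fail, "no distinct star arm (opposite-arm match overlaps mature)")
  }

  if (total_mismatches > max_mismatch) {
    fail <- c(fail, sprintf("mismatches>%d", max_mismatch))
  }
  if (loop_mismatches > max_loop_mismatch) {
    fail <- c(fail, sprintf("loop-region mismatches>%d", max_loop_mismatch))
  }

  # canonical duplex: both strands carry 2-nt 3' overhangs, which in window
  # coordinates shifts the star arm 2 nt rightward of the paired region
  s1 <- a1 + 2L
  s2 <- a2 + 2L
  star <- NA_character_
  star_range <- c(NA_integer_, NA_integer_)
  if (s1 >= 1L && s2 <= L && !large_loop) {
    star <- substr(window, s1, s2)
    star_range <- c(s1, s2)
  } else if (!large_loop) {
    fail <- c(fail, "star arm (with 2-nt overhang) falls outside window")
  }

  precursor <- NA_character_
  prec_range <- c(NA_integer_, NA_integer_)
  if (!is.na(star)) {
    core1 <- min(m1, s1)
    core2 <- max(m2, s2)
    if (core2 - core1 + 1L > max_precursor) {
      fail <- c(fail, sprintf("precursor longer than %d nt", max_precursor))
    } else {
      fl <- precursor_flank
      repeat {
        p1 <- max(1L, core1 - fl)
        p2 <- min(L, core2 + fl)
        if (p2 - p1 + 1L <= max_precursor || fl == 0L) break
        fl <- fl - 1L
      }
      precursor <- substr(window, p1, p2)
      prec_range <- c(p1, p2)
    }
  }

  passed <- length(fail) == 0L
  structure(
    list(
      mature = mature, star = star,
      total_mismatches = as.integer(total_mismatches),
      loop_region_mismatches = as.integer(loop_mismatches),
      overhang_5p = 2L, overhang_3p = 2L,
      large_loop = large_loop, passed = passed, fail_reasons = fail,
      mature_range = c(m1, m2), star_range = star_range,
      precursor_range = prec_range, precursor = precursor
    ),
    class = "duplex_evaluation"
  )
}

#' @export
print.duplex_evaluation <- function(x, ...) {
  cat("miRNA/miRNA* duplex evaluation\n")
  cat("  mature:", x$mature, sprintf("(%d nt)", nchar(x$mature)), "\n")
  cat("  star:  ", if (is.na(x$star)) "<none>" else x$star, "\n")
  cat("  mismatches:", x$total_mismatches,
      sprintf("(loop region: %d)", x$loop_region_mismatches), "\n")
  cat("  large loop:", x$large_loop, "\n")
  cat("  passed:", x$passed, "\n")
  if (length(x$fail_reasons)) cat("  reasons:", paste(x$fail_reasons, collapse = "; "), "\n")
  invisible(x)
}
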