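# miRNA locus annotation: exhaustive read mapping, read-stack construction,
# precursor window extraction, duplex evaluation, low-count removal, and
# known/novel classification against a miRBase-like reference.

#' Map reads to a genome (exhaustive, desk scale)
#'
#' Reports every end-to-end placement of each unique read sequence with at
#' most `max_mismatch` substitutions, on either strand. Reads with more
#' than `max_hits` placements are discarded and tallied.
#'
#' @param reads data.frame with a `seq` column plus per-sample count columns
#'   (see [collapse_reads()]), or a character vector of sequences (counted
#'   once each in a single pseudo-sample `n`).
#' @param genome named `DNAStringSet`.
#' @param max_mismatch substitution budget (default 0).
#' @param max_hits multi-mapping cap (default 20).
#' @return data.frame of hits: `seq`, `seq_id`, `start`, `end` (1-based
#'   closed), `strand`, `mismatches`, plus the count columns; attribute
#'   `n_discarded_multimappers` counts sequences over the cap.
#' @export
map_reads <- function(reads, genome, max_mismatch = 0L, max_hits = 20L) {
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome")
  }
  if (!is.data.frame(reads)) {
    reads <- collapse_reads(list(n = data.frame(seq = as.character(reads),
                                                stringsAsFactors = FALSE)))
  }
  count_cols <- setdiff(names(reads), "seq")
  uniq <- unique(reads$seq)
  rows <- list()
  discarded <- 0L
  for (s in uniq) {
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") s else revcomp(s)
      m <- Biostrings::vmatchPattern(pat, genome, max.mismatch = max_mismatch,
                                     fixed = TRUE)
      for (ci in seq_along(genome)) {
        rng <- m[[ci]]
        if (length(rng) == 0) next
        mm <- if (max_mismatch == 0) {
          rep(0L, length(rng))
        } else {
          vapply(seq_along(rng), function(k) {
            sub <- as.character(Biostrings::subseq(genome[[ci]],
                                                   IRanges::start(rng)[k],
                                                   IRanges::end(rng)[k]))
            as.integer(hamming(pat, sub))
          }, integer(1))
        }
        hits[[length(hits) + 1L]] <- data.frame(
          seq = s, seq_id = names(genome)[ci],
          start = IRanges::start(rng), end = IRanges::end(rng),
          strand = strand, mismatches = mm, stringsAsFactors = FALSE
        )
      }
    }
    if (length(hits) == 0) next
    hits <- do.call(rbind, hits)
    if (nrow(hits) > max_hits) {
      discarded <- discarded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- hits
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(0), seq_id = character(0), start = integer(0),
               end = integer(0), strand = character(0), mismatches = integer(0),
               stringsAsFactors = FALSE)
  idx <- match(out$seq, reads$seq)
  for (cc in count_cols) out[[cc]] <- reads[[cc]][idx]
  attr(out, "n_discarded_multimappers") <- discarded
  out
}

#' Collapse per-sample clean reads into a unique-sequence count table
#'
#' @param sample_reads named list of read data.frames (column `seq`).
#' @return data.frame: `seq` plus one integer count column per sample.
#' @export
collapse_reads <- function(sample_reads) {
  stopifnot(length(sample_reads) > 0, !is.null(names(sample_reads)))
  uniq <- unique(unlist(lapply(sample_reads, function(d) d$seq), use.names = FALSE))
  out <- data.frame(seq = uniq, stringsAsFactors = FALSE)
  for (sm in names(sample_reads)) {
    tab <- table(sample_reads[[sm]]$seq)
    out[[sm]] <- as.integer(tab[uniq])
    out[[sm]][is.na(out[[sm]])] <- 0L
  }
  out
}

#' Merge alignment hits into read stacks
#'
#' Hits on the same contig and strand whose intervals overlap or lie within
#' 2 nt of each other merge into one stack. Per-sample counts are summed
#' over member reads (a multi-mapping read contributes its full counts to
#' every stack it hits); the representative is the most abundant member
#' sequence, ties broken lexicographically.
#'
#' @param hits data.frame from [map_reads()].
#' @return data.frame of stacks: `seq_id`, `strand`, `start`, `end`,
#'   `representative`, `rep_start`, `rep_end`, one count column per sample.
#' @export
build_stacks <- function(hits) {
  count_cols <- setdiff(names(hits),
                        c("seq", "seq_id", "start", "end", "strand", "mismatches"))
  if (nrow(hits) == 0) {
    out <- data.frame(seq_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      representative = character(0), rep_start = integer(0),
                      rep_end = integer(0), stringsAsFactors = FALSE)
    for (cc in count_cols) out[[cc]] <- integer(0)
    return(out)
  }
  gr <- GenomicRanges::GRanges(hits$seq_id,
                               IRanges::IRanges(hits$start, hits$end),
                               strand = hits$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 3L, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  stack_of <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]

  rows <- lapply(seq_along(red), function(k) {
    mem <- hits[stack_of == k, , drop = FALSE]
    # counts per unique member sequence (count once even if the same read
    # sequence has two placements inside one stack)
    umem <- mem[!duplicated(mem$seq), , drop = FALSE]
    totals <- rowSums(as.matrix(umem[, count_cols, drop = FALSE]))
    best <- order(-totals, umem$seq)[1]
    cnts <- colSums(as.matrix(umem[, count_cols, drop = FALSE]))
    out <- data.frame(
      seq_id = as.character(GenomicRanges::seqnames(red))[k],
      strand = as.character(GenomicRanges::strand(red))[k],
      start = GenomicRanges::start(red)[k], end = GenomicRanges::end(red)[k],
      representative = umem$seq[best],
      rep_start = umem$start[best], rep_end = umem$end[best],
      stringsAsFactors = FALSE
    )
    for (cc in count_cols) out[[cc]] <- as.integer(cnts[[cc]])
    out
  })
  do.call(rbind, rows)
}

#' Annotate miRNA loci from read stacks
#'
#' Each stack's representative read is treated as the candidate mature:
#' its precursor window (+/- `flank` nt) is extracted and the duplex
#' criteria audited by [evaluate_duplex()]. Stacks whose representative
#' falls outside 20-24 nt or whose duplex fails are dropped; loci below
#' `min_count` reads in every sample are removed; overlapping same-strand
#' loci are deduplicated keeping the higher-count one.
#'
#' @param stacks data.frame from [build_stacks()].
#' @param genome named `DNAStringSet`.
#' @param min_count a locus is kept only if some sample has at least this
#'   many reads (default 10).
#' @param reference optional known-miRNA `DNAStringSet` for
#'   [classify_known_novel()].
#' @param flank precursor window extension (default 150 nt).
#' @return data.frame of loci: `name`, `status`, `family`, `seq_id`,
#'   `strand`, precursor/mature genomic coordinates, `mature`, `star`,
#'   `precursor` sequences, per-sample counts; attribute `evaluations`
#'   holds the per-locus `duplex_evaluation` objects.
#' @export
annotate_loci <- function(stacks, genome, min_count = 10L, reference = NULL,
                          flank = 150L) {
  count_cols <- setdiff(names(stacks),
                        c("seq_id", "strand", "start", "end",
                          "representative", "rep_start", "rep_end"))
  empty <- function() {
    out <- data.frame(name = character(0), status = character(0),
                      family = character(0), seq_id = character(0),
                      strand = character(0), precursor_start = integer(0),
                      precursor_end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), star_start = integer(0),
                      star_end = integer(0), mature = character(0),
                      star = character(0), precursor = character(0),
                      stringsAsFactors = FALSE)
    for (cc in count_cols) out[[cc]] <- integer(0)
    attr(out, "evaluations") <- list()
    out
  }
  if (nrow(stacks) == 0) return(empty())

  rows <- list()
  evals <- list()
  for (k in seq_len(nrow(stacks))) {
    st <- stacks[k, ]
    rep_seq <- st$representative
    if (nchar(rep_seq) < 20 || nchar(rep_seq) > 24) next
    win <- extract_precursor_window(
      list(seq_id = st$seq_id, strand = st$strand,
           start = st$rep_start, end = st$rep_end),
      genome, flank = flank
    )
    ev <- tryCatch(evaluate_duplex(rep_seq, win$seq), error = function(e) NULL)
    if (is.null(ev) || !ev$passed) next
    # map window-local 1-based ranges back to plus-strand genomic coordinates
    to_genomic <- function(r) {
      if (win$strand == "+") c(win$start + r[1] - 1L, win$start + r[2] - 1L)
      else c(win$end - r[2] + 1L, win$end - r[1] + 1L)
    }
    pg <- to_genomic(ev$precursor_range)
    mg <- to_genomic(ev$mature_range)
    sg <- to_genomic(ev$star_range)
    row <- data.frame(
      name = NA_character_, status = "novel", family = NA_character_,
      seq_id = st$seq_id, strand = st$strand,
      precursor_start = pg[1], precursor_end = pg[2],
      mature_start = mg[1], mature_end = mg[2],
      star_start = sg[1], star_end = sg[2],
      mature = rep_seq, star = ev$star, precursor = ev$precursor,
      stringsAsFactors = FALSE
    )
    for (cc in count_cols) row[[cc]] <- st[[cc]]
    rows[[length(rows) + 1L]] <- row
    evals[[length(evals) + 1L]] <- ev
  }
  if (length(rows) == 0) return(empty())
  loci <- do.call(rbind, rows)

  # low-expression removal: below min_count in every sample
  if (length(count_cols)) {
    mx <- apply(as.matrix(loci[, count_cols, drop = FALSE]), 1, max)
    keep <- mx >= min_count
    loci <- loci[keep, , drop = FALSE]
    evals <- evals[keep]
  }
  if (nrow(loci) == 0) return(empty())

  # deduplicate overlapping same-strand loci, keeping the higher-count one
  totals <- if (length(count_cols)) {
    rowSums(as.matrix(loci[, count_cols, drop = FALSE]))
  } else rep(0, nrow(loci))
  gr <- GenomicRanges::GRanges(loci$seq_id,
                               IRanges::IRanges(loci$precursor_start,
                                                loci$precursor_end),
                               strand = loci$strand)
  ord <- order(-totals, loci$seq_id, loci$mature_start)
  keep <- logical(nrow(loci))
  taken <- GenomicRanges::GRanges()
  for (i in ord) {
    if (length(taken) == 0 ||
        !any(IRanges::overlapsAny(gr[i], taken))) {
      keep[i] <- TRUE
      taken <- c(taken, gr[i])
    }
  }
  loci <- loci[keep, , drop = FALSE]
  evals <- evals[keep]

  # genomic order, then classify and name
  ord <- order(loci$seq_id, loci$mature_start)
  loci <- loci[ord, , drop = FALSE]
  evals <- evals[ord]
  rownames(loci) <- NULL
  loci <- classify_known_novel(loci, reference)
  attr(loci, "evaluations") <- evals
  loci
}

# best ungapped comparison of two sequences differing by at most
# max_len_diff nt: slide the shorter along the longer, count substitutions
# (unaligned overhang positions count as differences)
best_offset_subs <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  best <- Inf
  for (off in 0:(lb - la)) {
    d <- hamming(a, substr(b, off + 1L, off + la)) + (lb - la)
    best <- min(best, d)
  }
  best
}

#' Classify loci as known or novel against a miRNA reference
#'
#' A locus is known iff some reference mature matches its mature with at
#' most `max_sub` substitutions and a length difference of at most
#' `max_len_diff` nt (best ungapped offset; overhanging positions count as
#' substitutions). Known loci take the family of the best match; novel loci
#' are named `miRN1`, `miRN2`, ... in genomic order.
#'
#' @param loci loci data.frame (from [annotate_loci()]).
#' @param reference named `DNAStringSet` of known matures; family labels
#'   are parsed from ids (e.g. `pde-miR166a` gives family `miR166`). `NULL`
#'   or empty makes every locus novel.
#' @param max_sub substitution tolerance (default 2).
#' @param max_len_diff length-difference tolerance (default 2).
#' @return `loci` with `status`, `family`, `name` filled in.
#' @export
classify_known_novel <- function(loci, reference = NULL, max_sub = 2L,
                                 max_len_diff = 2L) {
  if (nrow(loci) == 0) return(loci)
  n_novel <- 0L
  for (i in seq_len(nrow(loci))) {
    best <- Inf; best_ref <- NA_character_
    if (!is.null(reference) && length(reference) > 0) {
      for (r in seq_along(reference)) {
        rs <- as.character(reference[[r]])
        if (abs(nchar(rs) - nchar(loci$mature[i])) > max_len_diff) next
        d <- best_offset_subs(loci$mature[i], rs)
        if (d < best) { best <- d; best_ref <- names(reference)[r] }
      }
    }
    if (is.finite(best) && best <= max_sub) {
      loci$status[i] <- "known"
      fam <- regmatches(best_ref, regexpr("miR[0-9]+", best_ref))
      loci$family[i] <- if (length(fam)) fam else NA_character_
      loci$name[i] <- sub("^[a-z]{3}-", "", best_ref)
    } else {
      n_novel <- n_novel + 1L
      loci$status[i] <- "novel"
      loci$family[i] <- NA_character_
      loci$name[i] <- sprintf("miRN%d", n_novel)
    }
  }
  loci
}

#' Write annotated loci to GFF3
#'
#' One `miRNA_primary_transcript` feature per locus (the precursor span)
#' with child `miRNA` features for the mature and star sequences, named
#' with `-mature` / `-star` suffixes. Coordinates are 1-based closed.
#'
#' @param loci loci data.frame from [annotate_loci()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
export_loci_gff3 <- function(loci, path) {
  if (nrow(loci) == 0) {
    rtracklayer::export(GenomicRanges::GRanges(), path, format = "gff3")
    return(invisible(path))
  }
  gene <- GenomicRanges::GRanges(
    loci$seq_id,
    IRanges::IRanges(loci$precursor_start, loci$precursor_end),
    strand = loci$strand,
    type = "miRNA_primary_transcript",
    ID = paste0(loci$name, "-precursor"),
    Parent = NA_character_
  )
  mature <- GenomicRanges::GRanges(
    loci$seq_id,
    IRanges::IRanges(loci$mature_start, loci$mature_end),
    strand = loci$strand,
    type = "miRNA",
    ID = paste0(loci$name, "-mature"),
    Parent = paste0(loci$name, "-precursor")
  )
  star <- GenomicRanges::GRanges(
    loci$seq_id,
    IRanges::IRanges(loci$star_start, loci$star_end),
    strand = loci$strand,
    type = "miRNA",
    ID = paste0(loci$name, "-star"),
    Parent = paste0(loci$name, "-precursor")
  )
  gr <- c(gene, mature, star)
  gr$source <- "sylvamir"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
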