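# Degradome-guided target calling: tag placement, Allen-style
# complementarity scoring (penalties doubled in the seed-proximal region,
# G:U half-penalized), cleavage localization opposite miRNA positions
# 10-11, category 0-4 confidence classification, and a permutation null.

BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L, N = 5L)

# penalty for pairing miRNA base (row) against the transcript base it sits
# opposite (column): Watson-Crick 0, G:U wobble 0.5, otherwise 1 (N always 1)
PAIR_PENALTY <- local({
  m <- matrix(1, 5, 5, dimnames = list(c("A","C","G","T","N"), c("A","C","G","T","N")))
  m["A", "T"] <- 0; m["T", "A"] <- 0; m["C", "G"] <- 0; m["G", "C"] <- 0
  m["G", "T"] <- 0.5; m["T", "G"] <- 0.5
  m
})

mirna_multipliers <- function(L, core = c(2L, 13L)) {
  mult <- rep(1, L)
  mult[core[1]:min(core[2], L)] <- 2
  mult
}

#' Map degradome 5' tags onto transcripts
#'
#' Each tag is placed by exact match of its first 20 nt against the
#' transcript sense strand; a multi-placed tag contributes to every
#' placement. The tag's 5' end increments the per-position tag count.
#'
#' @param tags data.frame of tags (`seq` column) or character vector.
#' @param transcripts named `DNAStringSet`.
#' @param seed_len prefix length used for placement (default 20).
#' @return named list of `degradome_profile` objects (`transcript_id`,
#'   `length`, `tag5_counts`); attribute `n_unplaced` counts tags with no
#'   placement.
#' @export
map_tags <- function(tags, transcripts, seed_len = 20L) {
  if (length(transcripts) == 0) stop("empty transcriptome")
  seqs <- if (is.data.frame(tags)) tags$seq else as.character(tags)
  seqs <- seqs[nchar(seqs) >= seed_len]
  profiles <- lapply(seq_along(transcripts), function(i) {
    structure(list(transcript_id = names(transcripts)[i],
                   length = Biostrings::width(transcripts)[i],
                   tag5_counts = integer(Biostrings::width(transcripts)[i])),
              class = "degradome_profile")
  })
  names(profiles) <- names(transcripts)
  n_unplaced <- 0L
  if (length(seqs) > 0) {
    pre <- substr(seqs, 1, seed_len)
    tab <- table(pre)
    uniq <- names(tab)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq))
    placed <- logical(length(uniq))
    for (i in seq_along(transcripts)) {
      m <- Biostrings::matchPDict(pd, transcripts[[i]])
      starts <- IRanges::start(m)
      hit <- which(lengths(starts) > 0)
      for (u in hit) {
        placed[u] <- TRUE
        for (s in starts[[u]]) {
          profiles[[i]]$tag5_counts[s] <- profiles[[i]]$tag5_counts[s] +
            as.integer(tab[u])
        }
      }
    }
    n_unplaced <- sum(as.integer(tab[!placed]))
  }
  attr(profiles, "n_unplaced") <- n_unplaced
  profiles
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("degradome profile %s: %d nt, %d tags, max %d at position %d\n",
              x$transcript_id, x$length, sum(x$tag5_counts),
              if (sum(x$tag5_counts)) max(x$tag5_counts) else 0L,
              if (sum(x$tag5_counts)) which.max(x$tag5_counts) else NA_integer_))
  invisible(x)
}

#' Score miRNA:target-site complementarity
#'
#' Aligns the miRNA (5'->3') against the reverse complement of the site,
#' ungapped when lengths match, otherwise with a single gap absorbing the
#' length difference (up to 4 nt), placed wherever it minimizes the score.
#' Penalties per miRNA position: mismatch 1, G:U wobble 0.5, gap 1 per
#' gapped nt; penalties are doubled at miRNA positions 2-13 from the 5'
#' end. Lower scores mean better sites; ambiguous bases score as
#' mismatches.
#'
#' @param mirna miRNA sequence, 5'->3' (DNA alphabet; U accepted).
#' @param site target-site window on the transcript sense strand, length
#'   within +/- 4 nt of the miRNA.
#' @return list with `score` and `alignment` (data.frame `mirna_pos`,
#'   `site_pos`; NA site positions mark gapped miRNA bases).
#' @export
score_complementarity <- function(mirna, site) {
  mirna <- chartr("Uu", "Tt", toupper(mirna))
  site <- chartr("Uu", "Tt", toupper(site))
  L <- nchar(mirna)
  S <- nchar(site)
  if (abs(S - L) > 4) stop("site window length must be within 4 nt of the miRNA")
  mi <- BASE_IDX[strsplit(mirna, "")[[1]]]
  si <- BASE_IDX[strsplit(site, "")[[1]]]
  mi[is.na(mi)] <- 5L; si[is.na(si)] <- 5L
  mult <- mirna_multipliers(L)

  # ungapped core: miRNA position i pairs site position (S - i + 1) after an
  # optional single gap shifts one side
  score_pairing <- function(site_of_mirna) {
    # site_of_mirna: vector length L, NA = miRNA base sits in a gap
    pen <- numeric(L)
    gap <- is.na(site_of_mirna)
    pen[gap] <- 1
    pen[!gap] <- PAIR_PENALTY[cbind(mi[!gap], si[site_of_mirna[!gap]])]
    sum(pen * mult)
  }

  best <- Inf
  best_map <- NULL
  if (S == L) {
    m <- (S:1)
    sc <- score_pairing(m)
    best <- sc; best_map <- m
  } else if (S < L) {
    # miRNA bulge: (L - S) consecutive miRNA bases unpaired
    d <- L - S
    for (g in 1:(L - d + 1)) {
      m <- rep(NA_integer_, L)
      before <- seq_len(g - 1L)
      after <- if (g + d <= L) (g + d):L else integer(0)
      # site positions pair antiparallel around the gap
      m[before] <- S - before + 1L
      m[after] <- S - (after - d) + 1L
      sc <- score_pairing(m)
      if (sc < best) { best <- sc; best_map <- m }
    }
  } else {
    # transcript bulge: (S - L) site bases skipped between two miRNA bases;
    # the gap penalty lands on the 3'-adjacent miRNA position's multiplier
    d <- S - L
    for (g in 1:(L + 1)) {
      m <- integer(L)
      up <- seq_len(g - 1L)
      dn <- if (g <= L) g:L else integer(0)
      m[up] <- S - up + 1L
      m[dn] <- S - (dn + d) + 1L
      pen <- PAIR_PENALTY[cbind(mi, si[m])]
      gpos <- min(g, L)
      sc <- sum(pen * mult) + d * mult[gpos]
      if (sc < best) { best <- sc; best_map <- m }
    }
  }
  list(score = best,
       alignment = data.frame(mirna_pos = seq_len(L), site_pos = best_map))
}

#' Locate the cleavage position from a site alignment
#'
#' AGO-guided cleavage falls on the target opposite miRNA positions 10-11;
#' the degradome tag's 5' end sits at the base paired with position 10
#' (the first base of the downstream fragment).
#'
#' @param alignment data.frame with `mirna_pos` and transcript coordinates
#'   in `site_pos` (or `transcript_pos`).
#' @param site_start optional transcript coordinate of the site window's
#'   first base; when given, window-local `site_pos` values are shifted to
#'   transcript coordinates.
#' @return 1-based transcript coordinate of the cleavage-product 5' end.
#' @export
locate_cleavage <- function(alignment, site_start = NULL) {
  col <- if ("transcript_pos" %in% names(alignment)) "transcript_pos" else "site_pos"
  p10 <- alignment[[col]][alignment$mirna_pos == 10L]
  p11 <- alignment[[col]][alignment$mirna_pos == 11L]
  if (length(p10) != 1 || length(p11) != 1 || is.na(p10) || is.na(p11)) {
    stop("alignment gap at miRNA positions 10-11; site rejected")
  }
  pos <- p10
  if (!is.null(site_start)) pos <- site_start + pos - 1L
  as.integer(pos)
}

#' Classify a cleavage site's degradome support (category 0-4)
#'
#' With `c` the tag count at the site: a single tag is category 4; the
#' transcript's unique maximum is category 0; a tied maximum is category 1;
#' above the mean of nonzero positions is category 2; otherwise category 3.
#' A position with no tags is not called (`NA`).
#'
#' @param profile a `degradome_profile` (needs at least one tag).
#' @param pos 1-based transcript position.
#' @return integer category 0-4, or `NA` when `counts[pos] == 0`.
#' @export
categorize_site <- function(profile, pos) {
  counts <- if (inherits(profile, "degradome_profile")) profile$tag5_counts else profile
  if (pos < 1 || pos > length(counts)) stop("position outside transcript")
  if (sum(counts) < 1) stop("profile has no tags")
  c0 <- counts[pos]
  if (c0 == 0) return(NA_integer_)
  if (c0 == 1) return(4L)
  mx <- max(counts)
  if (c0 == mx) {
    if (sum(counts == mx) == 1) return(0L) else return(1L)
  }
  if (c0 > mean(counts[counts > 0])) return(2L)
  3L
}

# vectorized ungapped scan of a miRNA along a transcript: for each window
# start w, the miRNA pairs transcript[w .. w+L-1] antiparallel; returns the
# score at every start and the implied cleavage position (opposite miRNA
# position 10).
scan_transcript <- function(mirna, tx_chars_idx, mult = NULL) {
  L <- length(mirna)
  n <- length(tx_chars_idx)
  if (n < L) {
    return(data.frame(window_start = integer(0), score = numeric(0),
                      cleavage_pos = integer(0)))
  }
  if (is.null(mult)) mult <- mirna_multipliers(L)
  n_off <- n - L + 1L
  # miRNA position i pairs transcript position w + L - i
  offs <- seq_len(n_off)
  idx_mat <- outer(offs, L - seq_len(L), `+`)     # n_off x L transcript pos
  pen <- matrix(PAIR_PENALTY[cbind(rep(mirna, each = n_off),
                                   tx_chars_idx[as.vector(idx_mat)])],
                nrow = n_off)
  score <- as.numeric(pen %*% mult)
  data.frame(window_start = offs, score = score,
             cleavage_pos = offs + L - 10L)
}

tx_index <- function(seq) {
  i <- BASE_IDX[strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]]
  i[is.na(i)] <- 5L
  i
}

mirna_index <- function(seq) tx_index(seq)

#' Permutation p-value for a called target site
#'
#' Shuffles the miRNA sequence `R` times (uniform permutations); each
#' shuffle is scanned across the same transcript under the same score
#' cutoff and category rule, and its best site recorded. The p-value is
#' `(1 + #{shuffles at least as good}) / (R + 1)`, where "at least as good"
#' means category no larger and score no larger than observed.
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence (character or `DNAString`).
#' @param profile `degradome_profile` for the transcript.
#' @param observed list/row with `score` and `category` of the called site.
#' @param R number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param max_score score cutoff applied to shuffled sites (default 7).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(mirna, transcript, profile, observed,
                               R = 1000L, seed = 1L, max_score = 7.0) {
  if (R < 1) stop("R must be positive")
  set.seed(seed)
  txi <- tx_index(as.character(transcript))
  mi <- mirna_index(mirna)
  mult <- mirna_multipliers(length(mi))
  counts <- profile$tag5_counts
  obs_cat <- as.integer(observed$category)
  obs_score <- as.numeric(observed$score)
  hits <- 0L
  for (r in seq_len(R)) {
    sh <- sample(mi)
    sc <- scan_transcript(sh, txi, mult)
    ok <- sc$score <= max_score & sc$score <= obs_score &
      sc$cleavage_pos >= 1 & sc$cleavage_pos <= length(counts)
    if (!any(ok)) next
    cand <- sc[ok, , drop = FALSE]
    cand <- cand[counts[cand$cleavage_pos] > 0, , drop = FALSE]
    if (nrow(cand) == 0) next
    cats <- vapply(cand$cleavage_pos, function(p) {
      cat <- categorize_site(counts, p)
      if (is.na(cat)) 5L else cat
    }, integer(1))
    if (any(cats <= obs_cat)) hits <- hits + 1L
  }
  (1 + hits) / (R + 1)
}

#' Call miRNA cleavage targets from degradome profiles
#'
#' Scans every miRNA against every transcript (ungapped, seed-anchored
#' windows), keeps sites with complementarity score at most `max_score`,
#' degradome tag support at the predicted cleavage position, category at
#' most `max_category`, and permutation p-value at most `alpha`. The
#' result is sorted by (category, p-value).
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named `DNAStringSet`.
#' @param profiles list of `degradome_profile` from [map_tags()].
#' @param max_score Allen-style score cutoff (default 7.0).
#' @param max_category most permissive confidence category kept (default 2;
#'   categories 3-4 are conventionally unreliable).
#' @param alpha permutation p-value cutoff (default 0.05).
#' @param R permutation count (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return data.frame of `target_site` rows: `mirna_id`, `transcript_id`,
#'   `score`, `cleavage_pos`, `site_count`, `category`, `p_value`.
#' @export
call_targets <- function(mirnas, transcripts, profiles, max_score = 7.0,
                         max_category = 2L, alpha = 0.05, R = 1000L,
                         seed = 1L) {
  rows <- list()
  for (mi_name in names(mirnas)) {
    mirna <- mirnas[[mi_name]]
    miv <- mirna_index(mirna)
    mult <- mirna_multipliers(length(miv))
    for (tx_name in names(transcripts)) {
      prof <- profiles[[tx_name]]
      if (is.null(prof) || sum(prof$tag5_counts) == 0) next
      txi <- tx_index(as.character(transcripts[[tx_name]]))
      sc <- scan_transcript(miv, txi, mult)
      ok <- sc$score <= max_score & sc$cleavage_pos >= 1 &
        sc$cleavage_pos <= prof$length
      if (!any(ok)) next
      cand <- sc[ok, , drop = FALSE]
      cand <- cand[prof$tag5_counts[cand$cleavage_pos] > 0, , drop = FALSE]
      if (nrow(cand) == 0) next
      for (k in seq_len(nrow(cand))) {
        category <- categorize_site(prof, cand$cleavage_pos[k])
        if (is.na(category) || category > max_category) next
        p <- permutation_pvalue(
          mirna, as.character(transcripts[[tx_name]]), prof,
          list(score = cand$score[k], category = category),
          R = R, seed = seed + k, max_score = max_score
        )
        if (p > alpha) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mi_name, transcript_id = tx_name,
          score = cand$score[k], cleavage_pos = cand$cleavage_pos[k],
          site_count = prof$tag5_counts[cand$cleavage_pos[k]],
          category = category, p_value = p, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), transcript_id = character(0),
               score = numeric(0), cleavage_pos = integer(0),
               site_count = integer(0), category = integer(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  out[order(out$category, out$p_value, out$mirna_id, out$transcript_id), ,
      drop = FALSE]
}

#' Write a per-site text target plot
#'
#' Position-versus-count table for one transcript with the called cleavage
#' position marked.
#'
#' @param profile a `degradome_profile`.
#' @param cleavage_pos called cleavage position (optional).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_plot <- function(profile, cleavage_pos = NA_integer_, path) {
  df <- data.frame(position = seq_len(profile$length),
                   tag5_count = profile$tag5_counts,
                   at_cleavage = seq_len(profile$length) %in% cleavage_pos)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
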