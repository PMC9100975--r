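# Synthetic-data generator. Plants hairpin miRNA loci, per-sample negative
# binomial counts with known fold changes, small-RNA reads with adapter and
# defect classes, contaminant reads, target transcripts, and degradome tags
# concentrated at planted cleavage positions. Everything is seeded and
# byte-reproducible; planted loci are validated against the annotation
# criteria at generation time, and decoy stacks are rejection-sampled so
# they genuinely fail them.

DEFECT_CATEGORIES <- c("low_quality", "high_n", "five_prime_adapter",
                       "no_three_prime_adapter", "poly_nt",
                       "length_out_of_range")

#' Build and validate a simulation configuration
#'
#' Defaults encode the study conditions the pipeline models: 1 x 50 bp
#' small-RNA sequencing, three biological replicates per tissue (developing
#' xylem `X` vs phloem `P`), the standard small-RNA 3' adapter, defect-class
#' fractions patterned on the published library bookkeeping, and planted
#' fold changes straddling the |log2FC| > 1.5 differential-expression
#' threshold.
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   artifacts.
#' @param n_planted_loci number of planted hairpin loci.
#' @param n_decoy_stacks number of non-hairpin decoy read stacks.
#' @param genome_length genome length in nt (single contig).
#' @param read_length sequencing read length (nt).
#' @param adapter3 3' adapter sequence (>= 10 nt).
#' @param n_samples_per_group biological replicates per tissue group.
#' @param depth_per_sample approximate reads per library.
#' @param nb_dispersion negative binomial dispersion (>= 0; 0 = Poisson).
#' @param planted_fold_changes positive fold changes (group X over group P),
#'   recycled across planted loci.
#' @param defect_fractions named fractions for the six filter categories.
#' @param contaminant_fraction fraction of reads drawn from contaminant
#'   references.
#' @param degradome_signal_fraction fraction of a target transcript's tags
#'   placed exactly at the planted cleavage position.
#' @param n_transcripts number of simulated transcripts.
#' @param transcript_length transcript length in nt.
#' @param degradome_depth total degradome tags across the pooled library.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_planted_loci = 10L,
                              n_decoy_stacks = 20L,
                              genome_length = 50000L,
                              read_length = 50L,
                              adapter3 = "AGATCGGAAGAGCACACGTCT",
                              n_samples_per_group = 3L,
                              depth_per_sample = 5000L,
                              nb_dispersion = 0.1,
                              planted_fold_changes = c(1, 8, 1, 0.125, 6,
                                                       1, 0.2, 4, 1, 0.25),
                              defect_fractions = c(low_quality = 0.003,
                                                   high_n = 0.004,
                                                   five_prime_adapter = 0.0016,
                                                   no_three_prime_adapter = 0.017,
                                                   poly_nt = 0.0008,
                                                   length_out_of_range = 0.02),
                              contaminant_fraction = 0.05,
                              degradome_signal_fraction = 0.8,
                              n_transcripts = 30L,
                              transcript_length = 400L,
                              degradome_depth = 4000L) {
  adapter3 <- toupper(adapter3)
  if (nchar(adapter3) < 10) stop("adapter too short for inference fixture")
  if (!grepl("^[ACGT]+$", adapter3)) stop("adapter3 must be A/C/G/T")
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_planted_loci >= 0, n_decoy_stacks >= 0,
    genome_length > 0, read_length >= 30,
    n_samples_per_group >= 1, depth_per_sample >= 0,
    nb_dispersion >= 0,
    n_transcripts >= 1, transcript_length >= 150, degradome_depth >= 0
  )
  if (any(planted_fold_changes <= 0)) stop("fold changes must be positive")
  miss <- setdiff(DEFECT_CATEGORIES, names(defect_fractions))
  full <- setNames(numeric(length(DEFECT_CATEGORIES)), DEFECT_CATEGORIES)
  full[names(defect_fractions)] <- defect_fractions
  if (length(miss) == 0 && !all(names(defect_fractions) %in% DEFECT_CATEGORIES)) {
    stop("unknown defect category: ",
         paste(setdiff(names(defect_fractions), DEFECT_CATEGORIES), collapse = ", "))
  }
  if (any(full < 0 | full > 1) || contaminant_fraction < 0 || contaminant_fraction > 1) {
    stop("fractions must lie in [0,1]")
  }
  if (sum(full) >= 1) stop("defect fractions must sum to less than 1")
  if (sum(full) + contaminant_fraction >= 0.9) {
    stop("defect plus contaminant fractions leave too few clean reads")
  }
  if (degradome_signal_fraction < 0 || degradome_signal_fraction > 1) {
    stop("degradome_signal_fraction must lie in [0,1]")
  }
  structure(list(
    seed = as.integer(seed),
    n_planted_loci = as.integer(n_planted_loci),
    n_decoy_stacks = as.integer(n_decoy_stacks),
    genome_length = as.integer(genome_length),
    read_length = as.integer(read_length),
    adapter3 = adapter3,
    n_samples_per_group = as.integer(n_samples_per_group),
    depth_per_sample = as.integer(depth_per_sample),
    nb_dispersion = nb_dispersion,
    planted_fold_changes = planted_fold_changes,
    defect_fractions = full,
    contaminant_fraction = contaminant_fraction,
    degradome_signal_fraction = degradome_signal_fraction,
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    degradome_depth = as.integer(degradome_depth)
  ), class = "simulation_config")
}

sample_names <- function(config) {
  n <- config$n_samples_per_group
  c(paste0("X", seq_len(n)), paste0("P", seq_len(n)))
}

sample_groups <- function(config) {
  n <- config$n_samples_per_group
  factor(rep(c("X", "P"), each = n), levels = c("X", "P"))
}

# leftmost <=1-mismatch hit of the adapter seed must sit exactly where the
# adapter starts, otherwise trimming would truncate the insert wrongly
adapter_trim_safe <- function(insert, adapter3) {
  seed10 <- substr(adapter3, 1, 10)
  pos <- leftmost_seed_match(paste0(insert, adapter3), seed10, 1L)
  !is.na(pos) && pos == nchar(insert) + 1L
}

near_contaminant <- function(seq, contaminants, max_mismatch = 1L) {
  pats <- c(seq, revcomp(seq))
  for (ref in contaminants) {
    for (p in pats) {
      if (any(Biostrings::vcountPattern(p, ref$sequences,
                                        max.mismatch = max_mismatch,
                                        fixed = TRUE) > 0)) return(TRUE)
    }
  }
  FALSE
}

#' Simulate contaminant reference sets
#'
#' Random rRNA, tRNA, and organelle references used both to source
#' contaminant reads and to test decontamination.
#'
#' @param config a `simulation_config`.
#' @return list of [reference_set()] objects.
#' @export
simulate_contaminants <- function(config) {
  set.seed(config$seed + 6000L)
  list(
    reference_set("rRNA_ref", "rRNA",
                  setNames(Biostrings::DNAStringSet(random_dna(2, c(2000, 1500))),
                           c("rrna_28S", "rrna_18S"))),
    reference_set("tRNA_ref", "tRNA",
                  setNames(Biostrings::DNAStringSet(random_dna(1, 500)), "trna_pool")),
    reference_set("organelle_ref", "organelle",
                  setNames(Biostrings::DNAStringSet(random_dna(1, 1200)), "chloroplast_frag"))
  )
}

# draw one hairpin: mature arm, edited reverse-complement arm, 8-40 nt loop.
# Mature sits on a random arm. Returns list(hairpin, mature, mature_offset).
draw_hairpin <- function() {
  mlen <- sample(20:24, 1, prob = c(0.15, 0.5, 0.15, 0.1, 0.1))
  mature <- random_dna(1, mlen)
  n_edits <- sample(0:3, 1, prob = c(0.4, 0.3, 0.2, 0.1))
  arm <- strsplit(revcomp(mature), "")[[1]]
  if (n_edits > 0) {
    at <- sample(seq_along(arm), n_edits)
    for (i in at) arm[i] <- sample(setdiff(DNA_BASES, arm[i]), 1)
  }
  arm <- paste(arm, collapse = "")
  loop <- random_dna(1, sample(8:40, 1))
  mature_is_5p <- runif(1) < 0.5
  if (mature_is_5p) {
    list(hairpin = paste0(mature, loop, arm), mature = mature,
         mature_offset = 0L, n_edits = n_edits)
  } else {
    list(hairpin = paste0(arm, loop, mature), mature = mature,
         mature_offset = nchar(arm) + nchar(loop), n_edits = n_edits)
  }
}

#' Simulate a genome with planted hairpin loci and decoy stacks
#'
#' Embeds `n_planted_loci` hairpins (a random arm, its reverse complement
#' with a handful of substitutions, and an 8-40 nt loop) in an i.i.d.
#' random background, each on a random strand. Every planted locus is
#' validated against [evaluate_duplex()] at generation time; decoy stack
#' sequences are rejection-sampled so their precursor windows fail it.
#' Planted matures are checked for unique placement, safe adapter trimming,
#' and distance > 1 mismatch from the contaminant references.
#'
#' @param config a `simulation_config`.
#' @return list with `genome` (`DNAStringSet`, one contig `chr1`),
#'   `truth` (a `simulation_truth` list), and `contaminants`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_planted_loci
  G <- config$genome_length
  if (n * 400L > G) stop("genome too small")
  contaminants <- simulate_contaminants(config)
  set.seed(config$seed)

  genome <- random_dna(1, G)
  loci <- NULL
  used_seqs <- character(0)

  if (n > 0) {
    block <- G %/% n
    if (block < 500L) stop("genome too small")
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:50) {
        hp <- draw_hairpin()
        hlen <- nchar(hp$hairpin)
        lo <- (i - 1L) * block + 1L
        start <- lo + sample(200:(block - 200L - hlen), 1)
        strand <- sample(c("+", "-"), 1)
        piece <- if (strand == "+") hp$hairpin else revcomp(hp$hairpin)
        cand <- genome
        substr(cand, start, start + hlen - 1L) <- piece
        mlen <- nchar(hp$mature)
        if (strand == "+") {
          m_start <- start + hp$mature_offset
        } else {
          m_start <- start + hlen - hp$mature_offset - mlen
        }
        m_end <- m_start + mlen - 1L
        # uniqueness, adapter safety, contaminant distance
        gss <- Biostrings::DNAStringSet(cand)
        hits <- Biostrings::vcountPattern(hp$mature, gss, fixed = TRUE) +
          Biostrings::vcountPattern(revcomp(hp$mature), gss, fixed = TRUE)
        if (sum(hits) != 1L) next
        if (hp$mature %in% used_seqs) next
        if (!adapter_trim_safe(hp$mature, config$adapter3)) next
        if (near_contaminant(hp$mature, contaminants)) next
        win <- extract_precursor_window(
          list(seq_id = "chr1", strand = strand, start = m_start, end = m_end),
          setNames(gss, "chr1")
        )
        ev <- evaluate_duplex(hp$mature, win$seq)
        if (!ev$passed) next
        if (!adapter_trim_safe(ev$star, config$adapter3)) next
        genome <- cand
        used_seqs <- c(used_seqs, hp$mature, ev$star)
        rows[[i]] <- data.frame(
          name = sprintf("locus%02d", i), seq_id = "chr1", strand = strand,
          hairpin_start = start, hairpin_end = start + hlen - 1L,
          mature_start = m_start, mature_end = m_end,
          mature = hp$mature, star = ev$star, precursor = ev$precursor,
          n_edits = hp$n_edits, stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) stop("failed to place a valid hairpin locus (seed ", config$seed, ")")
    }
    loci <- do.call(rbind, rows)
  } else {
    loci <- data.frame(name = character(0), seq_id = character(0),
                       strand = character(0), hairpin_start = integer(0),
                       hairpin_end = integer(0), mature_start = integer(0),
                       mature_end = integer(0), mature = character(0),
                       star = character(0), precursor = character(0),
                       n_edits = integer(0), stringsAsFactors = FALSE)
  }

  genome_set <- setNames(Biostrings::DNAStringSet(genome), "chr1")

  # decoy stacks: real genomic substrings that do not form valid hairpins
  nd <- config$n_decoy_stacks
  decoys <- data.frame(name = character(0), seq_id = character(0),
                       strand = character(0), start = integer(0),
                       end = integer(0), seq = character(0),
                       mean_count = numeric(0), stringsAsFactors = FALSE)
  if (nd > 0) {
    taken <- IRanges::IRanges(start = loci$hairpin_start - 250L,
                              end = loci$hairpin_end + 250L)
    drows <- vector("list", nd)
    for (d in seq_len(nd)) {
      ok <- FALSE
      for (try in 1:200) {
        dlen <- sample(20:24, 1)
        start <- sample(200:(G - 200L - dlen), 1)
        cand_rng <- IRanges::IRanges(start, start + dlen - 1L)
        if (length(taken) && any(IRanges::overlapsAny(cand_rng, taken))) next
        strand <- sample(c("+", "-"), 1)
        plus_seq <- substr(genome, start, start + dlen - 1L)
        dseq <- if (strand == "+") plus_seq else revcomp(plus_seq)
        if (dseq %in% used_seqs) next
        gss <- genome_set
        hits <- Biostrings::vcountPattern(dseq, gss, fixed = TRUE) +
          Biostrings::vcountPattern(revcomp(dseq), gss, fixed = TRUE)
        if (sum(hits) != 1L) next
        if (!adapter_trim_safe(dseq, config$adapter3)) next
        if (near_contaminant(dseq, contaminants)) next
        win <- extract_precursor_window(
          list(seq_id = "chr1", strand = strand, start = start, end = start + dlen - 1L),
          genome_set
        )
        ev <- evaluate_duplex(dseq, win$seq)
        if (ev$passed) next  # must be a genuine non-hairpin
        used_seqs <- c(used_seqs, dseq)
        taken <- c(taken, IRanges::IRanges(start - 30L, start + dlen + 29L))
        drows[[d]] <- data.frame(
          name = sprintf("decoy%02d", d), seq_id = "chr1", strand = strand,
          start = start, end = start + dlen - 1L, seq = dseq,
          mean_count = exp(runif(1, log(20), log(150))),
          stringsAsFactors = FALSE
        )
        ok <- TRUE
        break
      }
      if (!ok) stop("failed to place decoy stack (seed ", config$seed, ")")
    }
    decoys <- do.call(rbind, drows)
  }

  truth <- structure(list(
    loci = loci, decoys = decoys, counts = NULL, true_log2fc = NULL,
    sites = NULL, config = config
  ), class = "simulation_truth")

  list(genome = genome_set, truth = truth, contaminants = contaminants)
}

#' Simulate a locus-by-sample count matrix with planted fold changes
#'
#' Counts are negative binomial; group `X` means differ from group `P`
#' means by the planted fold changes (recycled across loci). Per-locus base
#' means are drawn log-uniform in `[50, 500]` unless supplied.
#'
#' @param config a `simulation_config` (needs `n_samples_per_group >= 2`).
#' @param n_loci number of loci (default `config$n_planted_loci`).
#' @param base_means optional vector of group-P means.
#' @return list with `counts` (integer matrix, loci x samples), `true_log2fc`,
#'   and `groups` (factor `X`/`P`).
#' @export
simulate_counts <- function(config, n_loci = config$n_planted_loci,
                            base_means = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_samples_per_group < 2) stop("need at least 2 samples per group")
  if (any(config$planted_fold_changes <= 0)) stop("fold changes must be positive")
  set.seed(config$seed + 1000L)
  fc <- rep_len(config$planted_fold_changes, max(n_loci, 1L))[seq_len(n_loci)]
  if (is.null(base_means)) {
    base_means <- exp(runif(n_loci, log(50), log(500)))
  } else {
    base_means <- rep_len(base_means, n_loci)
  }
  samples <- sample_names(config)
  groups <- sample_groups(config)
  mu <- matrix(rep(base_means, length(samples)), nrow = n_loci,
               ncol = length(samples))
  mu[, groups == "X"] <- mu[, groups == "X"] * fc
  draw <- function(m) {
    if (config$nb_dispersion == 0) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
  }
  counts <- matrix(draw(mu), nrow = n_loci, ncol = length(samples),
                   dimnames = list(NULL, samples))
  storage.mode(counts) <- "integer"
  list(counts = counts, true_log2fc = log2(fc), groups = groups)
}

# quality-string generator: high-quality base distribution (Q20 fraction
# about 2%, Q30 about 95%, echoing the published per-library Q30 values)
sim_quals <- function(n, len) {
  if (n == 0) return(character(0))
  q <- sample(c(40L, 37L, 35L, 33L, 28L, 22L, 15L), n * len, replace = TRUE,
              prob = c(0.55, 0.15, 0.12, 0.10, 0.045, 0.02, 0.015))
  m <- matrix(q + 33L, nrow = len)
  vapply(seq_len(n), function(i) intToUtf8(m[, i]), character(1))
}

# assemble full-length reads: insert + adapter + random padding, clipped
finish_reads <- function(inserts, adapter3, read_length) {
  n <- length(inserts)
  if (n == 0) return(character(0))
  need <- pmax(0L, read_length - nchar(inserts) - nchar(adapter3))
  pads <- random_dna(n, pmax(need, 1L))
  pads[need == 0L] <- ""
  substr(paste0(inserts, adapter3, pads), 1, read_length)
}

rejection_random_insert <- function(n, len, adapter3) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- random_dna(1, len)
      if (adapter_trim_safe(s, adapter3)) { out[i] <- s; break }
    }
  }
  out
}

#' Simulate per-sample small-RNA FASTQ reads
#'
#' Each planted locus contributes exactly its true count of mature reads per
#' sample (plus 20% star reads); decoy stacks contribute negative binomial
#' counts with no group effect. Defect reads are injected per
#' `defect_fractions`, one mutually exclusive defect class per read, so the
#' QC report's category counts are exactly recoverable; contaminant reads
#' are exact substrings of the contaminant references.
#'
#' @param truth a `simulation_truth` from [simulate_genome()]; if it lacks
#'   counts, [simulate_counts()] is called.
#' @param config the `simulation_config`.
#' @param contaminants contaminant reference sets (default regenerated from
#'   the config).
#' @param outdir optional directory; per-sample FASTQ files are written there.
#' @return list with `samples` (named list of read data.frames), `truth`
#'   (counts attached), `defect_counts` (sample x category matrix),
#'   `contaminant_counts`, and `files` (if written).
#' @export
simulate_reads <- function(truth, config, contaminants = NULL, outdir = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (nchar(config$adapter3) < 10) stop("adapter too short for inference fixture")
  if (is.null(contaminants)) contaminants <- simulate_contaminants(config)
  if (is.null(truth$counts)) {
    cc <- simulate_counts(config)
    truth$counts <- cc$counts
    truth$true_log2fc <- cc$true_log2fc
  }
  set.seed(config$seed + 2000L)
  samples <- sample_names(config)
  ad <- config$adapter3
  rl <- config$read_length
  marker5 <- substr(revcomp(ad), nchar(ad) - 9L, nchar(ad))
  fr <- config$defect_fractions
  contam_seqs <- unlist(lapply(contaminants, function(r) as.character(r$sequences)))

  n_loci <- nrow(truth$loci)
  defect_counts <- matrix(0L, nrow = length(samples),
                          ncol = length(DEFECT_CATEGORIES),
                          dimnames = list(samples, DEFECT_CATEGORIES))
  contaminant_counts <- setNames(integer(length(samples)), samples)
  out <- setNames(vector("list", length(samples)), samples)

  for (j in seq_along(samples)) {
    sm <- samples[j]
    inserts <- character(0)
    if (config$depth_per_sample > 0) {
      if (n_loci > 0) {
        mat_n <- truth$counts[, sm]
        star_n <- floor(0.2 * mat_n)
        inserts <- c(rep(truth$loci$mature, mat_n), rep(truth$loci$star, star_n))
      }
      if (nrow(truth$decoys) > 0) {
        dk <- if (config$nb_dispersion == 0) {
          rpois(nrow(truth$decoys), truth$decoys$mean_count)
        } else {
          rnbinom(nrow(truth$decoys), mu = truth$decoys$mean_count,
                  size = 1 / config$nb_dispersion)
        }
        inserts <- c(inserts, rep(truth$decoys$seq, dk))
      }
      # rescale the clean pool toward the requested depth
      target_clean <- round(config$depth_per_sample *
                              (1 - sum(fr) - config$contaminant_fraction))
      if (length(inserts) > target_clean && target_clean > 0) {
        inserts <- inserts[sort(sample(seq_along(inserts), target_clean))]
      }
    }
    base_n <- length(inserts)
    seqs <- finish_reads(inserts, ad, rl)
    quals <- sim_quals(base_n, rl)

    total <- if (base_n > 0) round(base_n / (1 - sum(fr) - config$contaminant_fraction)) else 0L
    n_def <- setNames(as.integer(round(total * fr)), DEFECT_CATEGORIES)
    n_con <- as.integer(round(total * config$contaminant_fraction))
    if (config$depth_per_sample == 0) { n_def[] <- 0L; n_con <- 0L }

    # low quality: ordinary read, 40% of bases below Q20
    if (n_def["low_quality"] > 0) {
      k <- n_def["low_quality"]
      s <- finish_reads(rejection_random_insert(k, 21L, ad), ad, rl)
      q <- vapply(seq_len(k), function(i) {
        sc <- sample(c(38L, 36L), rl, replace = TRUE)
        low <- sample(rl, ceiling(0.4 * rl))
        sc[low] <- sample(5L:15L, length(low), replace = TRUE)
        intToUtf8(sc + 33L)
      }, character(1))
      seqs <- c(seqs, s); quals <- c(quals, q)
    }
    # high N: > 10% ambiguous bases
    if (n_def["high_n"] > 0) {
      k <- n_def["high_n"]
      s <- finish_reads(rejection_random_insert(k, 21L, ad), ad, rl)
      s <- vapply(seq_len(k), function(i) {
        ch <- strsplit(s[i], "")[[1]]
        ch[sample(rl, ceiling(0.16 * rl))] <- "N"
        paste(ch, collapse = "")
      }, character(1))
      seqs <- c(seqs, s); quals <- c(quals, sim_quals(k, rl))
    }
    # 5' adapter contamination: read begins with the detection marker
    if (n_def["five_prime_adapter"] > 0) {
      k <- n_def["five_prime_adapter"]
      s <- substr(paste0(marker5, finish_reads(rejection_random_insert(k, 21L, ad), ad, rl)), 1, rl)
      seqs <- c(seqs, s); quals <- c(quals, sim_quals(k, rl))
    }
    # no 3' adapter: full-length random read with no adapter seed hit
    if (n_def["no_three_prime_adapter"] > 0) {
      k <- n_def["no_three_prime_adapter"]
      seed10 <- substr(ad, 1, 10)
      s <- character(k)
      for (i in seq_len(k)) {
        repeat {
          cand <- random_dna(1, rl)
          if (is.na(leftmost_seed_match(cand, seed10, 1L))) { s[i] <- cand; break }
        }
      }
      seqs <- c(seqs, s); quals <- c(quals, sim_quals(k, rl))
    }
    # poly A/T/C/G: homopolymer insert
    if (n_def["poly_nt"] > 0) {
      k <- n_def["poly_nt"]
      s <- character(k)
      for (i in seq_len(k)) {
        repeat {
          b <- sample(DNA_BASES, 1)
          ins <- strrep(b, 21L)
          if (adapter_trim_safe(ins, ad)) { s[i] <- finish_reads(ins, ad, rl); break }
        }
      }
      seqs <- c(seqs, s); quals <- c(quals, sim_quals(k, rl))
    }
    # insert length outside the 18-30 nt small-RNA window
    if (n_def["length_out_of_range"] > 0) {
      k <- n_def["length_out_of_range"]
      lens <- sample(c(10:17, 31:38), k, replace = TRUE)
      s <- vapply(seq_len(k), function(i) {
        repeat {
          ins <- random_dna(1, lens[i])
          if (adapter_trim_safe(ins, ad)) return(finish_reads(ins, ad, rl))
        }
      }, character(1))
      seqs <- c(seqs, s); quals <- c(quals, sim_quals(k, rl))
    }
    # contaminant-derived reads (clean by QC standards, removed later)
    if (n_con > 0) {
      s <- vapply(seq_len(n_con), function(i) {
        repeat {
          src <- contam_seqs[sample(length(contam_seqs), 1)]
          ilen <- sample(20:24, 1)
          at <- sample(nchar(src) - ilen + 1L, 1)
          ins <- substr(src, at, at + ilen - 1L)
          if (adapter_trim_safe(ins, ad)) return(ins)
        }
      }, character(1))
      seqs <- c(seqs, finish_reads(s, ad, rl))
      quals <- c(quals, sim_quals(n_con, rl))
    }

    defect_counts[sm, ] <- n_def
    contaminant_counts[sm] <- n_con
    nn <- length(seqs)
    ord <- if (nn > 0) sample(nn) else integer(0)
    out[[sm]] <- data.frame(
      id = if (nn > 0) sprintf("%s_read%06d", sm, seq_len(nn)) else character(0),
      seq = seqs[ord], qual = quals[ord], stringsAsFactors = FALSE
    )
  }

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- setNames(file.path(outdir, paste0(samples, ".fastq")), samples)
    for (sm in samples) write_fastq(out[[sm]], files[[sm]])
  }
  list(samples = out, truth = truth, defect_counts = defect_counts,
       contaminant_counts = contaminant_counts, files = files)
}

#' Simulate target transcripts with planted miRNA cleavage sites
#'
#' Roughly half of the planted matures get one perfectly complementary
#' target site each, embedded in its own random transcript. The planted
#' cleavage position is the transcript base paired opposite miRNA position
#' 10 (the 5' end of the downstream cleavage fragment).
#'
#' @param truth a `simulation_truth` with planted loci.
#' @param config the `simulation_config`.
#' @return list with `transcripts` (`DNAStringSet`) and `sites` (data.frame
#'   `mirna`, `mature`, `transcript`, `site_start`, `cleavage_pos`,
#'   `signal_fraction`).
#' @export
simulate_transcripts <- function(truth, config) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(config$seed + 3000L)
  ntx <- config$n_transcripts
  tlen <- config$transcript_length
  txs <- random_dna(ntx, tlen)
  names(txs) <- sprintf("tx%03d", seq_len(ntx))
  n_loci <- nrow(truth$loci)
  n_sites <- min(ntx, if (n_loci > 0) max(1L, ceiling(n_loci / 2)) else 0L)
  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    mature <- truth$loci$mature[i]
    L <- nchar(mature)
    site <- revcomp(mature)
    t1 <- sample(30:(tlen - L - 40L), 1)
    substr(txs[i], t1, t1 + L - 1L) <- site
    rows[[i]] <- data.frame(
      mirna = truth$loci$name[i], mature = mature,
      transcript = names(txs)[i], site_start = t1,
      cleavage_pos = t1 + L - 10L,
      signal_fraction = config$degradome_signal_fraction,
      stringsAsFactors = FALSE
    )
  }
  sites <- if (n_sites > 0) do.call(rbind, rows) else
    data.frame(mirna = character(0), mature = character(0),
               transcript = character(0), site_start = integer(0),
               cleavage_pos = integer(0), signal_fraction = numeric(0))
  list(transcripts = Biostrings::DNAStringSet(txs), sites = sites)
}

#' Simulate a pooled degradome 5'-tag library
#'
#' For each transcript carrying a planted site, `signal_fraction` of its
#' tags start exactly at the planted cleavage position; the remainder (and
#' all tags of siteless transcripts) start at uniform random positions.
#' The library is a single pool, as when tissues are mixed in equal amounts
#' before sequencing.
#'
#' @param truth a `simulation_truth` whose `sites` field is populated (or
#'   pass `sites`).
#' @param transcripts named `DNAStringSet` of transcripts.
#' @param config the `simulation_config`.
#' @param sites optional sites data.frame overriding `truth$sites`.
#' @return data.frame of tags with columns `id`, `seq`, `qual`.
#' @export
simulate_degradome <- function(truth, transcripts, config, sites = NULL) {
  if (is.null(sites)) sites <- truth$sites
  if (is.null(sites)) sites <- data.frame(transcript = character(0), cleavage_pos = integer(0))
  set.seed(config$seed + 4000L)
  tx_names <- names(transcripts)
  if (nrow(sites) > 0) {
    bad <- !(sites$transcript %in% tx_names)
    if (any(bad)) stop("planted site references unknown transcript: ",
                       paste(sites$transcript[bad], collapse = ", "))
    lens <- Biostrings::width(transcripts)[match(sites$transcript, tx_names)]
    if (any(sites$cleavage_pos < 1 | sites$cleavage_pos > lens)) {
      stop("cleavage position outside transcript")
    }
  }
  ntx <- length(transcripts)
  per_tx <- if (ntx > 0) config$degradome_depth %/% ntx else 0L
  ids <- seqs <- character(0)
  for (i in seq_len(ntx)) {
    txn <- tx_names[i]
    txs <- as.character(transcripts[[i]])
    L <- nchar(txs)
    if (per_tx == 0L || L < 40L) next
    site <- sites[sites$transcript == txn, , drop = FALSE]
    n_sig <- if (nrow(site) > 0) round(per_tx * site$signal_fraction[1]) else 0L
    pos <- c(rep(if (nrow(site) > 0) site$cleavage_pos[1] else 1L, n_sig),
             sample(seq_len(L - 19L), per_tx - n_sig, replace = TRUE))
    tag <- substr(rep(txs, length(pos)), pos, pmin(pos + config$read_length - 1L, L))
    ids <- c(ids, sprintf("%s_tag%05d", txn, seq_along(pos)))
    seqs <- c(seqs, tag)
  }
  n <- length(seqs)
  ord <- if (n > 0) sample(n) else integer(0)
  data.frame(id = if (n > 0) sprintf("deg_tag%06d", seq_len(n)) else character(0),
             seq = seqs[ord],
             qual = if (n > 0) strrep("I", nchar(seqs[ord])) else character(0),
             stringsAsFactors = FALSE)
}

#' Simulate a known-miRNA reference with family labels
#'
#' About 70% of planted matures are copied into the reference under
#' family-labelled names (e.g. `pde-miR166a`); the rest remain novel. A few
#' unrelated decoy entries exercise the mismatch logic of
#' [classify_known_novel()].
#'
#' @param truth a `simulation_truth`.
#' @param config the `simulation_config`.
#' @return list with `reference` (named `DNAStringSet`) and `truth` with
#'   `loci$status` / `loci$family` filled in.
#' @export
simulate_known_reference <- function(truth, config) {
  set.seed(config$seed + 5000L)
  fams <- c("miR156", "miR159", "miR160", "miR164", "miR166", "miR167",
            "miR171", "miR319", "miR394", "miR395", "miR396", "miR477")
  n <- nrow(truth$loci)
  status <- rep("novel", n)
  family <- rep(NA_character_, n)
  ref_names <- character(0)
  ref_seqs <- character(0)
  if (n > 0) {
    k <- round(0.7 * n)
    known_idx <- sort(sample(n, k))
    for (ii in seq_along(known_idx)) {
      i <- known_idx[ii]
      fam <- fams[(ii - 1L) %% length(fams) + 1L]
      nm <- sprintf("pde-%s%s", fam, letters[(ii - 1L) %/% length(fams) + 1L])
      status[i] <- "known"
      family[i] <- fam
      ref_names <- c(ref_names, nm)
      ref_seqs <- c(ref_seqs, truth$loci$mature[i])
    }
  }
  # unrelated reference entries, far from every planted mature
  extra <- random_dna(5, 21)
  ref_names <- c(ref_names, sprintf("ath-miR9%02da", 1:5))
  ref_seqs <- c(ref_seqs, extra)
  truth$loci$status <- status
  truth$loci$family <- family
  list(reference = setNames(Biostrings::DNAStringSet(ref_seqs), ref_names),
       truth = truth)
}

#' Simulate a term-to-gene annotation map
#'
#' One term collects the transcripts carrying planted cleavage sites (an
#' enrichment the pipeline should detect); the remaining terms are random
#' transcript subsets.
#'
#' @param transcripts named `DNAStringSet`.
#' @param sites planted-site data.frame (from [simulate_transcripts()]).
#' @param config the `simulation_config`.
#' @param n_terms number of annotation terms.
#' @return data.frame with columns `term`, `gene`.
#' @export
simulate_term_map <- function(transcripts, sites, config, n_terms = 6L) {
  set.seed(config$seed + 7000L)
  genes <- names(transcripts)
  rows <- list()
  target_genes <- unique(sites$transcript)
  if (length(target_genes) > 0) {
    members <- unique(c(target_genes, sample(genes, min(2L, length(genes)))))
    rows[[1]] <- data.frame(term = "T001", gene = members, stringsAsFactors = FALSE)
  }
  for (t in seq(length(rows) + 1L, n_terms)) {
    members <- sample(genes, max(3L, rbinom(1, length(genes), 0.25)))
    rows[[t]] <- data.frame(term = sprintf("T%03d", t), gene = members,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
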