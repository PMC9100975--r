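# Degradome tag mapping, complementarity scoring, cleavage localization,
# category classification, and the permutation null.

test_that("tags place by exact 20-nt prefix match and tally their 5' ends", {
  set.seed(61)
  tx <- setNames(Biostrings::DNAStringSet(random_dna(2, 300)), c("t1", "t2"))
  tag <- substr(as.character(tx[["t1"]]), 100, 149)
  absent <- random_dna(1, 50)
  profiles <- map_tags(c(tag, tag, absent), tx)
  expect_equal(profiles[["t1"]]$tag5_counts[100], 2L)
  expect_equal(sum(profiles[["t1"]]$tag5_counts), 2L)
  expect_equal(sum(profiles[["t2"]]$tag5_counts), 0L)
  expect_equal(attr(profiles, "n_unplaced"), 1L)
  expect_error(map_tags(tag, Biostrings::DNAStringSet()), "empty transcriptome")
})

test_that("complementarity scoring follows the position-weighted penalty scheme", {
  mirna <- "ACGTACGGTTCAGCTAAGCTA"          # 21 nt
  site <- oracle_revcomp(mirna)
  expect_equal(score_complementarity(mirna, site)$score, 0)

  # G:U wobble at miRNA position 5 (inside 2-13): 0.5 x 2 = 1.0
  # miRNA pos 5 is A in the base sequence; use a mirna with G at pos 5
  m2 <- "ACGTGCGGTTCAGCTAAGCTA"
  s2 <- oracle_revcomp(m2)
  # pairing partner of miRNA position 5 is site position L - 5 + 1 = 17;
  # G pairs C; change it to T for a G:U wobble
  substr(s2, 17, 17) <- "T"
  expect_equal(score_complementarity(m2, s2)$score, 1.0)

  # plain mismatch at miRNA position 20 (outside 2-13): 1.0, undoubled
  s3 <- oracle_revcomp(mirna)
  # partner of position 20 is site position 2; mirna[20] is T; make site A -> G
  stopifnot(substr(mirna, 20, 20) == "T")
  substr(s3, 2, 2) <- "G"   # T:G is a wobble -> 0.5; use C instead for mismatch
  expect_equal(score_complementarity(mirna, s3)$score, 0.5)
  s4 <- oracle_revcomp(mirna)
  substr(s4, 2, 2) <- "C"
  expect_equal(score_complementarity(mirna, s4)$score, 1.0)

  # same mismatch inside the core doubles: partner of position 5 is pos 17
  s5 <- oracle_revcomp(mirna)
  substr(s5, 17, 17) <- "A"  # mirna[5]=A vs A: mismatch
  expect_equal(score_complementarity(mirna, s5)$score, 2.0)

  # a single-nt transcript bulge costs one gap penalty
  s6 <- paste0(substr(site, 1, 10), "A", substr(site, 11, 21))
  expect_lte(score_complementarity(mirna, s6)$score, 2.0)
  expect_gte(score_complementarity(mirna, s6)$score, 1.0)

  expect_error(score_complementarity(mirna, paste0(site, "ACGTAC")), "within 4")
})

test_that("cleavage localizes opposite miRNA position 10 and shifts antiparallel", {
  aln <- data.frame(mirna_pos = 1:21, site_pos = 21:1)
  expect_equal(locate_cleavage(aln), 12L)         # 21 - 10 + 1
  expect_equal(locate_cleavage(aln, site_start = 100), 111L)

  shifted <- data.frame(mirna_pos = 1:21, site_pos = 22:2)
  expect_equal(locate_cleavage(shifted), 13L)

  gap <- aln
  gap$site_pos[10] <- NA
  expect_error(locate_cleavage(gap), "positions 10-11")

  # a window scan shifted +1 along the transcript moves the cleavage +1,
  # i.e. -1 in the antiparallel miRNA-anchored frame
  set.seed(62)
  tx <- random_dna(1, 100)
  m <- random_dna(1, 21)
  sc <- sylvamir:::scan_transcript(sylvamir:::mirna_index(m),
                                   sylvamir:::tx_index(tx))
  expect_equal(diff(sc$cleavage_pos[1:2]), 1L)
  expect_equal(sc$cleavage_pos[1], 1 + 21 - 10)
})

test_that("site categories match the published five-tier definition", {
  expect_equal(categorize_site(c(9, 2, 1, 1), 1), 0L)
  expect_equal(categorize_site(c(5, 5, 1), 1), 1L)
  prof <- c(5, 3, 3, 2, 1)           # mean of nonzero = 2.8
  expect_equal(categorize_site(prof, 2), 2L)
  expect_equal(categorize_site(prof, 4), 3L)
  expect_equal(categorize_site(prof, 5), 4L)
  expect_true(is.na(categorize_site(c(2, 0, 5), 2)))
  expect_error(categorize_site(c(1, 2), 3), "outside")
  expect_error(categorize_site(c(0, 0), 1), "no tags")
})

test_that("categories agree with brute-force enumeration and are monotone", {
  # all profiles of length <= 4 with counts in 0..3 here (the full
  # length-6 sweep runs in the acceptance suite)
  for (len in 2:4) {
    grid <- as.matrix(expand.grid(rep(list(0:3), len)))
    for (g in seq_len(nrow(grid))) {
      counts <- grid[g, ]
      if (sum(counts) == 0) next
      for (pos in seq_len(len)) {
        expect_identical(categorize_site(counts, pos),
                         oracle_categorize(counts, pos))
      }
      # monotonicity: raising counts[pos] never increases the category
      for (pos in seq_len(len)) {
        if (counts[pos] == 0) next
        bumped <- counts
        bumped[pos] <- bumped[pos] + 1L
        expect_lte(categorize_site(bumped, pos), categorize_site(counts, pos))
      }
    }
  }
})

test_that("the permutation p-value is deterministic, bounded, and small for planted sites", {
  set.seed(63)
  m <- random_dna(1, 21)
  tx <- paste0(random_dna(1, 80), oracle_revcomp(m), random_dna(1, 80))
  cleave <- 80 + 21 - 10 + 1   # site starts at 81
  counts <- integer(nchar(tx))
  counts[cleave] <- 50L
  counts[sample(setdiff(seq_len(nchar(tx) - 19), cleave), 10)] <- 1L
  prof <- structure(list(transcript_id = "t", length = nchar(tx),
                         tag5_counts = counts), class = "degradome_profile")

  obs <- list(score = 0, category = categorize_site(prof, cleave))
  expect_equal(obs$category, 0L)
  p1 <- permutation_pvalue(m, tx, prof, obs, R = 100, seed = 3)
  expect_equal(p1, permutation_pvalue(m, tx, prof, obs, R = 100, seed = 3))
  expect_lte(p1, 0.02)

  # an observation weaker than anything keeps p at its upper bound only
  # when every shuffle beats it; with an impossible negative score no
  # shuffle can match, so p is the floor
  worst <- list(score = -1, category = 0L)
  expect_equal(permutation_pvalue(m, tx, prof, worst, R = 50, seed = 3),
               1 / 51)
  # conversely an infinitely weak observation is beaten by every shuffle
  loose <- list(score = Inf, category = 4L)
  expect_equal(permutation_pvalue(m, tx, prof, loose, R = 50, seed = 3,
                                  max_score = Inf), 1)
  expect_error(permutation_pvalue(m, tx, prof, obs, R = 0), "positive")
})

test_that("target calling recovers exactly the planted sites", {
  sc <- get_scenario()
  txr <- simulate_transcripts(sc$truth, sc$cfg)
  truth <- sc$truth
  truth$sites <- txr$sites
  tags <- simulate_degradome(truth, txr$transcripts, sc$cfg)
  profiles <- map_tags(tags, txr$transcripts)

  mirnas <- setNames(sc$truth$loci$mature, sc$truth$loci$name)
  called <- call_targets(mirnas, txr$transcripts, profiles, R = 200, seed = 5)

  expect_equal(nrow(called), nrow(txr$sites))
  key <- function(d, m, t, p) paste(m, t, p)
  expect_setequal(key(NULL, called$mirna_id, called$transcript_id, called$cleavage_pos),
                  key(NULL, txr$sites$mirna, txr$sites$transcript, txr$sites$cleavage_pos))
  expect_true(all(called$category <= 2))
  expect_true(all(called$p_value <= 0.05))

  # relaxing the category filter can only grow the call set
  loose <- call_targets(mirnas, txr$transcripts, profiles, R = 200, seed = 5,
                        max_category = 4L)
  expect_gte(nrow(loose), nrow(called))

  # empty degradome: nothing called
  empty_prof <- map_tags(character(0), txr$transcripts)
  expect_equal(nrow(call_targets(mirnas, txr$transcripts, empty_prof)), 0)
})
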