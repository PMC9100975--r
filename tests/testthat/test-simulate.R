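# Synthetic-data generator: config validation, determinism, planted-locus
# validity, and the statistical properties of the count model.

test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(adapter3 = "ACGTACG"), "adapter too short")
  expect_error(simulation_config(planted_fold_changes = c(2, -1)), "positive")
  expect_error(simulation_config(defect_fractions = c(low_quality = 1.2)), "\\[0,1\\]")
  expect_error(simulation_config(contaminant_fraction = 2), "\\[0,1\\]")
  expect_error(simulation_config(defect_fractions = c(low_quality = 0.5,
                                                      high_n = 0.6)),
               "sum")
  expect_error(simulation_config(n_planted_loci = 200,
                                 genome_length = 10000) |>
                 simulate_genome(), "genome too small")
})

test_that("genome simulation is deterministic and empty when asked", {
  cfg <- simulation_config(seed = 7, n_planted_loci = 2, n_decoy_stacks = 2,
                           genome_length = 5000, depth_per_sample = 200)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$loci, g2$truth$loci)

  cfg0 <- simulation_config(seed = 3, n_planted_loci = 0, n_decoy_stacks = 0,
                            genome_length = 3000, depth_per_sample = 0)
  g0 <- simulate_genome(cfg0)
  expect_equal(nrow(g0$truth$loci), 0)
  expect_equal(sum(Biostrings::width(g0$genome)), 3000)
})

test_that("every planted locus satisfies the annotation criteria at generation time", {
  sc <- get_scenario()
  tr <- sc$truth$loci
  expect_equal(nrow(tr), sc$cfg$n_planted_loci)
  for (i in seq_len(nrow(tr))) {
    win <- extract_precursor_window(
      list(seq_id = tr$seq_id[i], strand = tr$strand[i],
           start = tr$mature_start[i], end = tr$mature_end[i]),
      sc$genome)
    ev <- evaluate_duplex(tr$mature[i], win$seq)
    expect_true(ev$passed, info = tr$name[i])
    expect_lte(nchar(ev$precursor), 300)
    expect_true(nchar(tr$mature[i]) >= 20 && nchar(tr$mature[i]) <= 24)
  }
  # decoys are genuine non-hairpins
  dc <- sc$truth$decoys
  for (i in seq_len(nrow(dc))) {
    win <- extract_precursor_window(
      list(seq_id = dc$seq_id[i], strand = dc$strand[i],
           start = dc$start[i], end = dc$end[i]), sc$genome)
    expect_false(evaluate_duplex(dc$seq[i], win$seq)$passed, info = dc$name[i])
  }
})

test_that("count simulation matches its negative binomial contract", {
  cfg <- simulation_config(seed = 5, n_samples_per_group = 2,
                           planted_fold_changes = 1, nb_dispersion = 0.1)
  cc <- simulate_counts(cfg, n_loci = 6)
  expect_true(all(cc$true_log2fc == 0))
  expect_identical(cc$counts, simulate_counts(cfg, n_loci = 6)$counts)

  # Monte-Carlo: mean within 5% of target, and overdispersed
  big <- simulation_config(seed = 9, n_samples_per_group = 5000,
                           planted_fold_changes = 1, nb_dispersion = 0.1)
  draws <- simulate_counts(big, n_loci = 1, base_means = 100)$counts
  expect_lt(abs(mean(draws) - 100) / 100, 0.05)
  expect_gt(var(as.numeric(draws)), mean(draws))

  expect_error(simulate_counts(simulation_config(n_samples_per_group = 1)),
               "at least 2")
})

test_that("read simulation is deterministic, respects depth zero, and plants exact counts", {
  cfg <- simulation_config(seed = 11, n_planted_loci = 3, n_decoy_stacks = 0,
                           genome_length = 8000, depth_per_sample = 2000,
                           n_samples_per_group = 2,
                           defect_fractions = c(low_quality = 0),
                           contaminant_fraction = 0)
  gen <- simulate_genome(cfg)
  truth <- gen$truth
  truth$counts <- matrix(100L, nrow = 3, ncol = 4,
                         dimnames = list(NULL, c("X1", "X2", "P1", "P2")))
  r1 <- simulate_reads(truth, cfg, gen$contaminants)
  r2 <- simulate_reads(truth, cfg, gen$contaminants)
  expect_identical(r1$samples, r2$samples)
  expect_true(all(r1$defect_counts == 0))

  # clean input: only planted mature/star reads, all clean after filtering
  fr <- filter_reads(r1$samples$X1, cfg$adapter3)
  expect_equal(fr$report$clean, fr$report$raw)

  # planted count 100 recovered exactly as a mapped stack count
  kept <- filter_contaminants(collapse_reads(list(X1 = fr$clean)),
                              gen$contaminants)$kept
  hits <- map_reads(kept, gen$genome)
  stacks <- build_stacks(hits)
  m1 <- truth$loci$mature[1]
  stack_count <- stacks$X1[stacks$representative == m1]
  expect_equal(stack_count, 100L)

  cfg0 <- simulation_config(seed = 2, n_planted_loci = 0, n_decoy_stacks = 0,
                            genome_length = 2000, depth_per_sample = 0)
  gen0 <- simulate_genome(cfg0)
  r0 <- simulate_reads(gen0$truth, cfg0, gen0$contaminants)
  expect_true(all(vapply(r0$samples, nrow, integer(1)) == 0))
})

test_that("degradome simulation concentrates tags at planted cleavage sites", {
  sc <- get_scenario()
  txr <- simulate_transcripts(sc$truth, sc$cfg)
  truth <- sc$truth
  truth$sites <- txr$sites
  tags <- simulate_degradome(truth, txr$transcripts, sc$cfg)
  expect_identical(tags, simulate_degradome(truth, txr$transcripts, sc$cfg))

  profiles <- map_tags(tags, txr$transcripts)
  for (i in seq_len(nrow(txr$sites))) {
    prof <- profiles[[txr$sites$transcript[i]]]
    expect_equal(which.max(prof$tag5_counts), txr$sites$cleavage_pos[i])
    expect_equal(categorize_site(prof, txr$sites$cleavage_pos[i]), 0L)
  }

  # no planted sites: uniform background only, no dominant singleton peak
  truth0 <- truth
  truth0$sites <- txr$sites[0, ]
  tags0 <- simulate_degradome(truth0, txr$transcripts, sc$cfg)
  prof0 <- map_tags(tags0, txr$transcripts)
  frac_max <- max(vapply(prof0, function(p) {
    if (sum(p$tag5_counts) == 0) 0 else max(p$tag5_counts) / sum(p$tag5_counts)
  }, numeric(1)))
  expect_lt(frac_max, sc$cfg$degradome_signal_fraction)

  bad <- txr$sites
  bad$cleavage_pos[1] <- 10000L
  expect_error(simulate_degradome(truth, txr$transcripts, sc$cfg, sites = bad),
               "outside transcript")
})
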