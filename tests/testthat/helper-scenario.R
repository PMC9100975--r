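# Shared synthetic scenario, built once per test run and reused across
# test files (generation takes a few seconds).

.scenario_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, n_planted_loci = 8L, n_decoy_stacks = 15L,
                    genome_length = 40000L, depth_per_sample = 4000L, ...)
}

# genome + truth + reads + per-sample clean reads + collapsed counts
get_scenario <- function() {
  if (is.null(.scenario_cache$sc)) {
    cfg <- small_config()
    gen <- simulate_genome(cfg)
    reads <- simulate_reads(gen$truth, cfg, gen$contaminants)
    clean <- lapply(reads$samples, function(d) filter_reads(d, cfg$adapter3)$clean)
    collapsed <- collapse_reads(clean)
    kept <- filter_contaminants(collapsed, gen$contaminants)$kept
    .scenario_cache$sc <- list(cfg = cfg, genome = gen$genome,
                               truth = reads$truth,
                               contaminants = gen$contaminants,
                               reads = reads, clean = clean,
                               collapsed = collapsed, kept = kept)
  }
  .scenario_cache$sc
}

# one full pipeline run (cached); used by pipeline and acceptance tests
get_pipeline_run <- function() {
  if (is.null(.scenario_cache$run)) {
    outdir <- file.path(tempdir(), "sylvamir_shared_run")
    manifest <- run_pipeline(small_config(), outdir = outdir,
                             permutation_R = 200L)
    .scenario_cache$run <- list(manifest = manifest, outdir = outdir)
  }
  .scenario_cache$run
}

# hand-built perfect hairpin window: flank + mature + loop + revcomp(mature)
# + flank; returns pieces for assertions
perfect_hairpin_window <- function(mature = "ACGTACGGTTCAGCTAAGCTA",
                                   loop = "TTTCAAGG",
                                   flank_left = strrep("CA", 10),
                                   flank_right = strrep("GT", 10)) {
  list(window = paste0(flank_left, mature, loop, oracle_revcomp(mature), flank_right),
       mature = mature, loop = loop,
       flank_left = flank_left, flank_right = flank_right)
}

# quick read-record constructor with uniform high qualities
mk_reads <- function(seqs, qual_char = "I") {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = strrep(qual_char, nchar(seqs)), stringsAsFactors = FALSE)
}
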