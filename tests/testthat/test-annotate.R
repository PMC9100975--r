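# Read mapping, stack construction, locus annotation, and known/novel
# classification.

test_that("mapping reports planted placements exactly and matches the full-scan oracle", {
  set.seed(41)
  g <- random_dna(1, 2000)
  read <- random_dna(1, 21)
  g2 <- g
  substr(g2, 300, 320) <- read
  substr(g2, 1200, 1220) <- read
  genome <- Biostrings::DNAStringSet(setNames(g2, "chr1"))

  hits <- map_reads(read, genome)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$start, c(300, 1200))

  absent <- map_reads("ACGTACGTACGTACGTACGTA", genome)
  expect_equal(nrow(absent), 0)

  # exhaustive agreement with the brute-force scanner, with and without
  # mismatches, both strands
  reads <- c(read, revcomp(read), random_dna(5, 21),
             substr(g2, 500, 521), substr(g2, 900, 923))
  for (mm in 0:1) {
    hits <- map_reads(reads, genome, max_mismatch = mm, max_hits = 50)
    for (r in unique(reads)) {
      got <- hits[hits$seq == r, c("start", "end", "strand", "mismatches")]
      want <- oracle_scan_genome(r, g2, mm)
      got <- got[order(got$start, got$strand), ]
      want <- want[order(want$start, want$strand), ]
      expect_equal(unname(as.matrix(got[, c("start", "end")])),
                   unname(as.matrix(want[, c("start", "end")])),
                   info = paste("mm:", mm))
      expect_equal(got$strand, want$strand)
    }
  }
  expect_error(map_reads(read, Biostrings::DNAStringSet()), "empty genome")
})

test_that("multi-mapping reads over the cap are discarded and tallied", {
  set.seed(42)
  read <- random_dna(1, 20)
  g <- paste0(random_dna(1, 50), strrep(paste0(read, random_dna(1, 10)), 4),
              random_dna(1, 50))
  genome <- Biostrings::DNAStringSet(setNames(g, "chr1"))
  hits <- map_reads(read, genome, max_hits = 3)
  expect_equal(nrow(hits), 0)
  expect_equal(attr(hits, "n_discarded_multimappers"), 1L)
  hits4 <- map_reads(read, genome, max_hits = 4)
  expect_equal(nrow(hits4), 4)
})

test_that("stacks merge hits within 2 nt and pick the most abundant representative", {
  mk_hits <- function(seqs, starts, counts) {
    data.frame(seq = seqs, seq_id = "chr1", start = starts,
               end = starts + nchar(seqs) - 1L, strand = "+",
               mismatches = 0L, s1 = counts, stringsAsFactors = FALSE)
  }
  # identical coordinates: one stack, counts summed
  h <- mk_hits(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTT"),
               c(101, 101), c(5, 3))
  st <- build_stacks(h)
  expect_equal(nrow(st), 1)
  expect_equal(st$s1, 8L)
  expect_equal(st$representative, "ACGTACGTACGTACGTACGTA")

  # 100 nt apart: two stacks
  h2 <- mk_hits(rep("ACGTACGTACGTACGTACGTA", 2), c(101, 201), c(1, 1))
  expect_equal(nrow(build_stacks(h2)), 2)

  # six hits at 2-nt offsets chain into hand-enumerated boundaries
  h6 <- mk_hits(rep(c("ACGTACGTACGTACGTACGTA"), 6),
                c(100, 122, 144, 300, 402, 424), rep(1, 6))
  # [100,120],[122,142],[144,164] abut within 2 nt -> one stack [100,164];
  # 300 alone; 402 and 424 merge -> [402,444]
  st6 <- build_stacks(h6)
  expect_equal(nrow(st6), 3)
  expect_equal(st6$start, c(100, 300, 402))
  expect_equal(st6$end, c(164, 320, 444))

  # ties go to the lexicographically smallest sequence
  ht <- mk_hits(c("TTTTACGTACGTACGTACGTT", "ACGTACGTACGTACGTACGTT"),
                c(101, 101), c(4, 4))
  expect_equal(build_stacks(ht)$representative, "ACGTACGTACGTACGTACGTT")
})

test_that("annotation recovers exactly the planted loci on synthetic data", {
  sc <- get_scenario()
  hits <- map_reads(sc$kept, sc$genome)
  stacks <- build_stacks(hits)
  loci <- annotate_loci(stacks, sc$genome, min_count = 10)

  tr <- sc$truth$loci
  expect_equal(nrow(loci), nrow(tr))
  expect_setequal(loci$mature, tr$mature)
  # sensitivity and precision both 1: every locus matches a planted mature
  # interval on the right strand
  for (i in seq_len(nrow(loci))) {
    j <- match(loci$mature[i], tr$mature)
    expect_equal(loci$strand[i], tr$strand[j])
    expect_equal(loci$mature_start[i], tr$mature_start[j])
    expect_equal(loci$mature_end[i], tr$mature_end[j])
  }
  # every emitted locus satisfies the type invariants
  expect_true(all(nchar(loci$precursor) <= 300))
  expect_true(all(nchar(loci$mature) >= 20 & nchar(loci$mature) <= 24))
  evs <- attr(loci, "evaluations")
  expect_true(all(vapply(evs, function(e) e$passed, logical(1))))

  expect_equal(nrow(annotate_loci(stacks[0, ], sc$genome)), 0)
})

test_that("loci below the count floor in every sample are removed", {
  sc <- get_scenario()
  mature1 <- sc$truth$loci$mature[1]
  reads <- data.frame(seq = mature1, s1 = 9L, s2 = 9L, s3 = 9L,
                      stringsAsFactors = FALSE)
  hits <- map_reads(reads, sc$genome)
  stacks <- build_stacks(hits)
  expect_equal(nrow(annotate_loci(stacks, sc$genome, min_count = 10)), 0)
  expect_equal(nrow(annotate_loci(stacks, sc$genome, min_count = 9)), 1)
})

test_that("known/novel classification follows the 2-substitution, 2-nt rule", {
  sc <- get_scenario()
  hits <- map_reads(sc$kept, sc$genome)
  stacks <- build_stacks(hits)
  kr <- simulate_known_reference(sc$truth, sc$cfg)
  loci <- annotate_loci(stacks, sc$genome, reference = kr$reference)

  tr <- kr$truth$loci
  for (i in seq_len(nrow(loci))) {
    j <- match(loci$mature[i], tr$mature)
    expect_equal(loci$status[i], tr$status[j], info = tr$name[j])
    if (tr$status[j] == "known") expect_equal(loci$family[i], tr$family[j])
  }
  # novel names run miRN1, miRN2, ... in genomic order
  novel <- loci[loci$status == "novel", ]
  expect_equal(novel$name, sprintf("miRN%d", seq_len(nrow(novel))))
  expect_equal(novel$mature_start, sort(novel$mature_start))

  # empty reference: everything novel
  all_novel <- annotate_loci(stacks, sc$genome, reference = NULL)
  expect_true(all(all_novel$status == "novel"))

  # a reference three substitutions away does not rescue a locus
  far_ref <- strsplit(loci$mature[1], "")[[1]]
  for (i in c(2, 8, 14)) far_ref[i] <- setdiff(c("A", "C", "G", "T"), far_ref[i])[1]
  ref3 <- Biostrings::DNAStringSet(setNames(paste(far_ref, collapse = ""),
                                            "xxx-miR999a"))
  re <- classify_known_novel(loci[1, , drop = FALSE], ref3)
  expect_equal(re$status, "novel")
  ref2 <- Biostrings::DNAStringSet(setNames(loci$mature[2], "xxx-miR888b"))
  re2 <- classify_known_novel(loci[2, , drop = FALSE], ref2)
  expect_equal(re2$status, "known")
  expect_equal(re2$family, "miR888")
})

test_that("reverse-complementing the genome mirrors the locus set", {
  sc <- get_scenario()
  hits <- map_reads(sc$kept, sc$genome)
  loci <- annotate_loci(build_stacks(hits), sc$genome)

  G <- sum(Biostrings::width(sc$genome))
  genome_rc <- Biostrings::DNAStringSet(setNames(revcomp(as.character(sc$genome)), "chr1"))
  hits_rc <- map_reads(sc$kept, genome_rc)
  loci_rc <- annotate_loci(build_stacks(hits_rc), genome_rc)

  expect_equal(nrow(loci_rc), nrow(loci))
  expect_setequal(loci_rc$mature, loci$mature)
  for (i in seq_len(nrow(loci))) {
    j <- match(loci$mature[i], loci_rc$mature)
    expect_equal(loci_rc$strand[j], if (loci$strand[i] == "+") "-" else "+")
    expect_equal(loci_rc$mature_start[j], G - loci$mature_end[i] + 1L)
    expect_equal(loci_rc$mature_end[j], G - loci$mature_start[i] + 1L)
  }
})

test_that("GFF3 export round-trips through rtracklayer", {
  sc <- get_scenario()
  hits <- map_reads(sc$kept, sc$genome)
  loci <- annotate_loci(build_stacks(hits), sc$genome)
  path <- tempfile(fileext = ".gff3")
  export_loci_gff3(loci, path)
  gr <- rtracklayer::import(path)
  expect_equal(sum(gr$type == "miRNA_primary_transcript"), nrow(loci))
  expect_equal(sum(gr$type == "miRNA"), 2 * nrow(loci))
  prec <- gr[gr$type == "miRNA_primary_transcript"]
  expect_setequal(GenomicRanges::start(prec), loci$precursor_start)
})
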