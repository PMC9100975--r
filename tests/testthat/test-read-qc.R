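# Adapter inference, trimming, and the six-way filter with exact
# conservation accounting.

ADAPTER <- "AGATCGGAAGAGCACACGTCT"

test_that("adapter inference recovers a constructed adapter and fails on noise", {
  set.seed(42)
  inserts <- random_dna(300, sample(20:24, 300, replace = TRUE))
  reads <- substr(paste0(inserts, ADAPTER, random_dna(300, 20)), 1, 50)
  expect_equal(infer_adapter3(mk_reads(reads)), substr(ADAPTER, 1, 10))

  noise <- random_dna(300, 50)
  expect_error(infer_adapter3(mk_reads(noise)), "no adapter consensus")

  expect_identical(infer_adapter3(mk_reads(noise), adapter = "acgtacgtacgt"),
                   "ACGTACGTACGT")
  expect_error(infer_adapter3(mk_reads(reads[1:50])), "at least 100")
})

test_that("trimming truncates at the leftmost seed hit and flags absent adapters", {
  set.seed(7)
  ins <- random_dna(1, 18)
  while (!grepl(paste0("^", ins, "AGATCGGAAG"),
                paste0(ins, ADAPTER))) ins <- random_dna(1, 18)
  read50 <- substr(paste0(ins, ADAPTER, random_dna(1, 20)), 1, 50)
  tr <- trim_reads(mk_reads(read50), ADAPTER)
  expect_equal(tr$insert, ins)
  expect_equal(nchar(tr$insert), 18)
  expect_false(tr$adapter_missing)

  # one mismatch in the seed still trims
  mm <- read50
  substr(mm, 20, 20) <- if (substr(mm, 20, 20) == "A") "C" else "A"
  tr_mm <- trim_reads(mk_reads(mm), ADAPTER)
  expect_equal(tr_mm$trim_pos, 19)

  no_ad <- "TCTTACTGATCGTTGCAATCGCATTGCAACCTTGCAATTGGCCTTAACCT"
  tr2 <- trim_reads(mk_reads(no_ad), ADAPTER)
  expect_true(tr2$adapter_missing)

  # adapter at position 1: empty insert, later a length discard
  at0 <- substr(paste0(ADAPTER, random_dna(1, 40)), 1, 50)
  res <- filter_reads(mk_reads(at0), ADAPTER)
  expect_equal(res$category, "length_out_of_range")

  expect_error(trim_reads(mk_reads(read50), "ACGTACG"), "at least 10")
})

test_that("a hand-built 12-read fixture lands one read per category plus six clean", {
  marker5 <- substr(revcomp(ADAPTER), 12, 21)
  good_q <- function(n) strrep("I", n)
  clean_ins <- c("ACGTGCATCGATAAGCTGAC", "TTGACCGGATCGAATCGCAT",
                 "CCATCGTTGCAAGGCATACG", "GGCATTCGAACCGTTAGCAT",
                 "TACGGATCCGTTACAGGCAT", "ATCGCATGGTTACGCAAGCT")
  mk <- function(ins) substr(paste0(ins, ADAPTER, strrep("CA", 10)), 1, 50)
  seqs <- vapply(clean_ins, mk, character(1))

  lowq <- mk(clean_ins[1])
  highn <- mk("ACGNNGCANCGNTANGCNGA")
  fivep <- substr(paste0(marker5, mk(clean_ins[2])), 1, 50)
  no3p <- "TCTTACTGATCGTTGCAATCGCATTGCAACCTTGCAATTGGCCTTAACCT"
  poly <- mk(strrep("A", 21))
  badlen <- mk("ACGTGCATCG")  # 10-nt insert

  reads <- data.frame(
    id = sprintf("r%02d", 1:12),
    seq = c(seqs, lowq, highn, fivep, no3p, poly, badlen),
    qual = c(vapply(c(seqs, ""), function(s) good_q(50), character(1))[1:6],
             paste0(strrep("(", 20), strrep("I", 30)),  # Q7 x20 of 50 = 40% low
             good_q(50), good_q(50), good_q(50), good_q(50), good_q(50)),
    stringsAsFactors = FALSE
  )
  res <- filter_reads(reads, ADAPTER)
  rp <- res$report
  expect_equal(rp$raw, 12)
  expect_equal(rp$clean, 6)
  expect_equal(c(rp$low_quality, rp$high_n, rp$five_prime_adapter,
                 rp$no_three_prime_adapter, rp$poly_nt, rp$length_out_of_range),
               rep(1, 6))
  # trimmed clean output carries the bare inserts
  expect_setequal(res$clean$seq, clean_ins)
})

test_that("all-clean input passes untouched and re-filtering is a no-op", {
  set.seed(13)
  ins <- random_dna(40, sample(20:24, 40, replace = TRUE))
  keepers <- vapply(ins, function(s) {
    !is.na(leftmost_seed_match(paste0(s, ADAPTER), substr(ADAPTER, 1, 10), 1L)) &&
      leftmost_seed_match(paste0(s, ADAPTER), substr(ADAPTER, 1, 10), 1L) == nchar(s) + 1
  }, logical(1))
  ins <- ins[keepers]
  reads <- mk_reads(substr(paste0(ins, ADAPTER, random_dna(length(ins), 20)), 1, 50))
  res <- filter_reads(reads, ADAPTER)
  expect_equal(res$report$clean, res$report$raw)

  # idempotence: already-trimmed output survives a second pass intact
  res2 <- filter_reads(res$clean, ADAPTER)
  expect_equal(res2$report$clean, res2$report$raw)
  expect_identical(res2$clean$seq, res$clean$seq)
})

test_that("conservation identity and clean-set order independence hold on random fixtures", {
  set.seed(99)
  params <- qc_params()
  marker5 <- substr(revcomp(ADAPTER), 12, 21)
  for (rep_i in 1:25) {
    n <- sample(5:30, 1)
    seqs <- character(n)
    quals <- character(n)
    for (i in seq_len(n)) {
      kind <- sample(c("clean", "noad", "short", "poly", "n", "lowq", "fivep"), 1)
      ins <- switch(kind,
                    clean = random_dna(1, sample(18:30, 1)),
                    noad = NA,
                    short = random_dna(1, sample(5:16, 1)),
                    poly = strrep(sample(c("A", "T", "C", "G"), 1), 22),
                    n = paste0(strrep("N", 8), random_dna(1, 13)),
                    lowq = random_dna(1, 21),
                    fivep = random_dna(1, 21))
      seqs[i] <- if (kind == "noad") random_dna(1, 50) else
        substr(paste0(if (kind == "fivep") marker5 else "", ins, ADAPTER,
                      random_dna(1, 30)), 1, 50)
      quals[i] <- if (kind == "lowq") {
        paste0(strrep("(", 25), strrep("I", nchar(seqs[i]) - 25))
      } else strrep("I", nchar(seqs[i]))
    }
    res <- filter_reads(data.frame(id = as.character(seq_len(n)), seq = seqs,
                                   qual = quals, stringsAsFactors = FALSE),
                        ADAPTER, params)
    rp <- res$report
    expect_identical(rp$raw,
                     rp$clean + rp$low_quality + rp$high_n +
                       rp$five_prime_adapter + rp$no_three_prime_adapter +
                       rp$poly_nt + rp$length_out_of_range)
    # order independence of the clean set: a read is clean iff it passes
    # every individual test (re-derived here from scratch)
    passes_all <- function(s, q) {
      sc <- utf8ToInt(q) - 33L
      if (mean(sc < 20) > 0.30) return(FALSE)
      ch <- strsplit(s, "")[[1]]
      if (mean(ch == "N") > 0.10) return(FALSE)
      m5 <- strsplit(marker5, "")[[1]]
      if (length(ch) >= 10 && sum(ch[1:10] != m5) <= 1) return(FALSE)
      sd <- strsplit(substr(ADAPTER, 1, 10), "")[[1]]
      pos <- NA
      if (length(ch) >= 10) {
        for (o in 1:(length(ch) - 9)) {
          if (sum(ch[o:(o + 9)] != sd) <= 1) { pos <- o; break }
        }
      }
      ins <- if (is.na(pos)) {
        if (length(ch) > 30) return(FALSE) else ch
      } else ch[seq_len(pos - 1)]
      L <- length(ins)
      if (L == 0) return(FALSE)
      if (max(tabulate(factor(ins, levels = c("A", "C", "G", "T", "N")))) / L >= 0.8) {
        return(FALSE)
      }
      L >= 18 && L <= 30
    }
    expected_clean <- mapply(passes_all, seqs, quals)
    expect_identical(unname(res$category == "clean"), unname(expected_clean))
  }
})

test_that("malformed records and unbalanced reports raise errors", {
  bad <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"),
                    qual = c("IIII", "III"), stringsAsFactors = FALSE)
  expect_error(filter_reads(bad, ADAPTER), "index 2")
  expect_error(filter_report(raw = 10, clean = 5, high_n = 1), "balance")
  expect_error(filter_report(raw = -1, clean = -1), "non-negative")
})
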