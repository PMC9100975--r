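Package: sylvamir
Title: Small RNA, miRNA Annotation, and Degradome Target Analysis for
    Woody Plant Vascular Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a plant
    small-RNA analysis pipeline: adapter inference and six-way read
    filtering with exact conservation accounting, contaminant removal,
    hairpin-based miRNA locus annotation under plant duplex criteria
    (precursor <= 300 nt, mature 20-24 nt, <= 5 duplex mismatches with
    <= 3 in the loop region), reads-per-ten-million normalization, a
    defined negative-binomial Wald test for differential expression,
    degradome-guided cleavage-site calling with category 0-4 confidence
    classification and a permutation p-value, and hypergeometric GO/KEGG
    enrichment with the rich-factor statistic. A synthetic-data generator
    plants hairpin loci, counts, and cleavage sites with known ground
    truth so that every stage is verifiable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
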