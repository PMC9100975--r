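# Published summary numbers from the poplar phloem / developing-xylem
# small-RNA study this pipeline models, bundled as plain-text data. They are
# inputs for the arithmetic bookkeeping audits (the raw sequencing data
# itself is deposited externally and is not desk-scale).

#' Published per-library sequencing summary
#'
#' Per-library raw/clean read counts, Q30, GC, and genome mapping rate for
#' the six sRNA libraries (three phloem `P`, three developing-xylem `X`)
#' of the modelled study.
#'
#' @return data.frame with columns `sample`, `raw_reads`, `clean_reads`,
#'   `q30_percent`, `gc_percent`, `mapped_rate_percent`.
#' @export
reported_library_summary <- function() {
  read.delim(system.file("extdata", "srna_library_summary.tsv",
                         package = "sylvamir"),
             stringsAsFactors = FALSE)
}

#' Published study-level summary values
#'
#' Totals used by the bookkeeping audits: raw/clean read totals, the four
#' printed filter-category counts, the 18-30 nt window counts, miRNA
#' catalog sizes, differential-expression summary, and the miR171
#' xylem/phloem expression values.
#'
#' @return named list of numeric values.
#' @export
reported_study_values <- function() {
  df <- read.delim(system.file("extdata", "srna_study_reported_values.tsv",
                               package = "sylvamir"),
                   stringsAsFactors = FALSE)
  setNames(as.list(as.numeric(df$value)), df$metric)
}
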