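# End-to-end orchestration of the synthetic study: simulate, QC,
# decontaminate, annotate, quantify/DE, degradome targets, enrichment,
# with a consolidated manifest and a human-readable report.

log_stage <- function(stage, ...) {
  message(sprintf("[sylvamir:%s] %s", stage, paste0(...)))
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> qc -> decontaminate -> annotate -> quantify/DE ->
#' degradome -> enrich on a synthetic study with known ground truth, writes
#' all intermediate artifacts under `outdir`, and returns a run manifest
#' with per-stage summaries, file digests, and truth-recovery metrics
#' (planted-locus sensitivity/precision, planted-target sensitivity).
#'
#' @param config a [simulation_config()], or the path to a YAML file whose
#'   fields are `simulation_config()` arguments.
#' @param outdir output directory (created if needed).
#' @param min_count low-expression cutoff for locus annotation (default 10).
#' @param lfc_threshold,alpha differential-expression thresholds.
#' @param permutation_R permutation count for target p-values.
#' @return invisible run manifest (list), also written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, outdir = tempfile("sylvamir_run_"),
                         min_count = 10L, lfc_threshold = 1.5, alpha = 0.05,
                         permutation_R = 200L) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- do.call(simulation_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # ---- simulate -------------------------------------------------------
  log_stage("simulate", "genome with ", config$n_planted_loci,
            " planted loci, ", config$n_decoy_stacks, " decoys")
  gen <- simulate_genome(config)
  genome <- gen$genome
  truth <- gen$truth
  contaminants <- gen$contaminants
  kr <- simulate_known_reference(truth, config)
  truth <- kr$truth
  txr <- simulate_transcripts(truth, config)
  truth$sites <- txr$sites
  reads <- simulate_reads(truth, config, contaminants,
                          outdir = file.path(outdir, "reads"))
  truth <- reads$truth
  write_fasta(genome, file.path(outdir, "genome.fa"))
  write_fasta(txr$transcripts, file.path(outdir, "transcripts.fa"))
  write_fasta(kr$reference, file.path(outdir, "known_mirnas.fa"))
  for (r in contaminants) {
    write_fasta(r$sequences, file.path(outdir, paste0(r$name, ".fa")))
  }
  write.table(truth$loci, file.path(outdir, "truth_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$sites, file.path(outdir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  samples <- sample_names(config)

  # ---- qc -------------------------------------------------------------
  log_stage("qc", "adapter inference and six-way filtering")
  qc_reports <- list()
  clean <- list()
  for (sm in samples) {
    rd <- reads$samples[[sm]]
    adapter <- tryCatch(infer_adapter3(rd), error = function(e) config$adapter3)
    fr <- filter_reads(rd, adapter)
    qc_reports[[sm]] <- fr$report
    clean[[sm]] <- fr$clean
  }
  qc_tab <- do.call(rbind, lapply(samples, function(sm) {
    cbind(sample = sm, as.data.frame(qc_reports[[sm]]))
  }))
  write.table(qc_tab, file.path(outdir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- decontaminate --------------------------------------------------
  log_stage("decontaminate", "removing rRNA/tRNA/organelle reads")
  collapsed <- collapse_reads(clean)
  decon <- filter_contaminants(collapsed, contaminants, max_mismatch = 1L)
  kept <- decon$kept

  # ---- annotate -------------------------------------------------------
  log_stage("annotate", "mapping and hairpin evaluation")
  hits <- map_reads(kept, genome, max_mismatch = 0L, max_hits = 20L)
  stacks <- build_stacks(hits)
  loci <- annotate_loci(stacks, genome, min_count = min_count,
                        reference = kr$reference)
  export_loci_gff3(loci, file.path(outdir, "loci.gff3"))
  write.table(loci, file.path(outdir, "loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # truth recovery
  locus_match <- function(i) {
    any(truth$loci$strand == loci$strand[i] &
          truth$loci$mature_start <= loci$mature_end[i] &
          truth$loci$mature_end >= loci$mature_start[i])
  }
  n_loci <- nrow(loci)
  matched <- if (n_loci > 0) vapply(seq_len(n_loci), locus_match, logical(1)) else logical(0)
  planted_found <- if (nrow(truth$loci) > 0) {
    vapply(seq_len(nrow(truth$loci)), function(t) {
      any(loci$strand == truth$loci$strand[t] &
            loci$mature_start <= truth$loci$mature_end[t] &
            loci$mature_end >= truth$loci$mature_start[t])
    }, logical(1))
  } else logical(0)
  sensitivity <- if (length(planted_found)) mean(planted_found) else NA_real_
  precision <- if (n_loci > 0) mean(matched) else NA_real_

  # ---- quantify / DE --------------------------------------------------
  log_stage("quantify", "RPTM and NB Wald differential expression")
  de <- NULL
  expr <- NULL
  if (n_loci > 0) {
    counts <- as.matrix(loci[, samples, drop = FALSE])
    rownames(counts) <- loci$name
    total_mapped <- vapply(samples, function(sm) {
      sum(stacks[[sm]])
    }, numeric(1))
    total_mapped <- pmax(total_mapped, colSums(counts))
    expr <- expression_matrix(counts, total_mapped)
    write.table(cbind(locus = rownames(counts), as.data.frame(counts)),
                file.path(outdir, "counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(locus = rownames(counts), as.data.frame(expr$rptm)),
                file.path(outdir, "rptm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    de <- tryCatch({
      res <- nb_wald_test(counts, sample_groups(config))
      call_de(res, lfc_threshold = lfc_threshold, alpha = alpha)
    }, error = function(e) {
      log_stage("quantify", "DE skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(de)) {
      write.table(de, file.path(outdir, "de_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # ---- degradome ------------------------------------------------------
  log_stage("degradome", "tag simulation, mapping, target calling")
  tags <- simulate_degradome(truth, txr$transcripts, config)
  write_fastq(tags, file.path(outdir, "degradome_tags.fastq"))
  profiles <- map_tags(tags, txr$transcripts)
  mirnas <- if (n_loci > 0) setNames(loci$mature, loci$name) else character(0)
  targets <- call_targets(mirnas, txr$transcripts, profiles,
                          R = permutation_R, seed = config$seed + 8000L)
  write.table(targets, file.path(outdir, "targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  target_sensitivity <- NA_real_
  if (nrow(truth$sites) > 0) {
    found <- vapply(seq_len(nrow(truth$sites)), function(i) {
      tr <- truth$sites[i, ]
      planted_locus <- tr$mirna
      recovered_names <- loci$name[loci$mature == tr$mature]
      any(targets$transcript_id == tr$transcript &
            targets$cleavage_pos == tr$cleavage_pos &
            targets$mirna_id %in% recovered_names)
    }, logical(1))
    target_sensitivity <- mean(found)
  }

  # ---- enrichment -----------------------------------------------------
  log_stage("enrich", "hypergeometric term enrichment of target genes")
  term_map <- simulate_term_map(txr$transcripts, truth$sites, config)
  write.table(term_map, file.path(outdir, "term_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  universe <- names(txr$transcripts)
  target_genes <- intersect(unique(targets$transcript_id), universe)
  enrichment <- enrich(target_genes, term_map, universe)
  write.table(enrichment, file.path(outdir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- manifest -------------------------------------------------------
  mapped_per_sample <- if (nrow(stacks) > 0) {
    vapply(samples, function(sm) sum(stacks[[sm]]), numeric(1))
  } else setNames(numeric(length(samples)), samples)
  clean_per_sample <- vapply(samples, function(sm) qc_reports[[sm]]$clean, numeric(1))
  manifest <- list(
    tool = "sylvamir",
    version = as.character(utils::packageVersion("sylvamir")),
    seed = config$seed,
    config = unclass(config),
    samples = samples,
    stages = list(
      qc = lapply(qc_reports, unclass),
      decontaminate = list(removed = nrow(decon$removed),
                           kept = nrow(decon$kept),
                           per_kind = as.list(decon$counts)),
      annotate = list(n_loci = n_loci,
                      n_known = sum(loci$status == "known"),
                      n_novel = sum(loci$status == "novel"),
                      sensitivity = sensitivity, precision = precision),
      de = if (!is.null(de)) list(n_up = attr(de, "n_up"),
                                  n_down = attr(de, "n_down"),
                                  n_tested = sum(!is.na(de$p_value)))
           else list(n_up = 0L, n_down = 0L, n_tested = 0L),
      degradome = list(n_targets = nrow(targets),
                       target_sensitivity = target_sensitivity),
      enrich = list(n_terms = nrow(enrichment),
                    top_term = if (nrow(enrichment)) enrichment$term_id[1] else NA)
    ),
    mapped_per_sample = as.list(mapped_per_sample),
    clean_per_sample = as.list(clean_per_sample),
    digests = file_digests(list.files(outdir, recursive = TRUE,
                                      full.names = TRUE, pattern = "\\.(fa|fastq|tsv|gff3)$"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(write_report(manifest), file.path(outdir, "report.txt"))
  invisible(manifest)
}

#' Render a human-readable pipeline report
#'
#' Per-sample table (raw, clean, Q30, GC, mapped rate), the filter
#' conservation identity check, the DE summary, and the head of the target
#' table.
#'
#' @param manifest a run manifest from [run_pipeline()].
#' @return character vector of report lines.
#' @export
write_report <- function(manifest) {
  lines <- c("sylvamir run report",
             sprintf("seed: %d", manifest$seed), "")
  lines <- c(lines, sprintf("%-8s %10s %10s %8s %8s %12s",
                            "sample", "raw", "clean", "Q30", "GC", "mapped_rate"))
  identity_ok <- TRUE
  for (sm in manifest$samples) {
    q <- manifest$stages$qc[[sm]]
    mapped <- manifest$mapped_per_sample[[sm]]
    rate <- if (q$clean > 0) mapped / q$clean else NA_real_
    discards <- q$low_quality + q$high_n + q$five_prime_adapter +
      q$no_three_prime_adapter + q$poly_nt + q$length_out_of_range
    if (q$raw != q$clean + discards) identity_ok <- FALSE
    lines <- c(lines, sprintf("%-8s %10d %10d %7.2f%% %7.2f%% %11.2f%%",
                              sm, q$raw, q$clean, 100 * q$q30_fraction,
                              100 * q$gc_fraction, 100 * rate))
  }
  lines <- c(lines, "",
             sprintf("filter conservation identity: %s",
                     if (identity_ok) "PASS" else "FAIL"))
  ann <- manifest$stages$annotate
  de <- manifest$stages$de
  pct <- if (ann$n_loci > 0) {
    round(100 * (de$n_up + de$n_down) / ann$n_loci, 2)
  } else 0
  lines <- c(lines,
             sprintf("loci: %d (%d known, %d novel); planted sensitivity %.2f, precision %.2f",
                     ann$n_loci, ann$n_known, ann$n_novel,
                     ann$sensitivity, ann$precision),
             sprintf("differential expression: %d up, %d down (%.2f%% of %d loci)",
                     de$n_up, de$n_down, pct, ann$n_loci),
             sprintf("degradome targets: %d (planted-site sensitivity %.2f)",
                     manifest$stages$degradome$n_targets,
                     manifest$stages$degradome$target_sensitivity))
  lines
}
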