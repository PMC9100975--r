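# Expression quantification and differential expression: RPTM
# normalization, median-of-ratios size factors, and a defined
# negative-binomial Wald test with method-of-moments dispersion shrunk
# toward a fitted mean-dispersion trend.

#' Reads-per-ten-million normalization
#'
#' `rptm[i, j] = raw_counts[i, j] / total_mapped[j] * 1e7`.
#'
#' @param raw_counts non-negative integer matrix (loci x samples).
#' @param total_mapped per-sample totals of mapped reads; every entry must
#'   be positive and at least the corresponding column sum.
#' @return numeric matrix of RPTM values.
#' @export
compute_rptm <- function(raw_counts, total_mapped) {
  raw_counts <- as.matrix(raw_counts)
  if (length(total_mapped) != ncol(raw_counts)) {
    stop("one total per sample required")
  }
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive for every sample")
  sweep(raw_counts, 2, total_mapped, "/") * 1e7
}

#' Build an expression matrix container
#'
#' @param raw_counts loci x samples integer matrix (rownames = locus ids).
#' @param total_mapped per-sample mapped-read totals (>= column sums).
#' @return object of class `expression_matrix`: list with `locus_ids`,
#'   `sample_ids`, `raw_counts`, `total_mapped`, `rptm`.
#' @export
expression_matrix <- function(raw_counts, total_mapped) {
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  if (any(total_mapped < colSums(raw_counts))) {
    stop("total_mapped must be at least the per-sample column sum")
  }
  structure(list(
    locus_ids = rownames(raw_counts),
    sample_ids = colnames(raw_counts),
    raw_counts = raw_counts,
    total_mapped = total_mapped,
    rptm = compute_rptm(raw_counts, total_mapped)
  ), class = "expression_matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over loci (restricted to
#' loci with nonzero counts in every sample) of the ratio of the sample's
#' count to the locus's geometric mean across samples. Factors are not
#' rescaled further.
#'
#' @param raw_counts loci x samples count matrix.
#' @return per-sample numeric factors.
#' @export
estimate_size_factors <- function(raw_counts) {
  raw_counts <- as.matrix(raw_counts)
  all_nz <- rowSums(raw_counts == 0) == 0
  if (!any(all_nz)) {
    stop("no locus has nonzero counts in all samples; ",
         "consider a pseudo-reference fallback")
  }
  sub <- raw_counts[all_nz, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub / geo, 2, median)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per locus, group means of size-factor-normalized counts define the
#' log2 fold change (first group listed in `groups` over the second).
#' Dispersion is estimated by method of moments on normalized counts
#' (pooled within-group variance), floored at 1e-8 and shrunk 50% toward a
#' fitted mean-dispersion trend; the Wald statistic is the log2 fold change
#' over its delta-method standard error, with a two-sided normal p-value.
#' A locus with all-zero counts in one group gets a signed-infinite log2
#' fold change and a p-value from a +0.5 pseudo-count path, and is flagged.
#'
#' @param raw_counts loci x samples count matrix.
#' @param groups character/factor of length `ncol(raw_counts)` with exactly
#'   two levels, each with at least 2 samples. The numerator group is the
#'   first one encountered.
#' @param size_factors optional; default [estimate_size_factors()].
#' @return data.frame: `locus_id`, `baseMeanNum`, `baseMeanDen`, `log2fc`,
#'   `se`, `stat`, `p_value`, `dispersion`, `zero_group_flag`; attribute
#'   `size_factors`.
#' @export
nb_wald_test <- function(raw_counts, groups, size_factors = NULL) {
  raw_counts <- as.matrix(raw_counts)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs at least 2 samples")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(raw_counts)
  num <- groups == lv[1]
  den <- groups == lv[2]
  norm <- sweep(raw_counts, 2, size_factors, "/")

  mean_num <- rowMeans(norm[, num, drop = FALSE])
  mean_den <- rowMeans(norm[, den, drop = FALSE])
  mu <- (mean_num + mean_den) / 2

  ss <- function(m) rowSums((m - rowMeans(m))^2)
  pooled_var <- (ss(norm[, num, drop = FALSE]) + ss(norm[, den, drop = FALSE])) /
    (sum(num) + sum(den) - 2)
  disp_raw <- pmax((pooled_var - mu) / mu^2, 1e-8)
  disp_raw[!is.finite(disp_raw)] <- 1e-8

  # mean-dispersion trend: asymptotic dispersion plus a 1/mean term
  use <- is.finite(mu) & mu > 0
  trend <- rep(median(disp_raw[use]), length(mu))
  if (sum(use) >= 10) {
    fit <- tryCatch(lm(disp_raw[use] ~ I(1 / mu[use])), error = function(e) NULL)
    if (!is.null(fit)) {
      a <- max(coef(fit)[1], 1e-8)
      b <- max(coef(fit)[2], 0)
      trend <- a + b / pmax(mu, 1e-8)
    }
  }
  dispersion <- 0.5 * disp_raw + 0.5 * trend

  zero_flag <- mean_num == 0 | mean_den == 0
  # +0.5 pseudo-count path for inference in degenerate loci
  pseudo <- sweep(raw_counts + 0.5, 2, size_factors, "/")
  p_num <- rowMeans(pseudo[, num, drop = FALSE])
  p_den <- rowMeans(pseudo[, den, drop = FALSE])
  eff_num <- ifelse(zero_flag, p_num, mean_num)
  eff_den <- ifelse(zero_flag, p_den, mean_den)

  log2fc <- log2(mean_num / mean_den)
  log2fc[zero_flag & mean_num == 0 & mean_den > 0] <- -Inf
  log2fc[zero_flag & mean_den == 0 & mean_num > 0] <- Inf
  log2fc[mean_num == 0 & mean_den == 0] <- NA_real_

  var_group <- function(m_eff, mask) {
    s <- size_factors[mask]
    vapply(seq_along(m_eff), function(i) {
      sum(m_eff[i] / s + dispersion[i] * m_eff[i]^2) / sum(mask)^2
    }, numeric(1))
  }
  vnum <- var_group(eff_num, num)
  vden <- var_group(eff_den, den)
  ln2sq <- log(2)^2
  se <- sqrt(vnum / (eff_num^2 * ln2sq) + vden / (eff_den^2 * ln2sq))
  stat <- log2(eff_num / eff_den) / se
  p <- 2 * pnorm(-abs(stat))
  p[eff_num == 0 & eff_den == 0] <- NA_real_

  out <- data.frame(
    locus_id = if (!is.null(rownames(raw_counts))) rownames(raw_counts)
               else as.character(seq_len(nrow(raw_counts))),
    baseMeanNum = mean_num, baseMeanDen = mean_den,
    log2fc = log2fc, se = se, stat = stat, p_value = p,
    dispersion = dispersion, zero_group_flag = zero_flag,
    stringsAsFactors = FALSE
  )
  attr(out, "size_factors") <- size_factors
  attr(out, "numerator") <- lv[1]
  attr(out, "denominator") <- lv[2]
  out
}

#' Call differential expression
#'
#' Benjamini-Hochberg adjustment across tested loci (all-zero loci are
#' excluded from the family), then strict thresholds: up iff
#' `log2fc > lfc_threshold` and `padj < alpha`; down iff
#' `log2fc < -lfc_threshold` and `padj < alpha`; otherwise not significant.
#'
#' @param results data.frame from [nb_wald_test()].
#' @param lfc_threshold log2 fold-change threshold (strict, default 1.5).
#' @param alpha adjusted-p threshold (strict, default 0.05).
#' @return `results` with `padj` and `direction` columns; attributes
#'   `n_up`, `n_down`, `summary`.
#' @export
call_de <- function(results, lfc_threshold = 1.5, alpha = 0.05) {
  tested <- !is.na(results$p_value)
  if (any(results$p_value[tested] < 0 | results$p_value[tested] > 1)) {
    stop("p-values must lie in [0,1]")
  }
  padj <- rep(NA_real_, nrow(results))
  padj[tested] <- p.adjust(results$p_value[tested], method = "BH")
  direction <- rep("ns", nrow(results))
  up <- tested & !is.na(results$log2fc) & results$log2fc > lfc_threshold & padj < alpha
  down <- tested & !is.na(results$log2fc) & results$log2fc < -lfc_threshold & padj < alpha
  direction[up] <- "up"
  direction[down] <- "down"
  results$padj <- padj
  results$direction <- direction
  attr(results, "n_up") <- sum(up)
  attr(results, "n_down") <- sum(down)
  attr(results, "summary") <- sprintf(
    "%d up, %d down of %d tested loci (%.2f%% differentially expressed)",
    sum(up), sum(down), sum(tested),
    if (sum(tested) > 0) 100 * (sum(up) + sum(down)) / sum(tested) else 0
  )
  class(results) <- c("de_result", class(results))
  results
}

#' @export
print.de_result <- function(x, ...) {
  cat("Differential expression results\n")
  cat(" ", attr(x, "summary"), "\n")
  NextMethod()
}
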