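# Over-representation analysis of target-gene sets (hypergeometric upper
# tail, BH adjustment, rich factor) and miRNA-family set utilities.

#' Hypergeometric term enrichment with rich factors
#'
#' For each term: `k` target genes in the term, `K` universe genes in the
#' term, `n` targets, `N` universe genes; `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`; rich factor `k / K` (target genes in the
#' term over all annotated genes in the term); BH adjustment across terms.
#'
#' @param target_genes character vector (must be a subset of `universe`).
#' @param term_map two-column data.frame (`term`, `gene`) or named list of
#'   gene vectors.
#' @param universe all annotated genes (non-empty).
#' @return data.frame: `term_id`, `k`, `K`, `n`, `N`, `rich_factor`,
#'   `p_value`, `padj`, sorted by p-value.
#' @export
enrich <- function(target_genes, term_map, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  target_genes <- unique(as.character(target_genes))
  if (!all(target_genes %in% universe)) {
    stop("target genes must be a subset of the universe")
  }
  if (is.data.frame(term_map)) {
    term_map <- split(as.character(term_map$gene), as.character(term_map$term))
  }
  N <- length(universe)
  n <- length(target_genes)
  rows <- lapply(names(term_map), function(tid) {
    tg <- intersect(unique(term_map[[tid]]), universe)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, target_genes))
    data.frame(term_id = tid, k = k, K = K, n = n, N = N,
               rich_factor = k / K,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), rich_factor = numeric(0),
                      p_value = numeric(0), padj = numeric(0)))
  }
  out$padj <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Venn partition of miRNA family catalogs
#'
#' Partitions the union of all family names by the exact set of groups in
#' which each family is present. With `mode = "all"` (default) a family is
#' present in a group when every species of the group carries it; with
#' `mode = "any"` one species suffices. Families present in no group land
#' in the `"(none)"` cell, so the partition counts always sum to the union
#' size.
#'
#' @param catalogs named list: species -> character vector of family names.
#' @param groups named list: group -> species names (default: each species
#'   is its own group).
#' @param mode `"all"` or `"any"` (see above).
#' @return list with `counts` (data.frame `groups`, `n`) and `members`
#'   (named list of family vectors).
#' @export
family_sets <- function(catalogs, groups = NULL, mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(length(catalogs) >= 1, !is.null(names(catalogs)))
  if (anyDuplicated(names(catalogs))) stop("duplicate species names")
  if (is.null(groups)) {
    groups <- setNames(as.list(names(catalogs)), names(catalogs))
  }
  bad <- setdiff(unlist(groups), names(catalogs))
  if (length(bad)) stop("unknown species in groups: ", paste(bad, collapse = ", "))
  fams <- sort(unique(unlist(catalogs)))
  agg <- if (mode == "all") all else any
  key <- vapply(fams, function(f) {
    ing <- vapply(names(groups), function(g) {
      agg(vapply(groups[[g]], function(sp) f %in% catalogs[[sp]], logical(1)))
    }, logical(1))
    if (!any(ing)) "(none)" else paste(names(groups)[ing], collapse = "&")
  }, character(1))
  members <- split(fams, key)
  counts <- data.frame(groups = names(members),
                       n = vapply(members, length, integer(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts[order(-counts$n, counts$groups), , drop = FALSE],
       members = members)
}
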