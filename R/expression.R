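# Differential-expression calling, set overlap, and hypergeometric term
# enrichment with Benjamini-Hochberg correction.
#
# Differential expression is only an upstream input to the overlap and
# marked-fraction analyses, so calling is delegated to DESeq2 (negative
# binomial Wald test); the thresholds applied on top (|log2FC| >= 1,
# BH-adjusted p < 0.05) are this pipeline's DEG definition.

#' Median-of-ratios size factors
#'
#' @param count_matrix Nonnegative integer matrix, genes in rows, samples in
#'   columns.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(count_matrix) {
  m <- as.matrix(count_matrix)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) stop("no gene with positive counts in all samples")
  logm <- log(m[allpos, , drop = FALSE])
  log_gm <- rowMeans(logm)
  apply(logm, 2, function(col) exp(stats::median(col - log_gm)))
}

#' Call differentially expressed genes
#'
#' Runs the DESeq2 negative-binomial Wald test between the two groups and
#' flags genes with `|log2fc| >= lfc_threshold` and BH-adjusted p below
#' `alpha` (genes with an `NA` adjusted p from independent filtering are
#' never flagged).
#'
#' @param count_matrix Genes x samples count matrix (nonnegative integers).
#' @param groups Factor/character vector of length `ncol(count_matrix)` with
#'   exactly two levels; the fold change is second level over first.
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A `data.frame` (`DegRecord`) with `gene_id`, `base_mean`,
#'   `log2fc`, `p_value`, `p_adj`, `is_deg`. The `method` attribute records
#'   the model used.
#' @export
call_deg <- function(count_matrix, groups, lfc_threshold = 1, alpha = 0.05) {
  m <- as.matrix(count_matrix)
  storage.mode(m) <- "integer"
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  coldata <- S4Vectors::DataFrame(group = factor(groups, levels = lv))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, stats::as.formula("~ group"))
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("group", lv[2], lv[1]),
                         alpha = alpha)
  out <- data.frame(
    gene_id = rownames(m),
    base_mean = res$baseMean,
    log2fc = res$log2FoldChange,
    p_value = res$pvalue,
    p_adj = res$padj,
    stringsAsFactors = FALSE
  )
  out$is_deg <- !is.na(out$p_adj) & !is.na(out$log2fc) &
    abs(out$log2fc) >= lfc_threshold & out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "method") <- "DESeq2 negative-binomial Wald test + BH"
  out
}

#' Overlap between differentially spliced and differentially expressed genes
#'
#' @param dis_genes,deg_genes Character vectors of gene ids.
#' @return A list with `n_dis_only`, `n_deg_only`, `n_both`.
#' @export
overlap_sets <- function(dis_genes, deg_genes) {
  dis <- unique(dis_genes); deg <- unique(deg_genes)
  both <- intersect(dis, deg)
  list(n_dis_only = length(setdiff(dis, deg)),
       n_deg_only = length(setdiff(deg, dis)),
       n_both = length(both))
}

#' Hypergeometric term enrichment with BH correction
#'
#' Per term, tests over-representation of the study set with the upper-tail
#' hypergeometric probability `P(X >= k)` for `k` study hits out of `K`
#' term members in a population of `N` with study size `n`, then adjusts
#' across tested terms with Benjamini-Hochberg. A term is reported when its
#' adjusted p is below `alpha` and at least `min_genes` study genes hit it.
#'
#' @param study_set Character vector of study gene ids (subset of
#'   `population`).
#' @param population Character vector of all gene ids.
#' @param term_map `data.frame` with columns `term_id`, `gene_id` (and
#'   optionally `description`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_genes Minimum study hits for a term to be reported (default 5).
#' @return A `data.frame` (`EnrichmentResult`) with one row per term:
#'   `term_id`, `k`, `K`, `n`, `N`, `p_value`, `p_adj`, `reported`.
#' @export
hypergeom_enrichment <- function(study_set, population, term_map,
                                 alpha = 0.05, min_genes = 5) {
  study <- unique(study_set); pop <- unique(population)
  outside <- setdiff(study, pop)
  if (length(outside) > 0) {
    stop("study gene(s) absent from population: ",
         paste(utils::head(outside, 3), collapse = ", "))
  }
  N <- length(pop); n <- length(study)
  terms <- split(term_map$gene_id, term_map$term_id)
  rows <- lapply(names(terms), function(tid) {
    members <- intersect(unique(terms[[tid]]), pop)
    K <- length(members)
    k <- length(intersect(members, study))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$reported <- out$p_adj < alpha & out$k >= min_genes
  rownames(out) <- NULL
  out
}
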