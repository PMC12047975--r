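#' Over-representation analysis by the hypergeometric test
#'
#' For each category, tests whether the gene list overlaps it more than
#' expected when drawing `n` genes at random from the background:
#' `p = P(X >= k)` for `X ~ Hypergeometric(K, N - K, n)`. Categories
#' overlapping the list in fewer than `min_overlap` genes are excluded
#' before testing (so they do not enter the Benjamini-Hochberg
#' denominator, matching common ORA tools). The enrichment ratio is
#' `(k / n) / (K / N)`.
#'
#' @param gene_list character vector of genes of interest (must be drawn
#'   from `background`; duplicates removed with a warning).
#' @param categories named list of character vectors (e.g. from
#'   [read_gmt()]); members outside the background are ignored.
#' @param background character vector: the gene universe.
#' @param min_overlap minimum list-category overlap to test (default 5).
#' @param fdr significance level on the BH-adjusted p (default 0.05).
#' @return `data.frame` ordered by raw p: `category`, `k` (overlap),
#'   `K` (category size), `n` (list size), `N` (background size), `ratio`,
#'   `pval`, `padj`, `significant`.
#' @export
ora <- function(gene_list, categories, background, min_overlap = 5,
                fdr = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  if (anyDuplicated(gene_list)) {
    warning("duplicate genes in list deduplicated")
    gene_list <- unique(gene_list)
  }
  if (!all(gene_list %in% background))
    stop("gene_list must be a subset of the background")
  N <- length(background)
  n <- length(gene_list)
  K <- vapply(categories, function(s) length(intersect(s, background)), 0L)
  k <- vapply(categories, function(s) length(intersect(s, gene_list)), 0L)
  keep <- k >= min_overlap
  cat_names <- names(categories)[keep]
  K <- K[keep]; k <- k[keep]
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(category = cat_names, k = unname(k), K = unname(K),
                    n = rep(n, length(k)), N = rep(N, length(k)),
                    ratio = unname((k / n) / (K / N)), pval = unname(p),
                    padj = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$padj < fdr
  out <- out[order(out$pval, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
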