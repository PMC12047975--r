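#' Weighted multi-criteria candidate-gene score
#'
#' Eight criteria summarize the evidence for a gene inside a QTL support
#' interval: (1) a coding variant segregating between the founders
#' (nonsynonymous / frameshift / stop-gain / splice), (2) a heart-failure
#' GWAS association, (3) a cardiovascular-disease GWAS association,
#' (4) cis-regulation of the gene in heart tissue, (5) differential
#' expression in cardiomyopathy vs control hearts, (6) heart expression
#' above a TPM threshold, (7) functional relevance in the heart, and
#' (8) a significant Mendelian-randomization causal test. The six evidence
#' criteria score 1 point each; functional relevance and MR score 2 each,
#' for a maximum of 10. Genes reaching 30% of the maximum (>= 3 points by
#' default) are selected.
#'
#' @param evidence one-row `data.frame` (or list) with logical fields
#'   `coding_variant`, `gwas_hf`, `gwas_cvd`, `cis_regulated`, `deg`,
#'   `functional_relevance`, `mr_significant` and numeric `expression_tpm`.
#'   Flags may also be given as text (`"Y"`/`"--"`, or a variant
#'   description for `coding_variant`). Missing flags are treated as FALSE.
#' @param weights named criterion weights; the default is
#'   `c(coding_variant = 1, gwas_hf = 1, gwas_cvd = 1, cis_regulated = 1,
#'   deg = 1, expression = 1, functional_relevance = 2, mr_significant = 2)`.
#' @param tpm_threshold expression criterion passes iff TPM is strictly
#'   greater than this (default 2; a value of exactly 2 scores 0).
#' @param select_frac selection threshold as a fraction of the maximum
#'   achievable score (default 0.30).
#' @return one-row `data.frame`: per-criterion points, `total`, `max_score`,
#'   `selected`.
#' @examples
#' score_gene(list(coding_variant = TRUE, gwas_hf = TRUE, gwas_cvd = TRUE,
#'                 cis_regulated = TRUE, deg = FALSE,
#'                 functional_relevance = FALSE, expression_tpm = 3.35,
#'                 mr_significant = TRUE))$total  # 7
#' @export
score_gene <- function(evidence,
                       weights = c(coding_variant = 1, gwas_hf = 1,
                                   gwas_cvd = 1, cis_regulated = 1, deg = 1,
                                   expression = 1, functional_relevance = 2,
                                   mr_significant = 2),
                       tpm_threshold = 2, select_frac = 0.30) {
  ev <- as.list(evidence)
  tpm <- ev$expression_tpm
  if (is.null(tpm)) tpm <- 0
  if (!is.finite(tpm) || tpm < 0) stop("expression_tpm must be >= 0")
  flags <- c("coding_variant", "gwas_hf", "gwas_cvd", "cis_regulated",
             "deg", "functional_relevance", "mr_significant")
  val <- vapply(flags, function(f) as_flag(ev[[f]]), NA)
  crit <- c(val[c("coding_variant", "gwas_hf", "gwas_cvd", "cis_regulated",
                  "deg")],
            expression = unname(tpm > tpm_threshold),
            val[c("functional_relevance", "mr_significant")])
  points <- as.integer(crit) * weights[names(crit)]
  total <- sum(points)
  max_score <- sum(weights)
  out <- as.data.frame(as.list(points))
  out$total <- total
  out$max_score <- max_score
  out$selected <- total >= ceiling(select_frac * max_score)
  out
}

# text/logical flag coercion: "--", "", "N", NA, FALSE are off; any variant
# description ("Nonsynonymous SNP", "Splice site mutation", "y") is on
as_flag <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(FALSE)
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  !(trimws(toupper(as.character(x))) %in% c("--", "-", "", "N", "NO", "0", "FALSE"))
}

#' Score a whole gene-evidence table
#'
#' @param evidence `data.frame` with one row per gene; must carry a
#'   `symbol` (or `gene`) column plus the fields of [score_gene()].
#' @inheritParams score_gene
#' @return `data.frame` of class `scorecard`: `symbol`, per-criterion
#'   points, `expression_tpm`, `total`, `selected`.
#' @export
score_genes <- function(evidence, weights = NULL, tpm_threshold = 2,
                        select_frac = 0.30) {
  if (nrow(evidence) == 0L) stop("empty evidence table")
  sym <- if ("symbol" %in% names(evidence)) evidence$symbol else evidence$gene
  if (is.null(sym)) stop("evidence needs a symbol (or gene) column")
  args <- list(tpm_threshold = tpm_threshold, select_frac = select_frac)
  if (!is.null(weights)) args$weights <- weights
  rows <- lapply(seq_len(nrow(evidence)), function(i)
    do.call(score_gene, c(list(evidence[i, , drop = FALSE]), args)))
  out <- cbind(data.frame(symbol = sym, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out$expression_tpm <- as.numeric(evidence$expression_tpm)
  class(out) <- c("scorecard", "data.frame")
  out
}

#' Rank scored candidates
#'
#' Orders by total score descending; ties broken by heart expression (TPM)
#' descending, then gene symbol. The tie-break beyond the score is a
#' package convention, recorded in the output attributes.
#'
#' @param scorecards a `scorecard` from [score_genes()].
#' @return the reordered scorecard with a `rank` column.
#' @export
rank_candidates <- function(scorecards) {
  if (nrow(scorecards) == 0L) stop("need at least one scorecard")
  o <- order(-scorecards$total, -scorecards$expression_tpm, scorecards$symbol)
  out <- scorecards[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "tie_break") <- "expression_tpm desc, then symbol"
  out
}

#' Genes overlapping a QTL support interval
#'
#' A gene is returned when its span overlaps the interval at all
#' (inclusive endpoints), so boundary-straddling genes count.
#'
#' @param annotation `data.frame` with columns `gene`, `chr`, `start_Mb`,
#'   `end_Mb`.
#' @param interval a [support_interval()] (or list with `chr`, `start_Mb`,
#'   `end_Mb`).
#' @return character vector of gene ids (possibly empty, with a warning
#'   when the annotation itself is empty).
#' @export
genes_in_interval <- function(annotation, interval) {
  if (nrow(annotation) == 0L) {
    warning("empty annotation")
    return(character(0))
  }
  hit <- annotation$chr == interval$chr &
    annotation$end_Mb >= interval$start_Mb &
    annotation$start_Mb <= interval$end_Mb
  annotation$gene[hit]
}

#' Classify a gene as cis-regulated relative to an eQTL peak
#'
#' Cis iff the gene midpoint lies within `window` Mb of the peak on the
#' same chromosome.
#'
#' @param gene_chr,gene_start_Mb,gene_end_Mb gene location (point genes:
#'   give start only).
#' @param peak_chr,peak_Mb eQTL peak location.
#' @param window distance threshold in Mb (default 5).
#' @return logical.
#' @export
classify_cis <- function(gene_chr, gene_start_Mb, gene_end_Mb = gene_start_Mb,
                         peak_chr, peak_Mb, window = 5) {
  if (as.character(gene_chr) != as.character(peak_chr)) return(FALSE)
  mid <- (gene_start_Mb + gene_end_Mb) / 2
  abs(mid - peak_Mb) <= window
}

#' Call differentially expressed genes from a results table
#'
#' DEG iff adjusted p < `padj_threshold` and |fold change| >
#' `fc_threshold`. Fold changes are taken on the linear scale with sign
#' encoding direction; log2 fold changes are converted first.
#'
#' @param results `data.frame` with columns `gene`, `padj` and either `fc`
#'   (signed linear fold change) or `log2fc`.
#' @param padj_threshold adjusted-p cutoff (default 0.05).
#' @param fc_threshold absolute fold-change cutoff (default 1.5).
#' @return named logical vector; genes with missing `padj` are dropped with
#'   a warning.
#' @export
flag_degs <- function(results, padj_threshold = 0.05, fc_threshold = 1.5) {
  fc <- if ("fc" %in% names(results)) results$fc
        else if ("log2fc" %in% names(results))
          sign(results$log2fc) * 2^abs(results$log2fc)
        else stop("results need an fc or log2fc column")
  keep <- !is.na(results$padj)
  if (any(!keep))
    warning(sum(!keep), " gene(s) skipped: missing adjusted p")
  stats::setNames(results$padj[keep] < padj_threshold &
                    abs(fc[keep]) > fc_threshold,
                  results$gene[keep])
}

#' Read a gene-evidence TSV
#'
#' Columns: `symbol`, `coding_variant`, `gwas_hf`, `gwas_cvd`,
#' `cis_regulated`, `deg`, `functional_relevance`, `expression_tpm`,
#' `mr_significant`. Flag cells may be `Y`/`--` text. Two such tables are
#' bundled under `inst/extdata`: the published evidence matrices for the
#' body-weight-loss QTL on chromosome 19 (`evidence_bwloss_chr19.tsv`,
#' 22 genes) and the echocardiography QTL on chromosome 14
#' (`evidence_echo_chr14.tsv`, 9 genes).
#'
#' @param path file path.
#' @return evidence `data.frame` suitable for [score_genes()].
#' @export
read_evidence <- function(path) {
  ev <- read_tsv_table(path)
  if (!"symbol" %in% names(ev)) stop("evidence table needs a symbol column")
  ev$expression_tpm <- as.numeric(ev$expression_tpm)
  ev
}
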