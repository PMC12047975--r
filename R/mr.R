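#' Harmonize exposure and outcome summary statistics
#'
#' Matches instruments by variant id and puts the outcome effect on the
#' exposure's effect allele: when the outcome's effect allele equals the
#' exposure's other allele (and vice versa) the outcome beta sign is
#' flipped. Palindromic variants (A/T or C/G) are dropped — without allele
#' frequencies their strand cannot be resolved — as are variants whose
#' alleles cannot be reconciled or that appear in only one table.
#'
#' @param exposure,outcome summary-statistic `data.frame`s with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se` (and
#'   optionally `gene` / `outcome`, `pval`).
#' @return `data.frame` of class `mr_instruments`: `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, plus `gene` / `outcome` when present; attribute `log`
#'   records drops and flips.
#' @export
harmonize <- function(exposure, outcome) {
  m <- merge(exposure, outcome, by = "variant_id",
             suffixes = c("_exp", "_out"))
  log <- character(0)
  if (nrow(m) == 0L) {
    log <- "no shared variants"
  }
  pal <- function(a, b) paste0(pmin(a, b), pmax(a, b)) %in% c("AT", "CG")
  is_pal <- pal(m$effect_allele_exp, m$other_allele_exp) |
    pal(m$effect_allele_out, m$other_allele_out)
  same <- m$effect_allele_exp == m$effect_allele_out &
    m$other_allele_exp == m$other_allele_out
  swapped <- m$effect_allele_exp == m$other_allele_out &
    m$other_allele_exp == m$effect_allele_out
  if (any(is_pal))
    log <- c(log, paste("dropped palindromic:",
                        paste(m$variant_id[is_pal], collapse = ", ")))
  mismatch <- !is_pal & !same & !swapped
  if (any(mismatch))
    log <- c(log, paste("dropped allele mismatch:",
                        paste(m$variant_id[mismatch], collapse = ", ")))
  flip <- swapped & !is_pal
  if (any(flip))
    log <- c(log, paste("flipped outcome beta:",
                        paste(m$variant_id[flip], collapse = ", ")))
  m$beta_out <- ifelse(flip, -m$beta_out, m$beta_out)
  keep <- (same | swapped) & !is_pal
  out <- data.frame(variant_id = m$variant_id[keep],
                    effect_allele = m$effect_allele_exp[keep],
                    other_allele = m$other_allele_exp[keep],
                    beta_exp = m$beta_exp[keep], se_exp = m$se_exp[keep],
                    beta_out = m$beta_out[keep], se_out = m$se_out[keep],
                    stringsAsFactors = FALSE)
  if ("gene" %in% names(m)) out$gene <- m$gene[keep]
  if ("outcome" %in% names(m)) out$outcome <- m$outcome[keep]
  attr(out, "log") <- log
  class(out) <- c("mr_instruments", "data.frame")
  out
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `theta = beta_out / beta_exp`, with the first-order (delta-method)
#' standard error `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param instruments one-row harmonized instrument set (columns
#'   `beta_exp`, `beta_out`, `se_out`).
#' @return one-row `data.frame`: `method = "Wald"`, `n_snps`, `estimate`,
#'   `se`, `pval`.
#' @export
wald_ratio <- function(instruments) {
  if (nrow(instruments) != 1L) stop("Wald ratio takes exactly one instrument")
  bx <- instruments$beta_exp
  if (bx == 0) stop("undefined Wald ratio: exposure beta is zero")
  est <- instruments$beta_out / bx
  se <- instruments$se_out / abs(bx)
  data.frame(method = "Wald", n_snps = 1L, estimate = est, se = se,
             pval = 2 * stats::pnorm(-abs(est / se)),
             stringsAsFactors = FALSE)
}

#' Fixed-effects inverse-variance-weighted causal estimate
#'
#' Combines per-instrument Wald ratios `r_i = beta_out_i / beta_exp_i` with
#' weights `w_i = (beta_exp_i / se_out_i)^2`:
#' `theta = sum(w r) / sum(w)`, `se = 1 / sqrt(sum(w))` — algebraically the
#' zero-intercept weighted regression of outcome on exposure betas with
#' weights `se_out^-2` (fixed-effects, no exposure-uncertainty term).
#' Instruments with `beta_exp = 0` are dropped with a warning; if a single
#' instrument remains the result falls back to [wald_ratio()].
#'
#' @param instruments harmonized instrument set (>= 1 row).
#' @return one-row `data.frame`: `method` (`"IVW"`, or `"Wald"` on
#'   fallback), `n_snps`, `estimate`, `se`, `pval`.
#' @export
ivw <- function(instruments) {
  if (nrow(instruments) == 0L) stop("no instruments")
  zero <- instruments$beta_exp == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) dropped: exposure beta is zero")
    instruments <- instruments[!zero, , drop = FALSE]
  }
  if (nrow(instruments) == 0L) stop("no usable instruments")
  if (nrow(instruments) == 1L) return(wald_ratio(instruments))
  r <- instruments$beta_out / instruments$beta_exp
  w <- (instruments$beta_exp / instruments$se_out)^2
  est <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  data.frame(method = "IVW", n_snps = nrow(instruments), estimate = est,
             se = se, pval = 2 * stats::pnorm(-abs(est / se)),
             stringsAsFactors = FALSE)
}

#' Two-sample MR across a gene x outcome grid
#'
#' Harmonizes each gene's instruments against each outcome and estimates
#' the causal effect with the Wald ratio (one instrument) or fixed-effects
#' IVW (two or more). Significance is called on the raw p-value by default
#' (no multiple-testing correction, the convention of the screening
#' application this reproduces); set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param exposure eQTL summary statistics with a `gene` column.
#' @param outcome outcome GWAS summary statistics with an `outcome` column.
#' @param alpha significance level on the (adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` of class `mr_results` with columns `gene`,
#'   `outcome`, `n_snps`, `method`, `estimate`, `se`, `pval`,
#'   `significant`; attribute `summary` holds the association counts
#'   (total, significant, distinct significant genes).
#' @export
run_mr <- function(exposure, outcome, alpha = 0.05,
                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  genes <- unique(exposure$gene)
  outs <- if (nrow(outcome)) unique(outcome$outcome) else character(0)
  rows <- list()
  for (g in genes) {
    exp_g <- exposure[exposure$gene == g, , drop = FALSE]
    for (o in outs) {
      out_o <- outcome[outcome$outcome == o, , drop = FALSE]
      h <- harmonize(exp_g, out_o)
      if (nrow(h) == 0L) next
      res <- if (nrow(h) == 1L) wald_ratio(h) else ivw(h)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(gene = g, outcome = o, stringsAsFactors = FALSE),
              res)
    }
  }
  if (length(rows) == 0L) {
    res <- data.frame(gene = character(0), outcome = character(0),
                      n_snps = integer(0), method = character(0),
                      estimate = numeric(0), se = numeric(0),
                      pval = numeric(0), significant = logical(0))
  } else {
    res <- do.call(rbind, rows)
    p <- if (adjust == "BH") stats::p.adjust(res$pval, "BH") else res$pval
    res$significant <- p < alpha
  }
  attr(res, "summary") <- list(
    n_associations = nrow(res),
    n_significant = sum(res$significant),
    n_significant_genes = length(unique(res$gene[res$significant])))
  class(res) <- c("mr_results", "data.frame")
  res
}
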