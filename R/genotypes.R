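#' Genotype matrix container
#'
#' Strains x markers numeric matrix with founder alleles coded
#' 0 (first founder, "B") / 1 (second founder, "D"); heterozygous calls are
#' coded 0.5 and unknowns `NA`. Carries the marker map alongside.
#'
#' @param geno numeric matrix, strains in rows (rownames = strain ids),
#'   markers in columns (colnames = marker names).
#' @param map a [founder_map()] covering every column of `geno`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map) {
  stopifnot(is.matrix(geno), inherits(map, "founder_map"))
  if (is.null(colnames(geno)) || is.null(rownames(geno)))
    stop("geno must have strain rownames and marker colnames")
  if (!all(colnames(geno) %in% map$marker))
    stop("all genotyped markers must appear in the map")
  map <- map[match(colnames(geno), map$marker), , drop = FALSE]
  bad <- !(geno %in% c(0, 0.5, 1) | is.na(geno))
  if (any(bad)) stop("genotype codes must be 0, 0.5, 1 or NA")
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Simulate recombinant inbred genotypes from two founders
#'
#' Each strain is an independent homozygous mosaic of the two founder
#' genomes. Along a chromosome the founder allele switches between adjacent
#' markers with the recombination fraction expected in a sib-mated RI line:
#' the single-meiosis fraction `r` (Haldane's map function applied to the cM
#' gap) expanded to `R = 4r / (1 + 6r)`. Chromosomes are independent and no
#' heterozygotes are emitted (fully inbred lines).
#'
#' @param map a [founder_map()].
#' @param n_strains number of strains to draw (>= 2).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param scheme `"ri_sib"` (default) applies the 4r/(1+6r) map expansion;
#'   `"single_meiosis"` passes `r` through unexpanded.
#' @return A [genotype_matrix()] with 0/1 entries.
#' @examples
#' g <- simulate_ri_genotypes(default_founder_map(), n_strains = 30, seed = 1)
#' @export
simulate_ri_genotypes <- function(map, n_strains, seed = NULL,
                                  scheme = c("ri_sib", "single_meiosis")) {
  if (!inherits(map, "founder_map")) stop("map must be a founder_map")
  if (nrow(map) == 0L) stop("empty founder map")
  if (n_strains < 2) stop("n_strains must be >= 2")
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)

  geno <- matrix(NA_real_, nrow = n_strains, ncol = nrow(map),
                 dimnames = list(sprintf("RIS%03d", seq_len(n_strains)),
                                 map$marker))
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    d <- diff(map$cM[idx])
    r <- 0.5 * (1 - exp(-2 * d / 100))      # Haldane, d in cM
    R <- if (scheme == "ri_sib") 4 * r / (1 + 6 * r) else r
    g <- matrix(0, nrow = n_strains, ncol = length(idx))
    g[, 1] <- stats::rbinom(n_strains, 1, 0.5)
    if (length(idx) > 1L) {
      for (j in seq_along(R)) {
        flip <- stats::runif(n_strains) < R[j]
        g[, j + 1] <- ifelse(flip, 1 - g[, j], g[, j])
      }
    }
    geno[, idx] <- g
  }
  genotype_matrix(geno, map)
}

#' Simulate per-animal phenotypes with planted QTL effects
#'
#' Strain genetic values are the additive sum of planted allele effects at
#' the QTL markers. Strain-level environmental noise is scaled so the planted
#' markers explain approximately `h2` of the strain-mean variance; each
#' animal then adds independent within-strain noise (`sd_within`). With no
#' QTL (or all effects zero) the trait is pure strain-level noise with unit
#' standard deviation.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()]; QTL positions must match map rows by
#'   (`chr`, `Mb`) exactly.
#' @param trait_name trait label written into the records.
#' @return `data.frame` of per-animal records: `strain`, `animal_id`, `sex`,
#'   `trait`, `value`, with attribute `strain_means` (the noiseless-replicate
#'   strain means) and `qtl_markers` (planted marker names).
#' @export
simulate_strain_phenotypes <- function(genotypes, config,
                                       trait_name = "sim_trait") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- genotypes$geno
  map <- genotypes$map
  n <- nrow(G)

  qtl_markers <- character(0)
  g_val <- rep(0, n)
  if (!is.null(config$qtl) && nrow(config$qtl) > 0L) {
    idx <- mapply(function(cc, mb) {
      hit <- which(map$chr == as.character(cc) & map$Mb == mb)
      if (length(hit) != 1L)
        stop("QTL position chr", cc, ":", mb, " Mb not found in the map")
      hit
    }, config$qtl$chr, config$qtl$Mb)
    qtl_markers <- map$marker[idx]
    g_val <- as.vector(G[, idx, drop = FALSE] %*% config$qtl$effect)
  }

  var_g <- stats::var(g_val)
  if (var_g == 0) {
    strain_mean <- stats::rnorm(n, 0, 1)       # pure noise trait
  } else if (config$h2 == 1) {
    strain_mean <- g_val
  } else if (config$h2 == 0) {
    strain_mean <- stats::rnorm(n, 0, sqrt(var_g))  # noise on the same scale
  } else {
    sd_e <- sqrt(var_g * (1 - config$h2) / config$h2)
    strain_mean <- g_val + stats::rnorm(n, 0, sd_e)
  }

  k <- config$n_animals_per_strain
  strains <- rownames(G)
  rec <- data.frame(
    strain = rep(strains, each = k),
    animal_id = paste0(rep(strains, each = k), "_a", rep(seq_len(k), n)),
    sex = rep(rep_len(c("M", "F"), k), n),
    trait = trait_name,
    value = rep(strain_mean, each = k) +
      stats::rnorm(n * k, 0, config$sd_within),
    stringsAsFactors = FALSE)
  attr(rec, "strain_means") <- stats::setNames(strain_mean, strains)
  attr(rec, "qtl_markers") <- qtl_markers
  rec
}

#' Simulate two-sample MR summary statistics with a planted causal slope
#'
#' For each gene, instrument (eQTL) exposure effects are drawn away from
#' zero; outcome effects follow `beta_out = theta * beta_exp_true + noise`
#' with the stated standard errors. A configurable fraction of instruments
#' have their effect/other alleles swapped in the outcome table (with the
#' sign of `beta_out` flipped accordingly) so that harmonization is
#' exercised. Alleles are drawn from non-palindromic pairs.
#'
#' @param n_genes number of genes (one instrument set each).
#' @param n_instruments_per_gene instruments per gene (>= 1).
#' @param theta causal slope linking exposure to outcome.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param se_exp,se_out standard errors of the exposure and outcome effects.
#' @param flip_fraction fraction of instruments stored allele-swapped in the
#'   outcome table.
#' @param outcome outcome label written to the outcome table.
#' @return list with `exposure` and `outcome` summary-statistic data frames
#'   (`gene`/`outcome`, `variant_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`) and the `theta` used.
#' @export
simulate_mr_statistics <- function(n_genes, n_instruments_per_gene, theta,
                                   seed = NULL, se_exp = 0.05, se_out = 0.05,
                                   flip_fraction = 0.3,
                                   outcome = "synthetic_outcome") {
  if (n_instruments_per_gene < 1) stop("need at least one instrument per gene")
  if (!is.null(seed)) set.seed(seed)
  m <- n_genes * n_instruments_per_gene
  gene <- rep(sprintf("G%04d", seq_len(n_genes)), each = n_instruments_per_gene)
  variant <- sprintf("rs%06d", seq_len(m))
  # non-palindromic allele pairs only, so no instruments are lost to the
  # palindromic-drop policy unless the caller plants them deliberately
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(4, m, replace = TRUE)
  ea <- pairs[pick, 1]; oa <- pairs[pick, 2]

  beta_true <- sample(c(-1, 1), m, replace = TRUE) * stats::runif(m, 0.3, 0.8)
  beta_exp <- beta_true + stats::rnorm(m, 0, se_exp)
  beta_out <- theta * beta_true + stats::rnorm(m, 0, se_out)

  exposure <- data.frame(gene = gene, variant_id = variant,
                         effect_allele = ea, other_allele = oa,
                         beta = beta_exp, se = se_exp,
                         pval = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
                         stringsAsFactors = FALSE)
  flip <- stats::runif(m) < flip_fraction
  outc <- data.frame(outcome = outcome, variant_id = variant,
                     effect_allele = ifelse(flip, oa, ea),
                     other_allele = ifelse(flip, ea, oa),
                     beta = ifelse(flip, -beta_out, beta_out),
                     se = se_out,
                     pval = 2 * stats::pnorm(-abs(beta_out / se_out)),
                     stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outc, theta = theta)
}
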