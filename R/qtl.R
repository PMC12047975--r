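#' Single-marker Haley-Knott regression scan
#'
#' Regresses the strain-mean trait on the coded genotype (0 / 0.5 / 1) at
#' every marker. The likelihood-ratio statistic is `LRS = n * ln(RSS0/RSS1)`
#' with `RSS0` the intercept-only residual sum of squares; `LOD = LRS /
#' (2 ln 10)`; the per-marker p-value is the regression F test on
#' (1, n - 2) degrees of freedom. Missing genotypes are dropped marker-wise.
#' Monomorphic markers get `LRS = 0` with flag `"monomorphic"`; a perfect
#' fit (`RSS1 = 0`) is reported as `Inf` with flag `"perfect_fit"`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param trait named numeric vector of strain-mean trait values
#'   (names = strain ids), or a [strain_trait_table()] restricted to one
#'   trait via [trait_vector()].
#' @return `data.frame` of class `qtl_scan`: `marker`, `chr`, `cM`, `Mb`,
#'   `n`, `LRS`, `LOD`, `neglog10p`, `flag`; attribute `method = "hk"`.
#' @export
hk_scan <- function(genotypes, trait) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  trait <- as_trait_vector(trait)
  common <- intersect(rownames(genotypes$geno), names(trait))
  if (length(common) < 3L)
    stop("need >= 3 strains with both genotype and trait")
  G <- genotypes$geno[common, , drop = FALSE]
  y <- trait[common]

  m <- ncol(G)
  LRS <- numeric(m); nn <- integer(m); pval <- numeric(m)
  flag <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    ok <- !is.na(G[, j]) & !is.na(y)
    g <- G[ok, j]; yy <- y[ok]
    n <- length(yy); nn[j] <- n
    if (n < 3L) { LRS[j] <- NA; pval[j] <- NA; flag[j] <- "too_few"; next }
    sxx <- sum((g - mean(g))^2)
    syy <- sum((yy - mean(yy))^2)
    if (sxx == 0) { LRS[j] <- 0; pval[j] <- 1; flag[j] <- "monomorphic"; next }
    if (syy == 0) { LRS[j] <- 0; pval[j] <- 1; next }  # constant trait
    sxy <- sum((g - mean(g)) * (yy - mean(yy)))
    rss1 <- syy - sxy^2 / sxx
    if (rss1 <= .Machine$double.eps * syy) {
      LRS[j] <- Inf; pval[j] <- 0; flag[j] <- "perfect_fit"; next
    }
    LRS[j] <- n * log(syy / rss1)
    Fstat <- (syy - rss1) / (rss1 / (n - 2))
    pval[j] <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  }
  out <- data.frame(marker = genotypes$map$marker, chr = genotypes$map$chr,
                    cM = genotypes$map$cM, Mb = genotypes$map$Mb, n = nn,
                    LRS = LRS, LOD = LRS / (2 * log(10)),
                    neglog10p = -log10(pval), flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "hk"
  class(out) <- c("qtl_scan", "data.frame")
  out
}

# coerce strain_trait_table (single trait) or named vector
as_trait_vector <- function(trait) {
  if (inherits(trait, "strain_trait_table")) {
    tr <- unique(trait$trait)
    if (length(tr) != 1L)
      stop("trait table holds several traits; use trait_vector()")
    return(stats::setNames(trait$value, trait$strain))
  }
  if (is.null(names(trait))) stop("trait vector must be named by strain")
  trait
}

# LRS for complete-data genotypes against many trait vectors at once:
# LRS = -n log(1 - r^2) via a single crossproduct. Y is n x k.
hk_lrs_matrix <- function(G, Y) {
  n <- nrow(G)
  Gs <- scale(G); Ys <- scale(Y)
  Gs[, attr(Gs, "scaled:scale") == 0] <- 0   # monomorphic -> r = 0
  r2 <- (crossprod(Gs, Ys) / (n - 1))^2
  r2[r2 >= 1] <- 1 - 1e-12
  -n * log(1 - r2)                            # markers x k
}

#' Genome-wide permutation threshold for the Haley-Knott scan
#'
#' Permutes trait values across strains `n_perm` times, records the
#' genome-wide maximum LRS of each permutation, and returns the empirical
#' `1 - alpha` quantile of those maxima. Reproducible bit-exactly for a
#' fixed seed.
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide significance level in (0, 1]; 0.05 is the
#'   conventional "significant" level, 0.37 "suggestive".
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return LRS threshold (numeric scalar) with attribute `maxima` holding
#'   the permutation maxima.
#' @export
permutation_threshold <- function(genotypes, trait, n_perm = 1000,
                                  alpha = 0.05, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  trait <- as_trait_vector(trait)
  common <- intersect(rownames(genotypes$geno), names(trait))
  G <- genotypes$geno[common, , drop = FALSE]
  y <- trait[common]
  ok <- !is.na(y)
  G <- G[ok, , drop = FALSE]; y <- y[ok]
  if (!is.null(seed)) set.seed(seed)
  if (!anyNA(G)) {
    Y <- vapply(seq_len(n_perm), function(i) sample(y), y)
    maxima <- apply(hk_lrs_matrix(G, Y), 2, max)
  } else {
    gm <- genotype_matrix(G, founder_map(colnames(G),
                                         genotypes$map$chr,
                                         genotypes$map$cM, genotypes$map$Mb))
    maxima <- vapply(seq_len(n_perm), function(i) {
      sc <- hk_scan(gm, stats::setNames(sample(y), names(y)))
      max(sc$LRS[is.finite(sc$LRS)])
    }, 0)
  }
  thr <- stats::quantile(maxima, probs = 1 - alpha, names = FALSE)
  attr(thr, "maxima") <- maxima
  attr(thr, "alpha") <- alpha
  thr
}

#' Mixed-model genome scan (EMMA-style)
#'
#' Controls for relatedness with a marker-based kinship matrix
#' `K = Gc Gc' / m` (centered genotypes, all markers). Variance components
#' are estimated once under the null by REML on the eigen-rotated model,
#' then every marker is tested by generalized least squares with a Wald
#' t-test — the single-null-fit approximation used by fast mixed-model
#' mappers. When `K` is the identity the scan reduces exactly to ordinary
#' regression.
#'
#' @inheritParams hk_scan
#' @param kinship optional precomputed kinship matrix (strains x strains);
#'   defaults to the all-marker estimate.
#' @return `data.frame` of class `qtl_scan` with columns `marker`, `chr`,
#'   `cM`, `Mb`, `n`, `LRS` (Wald chi-square), `LOD` (chi-square /
#'   (2 ln 10)), `neglog10p`, `flag`; attributes `method = "lmm"`,
#'   `h2` (REML heritability of the null model) and `delta`.
#' @export
lmm_scan <- function(genotypes, trait, kinship = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  trait <- as_trait_vector(trait)
  common <- intersect(rownames(genotypes$geno), names(trait))
  if (length(common) < 4L) stop("need >= 4 strains for the mixed model")
  G <- genotypes$geno[common, , drop = FALSE]
  y <- unname(trait[common])
  n <- length(y)

  Gi <- G
  if (anyNA(Gi)) {  # kinship needs complete data: mean-impute per marker
    mu <- colMeans(Gi, na.rm = TRUE)
    idx <- which(is.na(Gi), arr.ind = TRUE)
    Gi[idx] <- mu[idx[, 2]]
  }
  K <- if (is.null(kinship)) {
    Gc <- scale(Gi, center = TRUE, scale = FALSE)
    tcrossprod(Gc) / ncol(Gc)
  } else kinship[common, common]
  # unit mean diagonal so h2 = 1/(1+delta) is interpretable; the scale of
  # K is otherwise absorbed into delta and leaves the per-marker tests alone
  dK <- mean(diag(K))
  if (dK > 0) K <- K / dK
  eg <- eigen(K, symmetric = TRUE)
  lambda <- eg$values
  if (min(lambda) < -1e-8 * max(abs(lambda))) {
    warning("kinship not PSD; adding ridge")
    lambda <- lambda + abs(min(lambda)) + 1e-8
  }
  lambda <- pmax(lambda, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  x0 <- drop(crossprod(U, rep(1, n)))

  reml_m2ll <- function(log_delta) {  # null model: intercept only
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)
    xwx <- sum(w * x0^2)
    beta <- sum(w * x0 * ys) / xwx
    rss <- sum(w * (ys - x0 * beta)^2)
    (n - 1) * log(rss / (n - 1)) + sum(log(lambda + delta)) + log(xwx)
  }
  opt <- stats::optimize(reml_m2ll, interval = c(-10, 10))
  delta <- exp(opt$minimum)
  w <- 1 / (lambda + delta)

  m <- ncol(G)
  chisq <- numeric(m); pval <- numeric(m); flag <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    g <- Gi[, j]
    if (stats::var(g) == 0) {
      chisq[j] <- 0; pval[j] <- 1; flag[j] <- "monomorphic"; next
    }
    xj <- drop(crossprod(U, g))
    X <- cbind(x0, xj)
    XtWX <- crossprod(X * sqrt(w))
    XtWy <- crossprod(X, w * ys)
    beta <- solve(XtWX, XtWy)
    res <- ys - X %*% beta
    sig2 <- sum(w * res^2) / (n - 2)
    se <- sqrt(sig2 * solve(XtWX)[2, 2])
    tstat <- beta[2] / se
    chisq[j] <- tstat^2
    pval[j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- data.frame(marker = genotypes$map$marker, chr = genotypes$map$chr,
                    cM = genotypes$map$cM, Mb = genotypes$map$Mb, n = n,
                    LRS = chisq, LOD = chisq / (2 * log(10)),
                    neglog10p = -log10(pval), flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "lmm"
  attr(out, "delta") <- delta
  attr(out, "h2") <- 1 / (1 + delta)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' LOD-drop support interval around a chromosome's scan peak
#'
#' Walks outward from the peak marker to the outermost contiguous markers
#' whose LOD stays within `drop` units of the peak (default 2 LOD, i.e. a
#' 9.21-LRS drop). Endpoints are marker positions in Mb. A peak whose
#' interval touches the chromosome end is flagged one-sided.
#'
#' @param scan a `qtl_scan` from [hk_scan()] or [lmm_scan()].
#' @param chromosome chromosome to summarize.
#' @param drop LOD-unit drop defining the interval (default 2).
#' @return list of class `support_interval`: `chr`, `start_Mb`, `end_Mb`,
#'   `peak_Mb`, `peak_marker`, `peak_lod`, `drop`, `one_sided`.
#' @export
support_interval <- function(scan, chromosome, drop = 2) {
  stopifnot(inherits(scan, "qtl_scan"), drop >= 0)
  s <- scan[scan$chr == as.character(chromosome), , drop = FALSE]
  if (nrow(s) == 0L) stop("no markers on chromosome ", chromosome)
  s <- s[order(s$Mb), , drop = FALSE]
  lod <- s$LOD
  lod[!is.finite(lod)] <- max(lod[is.finite(lod)], 0)
  pk <- which.max(lod)
  lo <- pk
  while (lo > 1L && lod[lo - 1L] >= lod[pk] - drop) lo <- lo - 1L
  hi <- pk
  while (hi < nrow(s) && lod[hi + 1L] >= lod[pk] - drop) hi <- hi + 1L
  structure(list(chr = as.character(chromosome),
                 start_Mb = s$Mb[lo], end_Mb = s$Mb[hi],
                 peak_Mb = s$Mb[pk], peak_marker = s$marker[pk],
                 peak_lod = s$LOD[pk], drop = drop,
                 one_sided = (lo == 1L) || (hi == nrow(s))),
            class = "support_interval")
}

#' @export
print.support_interval <- function(x, ...) {
  cat(sprintf("chr%s: %.3f-%.3f Mb (peak %s at %.3f Mb, LOD %.2f, %g-LOD drop)%s\n",
              x$chr, x$start_Mb, x$end_Mb, x$peak_marker, x$peak_Mb,
              x$peak_lod, x$drop, if (x$one_sided) " [one-sided]" else ""))
  invisible(x)
}
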