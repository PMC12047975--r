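test_that("hk_scan matches the closed form and the one-way ANOVA oracle", {
  g <- tiny_geno(c(0, 0, 0, 0, 1, 1, 1, 1))
  y <- setNames(c(1.0, 1.1, 0.9, 1.0, 2.0, 2.1, 1.9, 2.0), paste0("s", 1:8))
  s <- hk_scan(g, y)
  expect_equal(s$LRS, 8 * log(2.04 / 0.04), tolerance = 1e-10)  # 8 ln 51
  expect_equal(s$LOD, s$LRS / (2 * log(10)))

  # constant trait -> LRS 0 everywhere
  s0 <- hk_scan(g, setNames(rep(3, 8), paste0("s", 1:8)))
  expect_equal(s0$LRS, 0)

  # affine invariance of LRS
  s2 <- hk_scan(g, 100 - 7 * y)
  expect_equal(s2$LRS, s$LRS, tolerance = 1e-10)

  # monomorphic and perfect-fit flags
  gm <- tiny_geno(rep(0, 8))
  expect_identical(hk_scan(gm, y)$flag, "monomorphic")
  ysep <- setNames(c(rep(0, 4), rep(1, 4)), paste0("s", 1:8))
  sp <- hk_scan(g, ysep)
  expect_identical(sp$flag, "perfect_fit")
  expect_identical(sp$LRS, Inf)
})

test_that("hk_scan equals per-marker OLS on random data, NAs dropped marker-wise", {
  set.seed(41)
  map <- default_founder_map(n_chr = 2, markers_per_chr = 10)
  g <- simulate_ri_genotypes(map, 30, seed = 41)
  y <- setNames(rnorm(30), rownames(g$geno))
  g$geno[3, 5] <- NA; g$geno[10, 5] <- NA; g$geno[1, 12] <- 0.5
  s <- hk_scan(g, y)
  expect_equal(s$LRS, hk_oracle_lrs(g$geno, y), tolerance = 1e-10)
  expect_equal(s$n[5], 28)
})

test_that("permutation thresholds are monotone, reproducible and quantile-edged", {
  map <- default_founder_map(n_chr = 2, markers_per_chr = 10)
  g <- simulate_ri_genotypes(map, 40, seed = 51)
  y <- setNames(rnorm(40), rownames(g$geno))
  t05 <- permutation_threshold(g, y, n_perm = 500, alpha = 0.05, seed = 5)
  t37 <- permutation_threshold(g, y, n_perm = 500, alpha = 0.37, seed = 5)
  expect_gte(t05, t37)                      # significant >= suggestive
  t1 <- permutation_threshold(g, y, n_perm = 500, alpha = 1, seed = 5)
  expect_equal(as.numeric(t1), min(attr(t1, "maxima")))
  expect_identical(
    as.numeric(permutation_threshold(g, y, n_perm = 200, seed = 9)),
    as.numeric(permutation_threshold(g, y, n_perm = 200, seed = 9)))
  expect_error(permutation_threshold(g, y, n_perm = 500, alpha = 0), "alpha")
  expect_error(permutation_threshold(g, y, n_perm = 50), "n_perm")

  # fast matrix path agrees with the scan-based maxima
  set.seed(7)
  perm <- sample(y)
  fast <- ritox:::hk_lrs_matrix(g$geno, matrix(perm, ncol = 1))
  slow <- hk_scan(g, setNames(perm, names(y)))$LRS
  expect_equal(as.numeric(fast), slow, tolerance = 1e-8)
})

test_that("lmm_scan reduces to OLS under identity kinship and recovers h2", {
  map <- default_founder_map(n_chr = 2, markers_per_chr = 10)
  g <- simulate_ri_genotypes(map, 40, seed = 61)
  y <- setNames(rnorm(40), rownames(g$geno))
  K <- diag(40); dimnames(K) <- list(rownames(g$geno), rownames(g$geno))
  s <- lmm_scan(g, y, kinship = K)
  ols <- vapply(seq_len(ncol(g$geno)), function(j) {
    if (var(g$geno[, j]) == 0) return(1)
    summary(lm(y ~ g$geno[, j]))$coefficients[2, 4]
  }, 0)
  expect_equal(10^(-s$neglog10p), ols, tolerance = 1e-8)

  # zero-variance marker flagged with p = 1
  g$geno[, 4] <- 0
  s2 <- lmm_scan(g, y, kinship = K)
  expect_identical(s2$flag[4], "monomorphic")
  expect_equal(s2$neglog10p[4], 0)

  # REML h2 recovery on a polygenic trait (median over a few sims)
  map2 <- default_founder_map(n_chr = 5, markers_per_chr = 20)
  h2hat <- vapply(1:10, function(i) {
    gg <- simulate_ri_genotypes(map2, 80, seed = 600 + i)
    Gc <- scale(gg$geno, scale = FALSE)
    Kg <- tcrossprod(Gc) / ncol(Gc)
    set.seed(700 + i)
    u <- drop(Gc %*% rnorm(ncol(Gc))) # polygenic signal
    u <- u / sd(u) * sqrt(0.6)
    yy <- setNames(u + rnorm(80, 0, sqrt(0.4)), rownames(gg$geno))
    attr(lmm_scan(gg, yy), "h2")
  }, 0)
  expect_lt(abs(median(h2hat) - 0.6), 0.15)
})

test_that("support_interval walks a 2-LOD drop with correct edge handling", {
  mk_scan <- function(lod, chr = "1", mb = seq_along(lod)) {
    out <- data.frame(marker = paste0("m", seq_along(lod)), chr = chr,
                      cM = mb, Mb = mb, n = 10, LRS = lod * 2 * log(10),
                      LOD = lod, neglog10p = lod, flag = NA_character_)
    class(out) <- c("qtl_scan", "data.frame")
    out
  }
  # single-marker chromosome: zero-width, flagged one-sided
  s1 <- support_interval(mk_scan(5), "1")
  expect_equal(c(s1$start_Mb, s1$end_Mb), c(1, 1))
  expect_true(s1$one_sided)

  # constructed profile: peak +/- 1 Mb
  s2 <- support_interval(mk_scan(c(1, 4, 9, 10, 9, 4, 1)), "1")
  expect_equal(c(s2$start_Mb, s2$peak_Mb, s2$end_Mb), c(3, 4, 5))
  expect_false(s2$one_sided)

  # property: peak inside interval; widening the drop never shrinks it
  set.seed(71)
  for (i in 1:200) {
    lod <- runif(15, 0, 10)
    a <- support_interval(mk_scan(lod), "1", drop = 1)
    b <- support_interval(mk_scan(lod), "1", drop = 3)
    expect_true(a$start_Mb <= a$peak_Mb && a$peak_Mb <= a$end_Mb)
    expect_lte(b$start_Mb, a$start_Mb)
    expect_gte(b$end_Mb, a$end_Mb)
  }
  expect_error(support_interval(mk_scan(1:3), "2"), "no markers")
})
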