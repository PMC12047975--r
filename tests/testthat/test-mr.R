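mk_stats <- function(variant, ea, oa, beta, se = 0.1, gene = NULL,
                     outcome = NULL) {
  d <- data.frame(variant_id = variant, effect_allele = ea, other_allele = oa,
                  beta = beta, se = se, stringsAsFactors = FALSE)
  if (!is.null(gene)) d$gene <- gene
  if (!is.null(outcome)) d$outcome <- outcome
  d
}

test_that("harmonize matches, flips and drops per the stated policy", {
  exp <- mk_stats(c("v1", "v2", "v3", "v4"), c("A", "A", "A", "C"),
                  c("G", "G", "T", "T"), beta = c(0.4, 0.5, 0.3, 0.2))
  out <- mk_stats(c("v1", "v2", "v3", "v4", "v5", "v6"),
                  c("A", "G", "A", "C", "A", "A"),
                  c("G", "A", "T", "T", "G", "C"),
                  beta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  h <- harmonize(exp, out)
  # v3 palindromic (A/T), v5 unshared; v4 identical alleles kept unchanged
  expect_identical(h$variant_id, c("v1", "v2", "v4"))
  expect_equal(h$beta_out, c(0.1, -0.2, 0.4))     # swapped alleles flipped
  expect_true(any(grepl("palindromic", attr(h, "log"))))
  # irreconcilable alleles (v6 A/C vs exposure A/G at v1-style row) dropped
  h6 <- harmonize(mk_stats("v6", "A", "G", 0.3), out)
  expect_equal(nrow(h6), 0L)

  none <- harmonize(exp[1, ], out[5, ])
  expect_equal(nrow(none), 0L)
})

test_that("Wald ratio follows the delta method", {
  ins <- data.frame(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.25,
                    se_out = 0.1)
  w <- wald_ratio(ins)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$pval, 2 * pnorm(-2.5))
  null <- wald_ratio(transform(ins, beta_out = 0))
  expect_equal(null$estimate, 0)
  expect_equal(null$pval, 1)
  expect_error(wald_ratio(transform(ins, beta_exp = 0)), "zero")
})

test_that("IVW equals the zero-intercept WLS oracle and reduces to Wald", {
  ins <- data.frame(beta_exp = c(0.4, 0.8), se_exp = 0.05,
                    beta_out = c(0.2, 0.32), se_out = c(0.1, 0.1))
  res <- ivw(ins)
  # oracle: explicit weighted regression through the origin
  fit <- lm(beta_out ~ 0 + beta_exp, data = ins, weights = 1 / ins$se_out^2)
  expect_equal(res$estimate, unname(coef(fit)), tolerance = 1e-12)
  w <- (ins$beta_exp / ins$se_out)^2
  expect_equal(res$se, 1 / sqrt(sum(w)), tolerance = 1e-12)

  # equal ratios -> that ratio
  eq <- data.frame(beta_exp = c(0.4, 0.8), beta_out = c(0.2, 0.4),
                   se_out = c(0.1, 0.2))
  expect_equal(ivw(eq)$estimate, 0.5)

  # single instrument: identical to the Wald ratio
  one <- data.frame(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.25,
                    se_out = 0.1)
  expect_identical(ivw(one), wald_ratio(one))

  # sign-flip invariance of (beta_exp, beta_out)
  flip <- ins; flip$beta_exp[1] <- -flip$beta_exp[1]
  flip$beta_out[1] <- -flip$beta_out[1]
  expect_equal(ivw(flip)$estimate, res$estimate, tolerance = 1e-12)

  # zero-exposure instrument dropped, falls back to Wald
  z <- rbind(one, data.frame(beta_exp = 0, se_exp = 0.05, beta_out = 0.1,
                             se_out = 0.1))
  expect_warning(rz <- ivw(z), "dropped")
  expect_identical(rz$method, "Wald")
})

test_that("run_mr assembles the gene x outcome grid with summary counts", {
  s <- simulate_mr_statistics(6, 2, theta = 0.8, seed = 91,
                              se_exp = 0.01, se_out = 0.01)
  res <- run_mr(s$exposure, s$outcome)
  expect_equal(nrow(res), 6)
  expect_true(all(res$method == "IVW"))
  expect_true(all(res$n_snps == 2))
  sm <- attr(res, "summary")
  expect_equal(sm$n_associations, 6)
  expect_equal(sm$n_significant_genes, 6)   # strong instruments, big theta
  # method invariant: Wald iff one instrument
  s1 <- simulate_mr_statistics(3, 1, theta = 0.8, seed = 92)
  res1 <- run_mr(s1$exposure, s1$outcome)
  expect_true(all(res1$method == "Wald" & res1$n_snps == 1))
  # empty outcome table -> empty result
  res0 <- run_mr(s$exposure, s$outcome[0, ])
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "summary")$n_associations, 0)
  # BH option is monotone relative to raw calls
  resBH <- run_mr(s$exposure, s$outcome, adjust = "BH")
  expect_lte(sum(resBH$significant), sum(res$significant))
})
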