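test_that("RI genotypes are binary mosaics obeying map expansion", {
  # zero cM distance -> identical columns; unlinked -> R = 0.5
  fm <- founder_map(c("a", "b", "c"), rep("1", 3),
                    cM = c(0, 1e-9, 1000), Mb = c(0, 1, 200))
  g <- simulate_ri_genotypes(fm, 2000, seed = 11)
  expect_true(all(g$geno %in% c(0, 1)))            # fully inbred: no hets
  expect_lt(mean(g$geno[, 1] != g$geno[, 2]), 0.001)
  expect_equal(mean(g$geno[, 1] != g$geno[, 3]), 0.5, tolerance = 0.06)

  # adjacent discordance ~ 4r/(1+6r) at an intermediate distance
  fm2 <- founder_map(c("a", "b"), c("1", "1"), cM = c(0, 25), Mb = c(0, 50))
  g2 <- simulate_ri_genotypes(fm2, 2000, seed = 12)
  r <- 0.5 * (1 - exp(-2 * 25 / 100))
  expect_lt(abs(mean(g2$geno[, 1] != g2$geno[, 2]) - 4 * r / (1 + 6 * r)),
            0.03)
  # pass-through scheme uses r itself
  g3 <- simulate_ri_genotypes(fm2, 2000, seed = 12, scheme = "single_meiosis")
  expect_lt(abs(mean(g3$geno[, 1] != g3$geno[, 2]) - r), 0.03)

  # founder symmetry: allele frequency ~ 0.5 per marker
  expect_true(all(abs(colMeans(g$geno) - 0.5) < 0.03))

  expect_error(simulate_ri_genotypes(fm, 1), "n_strains")
  expect_identical(simulate_ri_genotypes(fm, 50, seed = 3)$geno,
                   simulate_ri_genotypes(fm, 50, seed = 3)$geno)
})

test_that("founder_map validates its invariants", {
  expect_error(founder_map(character(0), character(0), numeric(0), numeric(0)))
  expect_error(founder_map(c("a", "b"), c("1", "1"), c(5, 5), c(1, 2)),
               "strictly increasing")
  expect_error(founder_map(c("a", "b"), c("1", "1"), c(0, 1), c(2, 1)),
               "strictly increasing")
  expect_error(founder_map(c("a", "a"), c("1", "1"), c(0, 1), c(1, 2)),
               "unique")
})

test_that("planted phenotypes carry the stated heritability structure", {
  map <- default_founder_map()
  g <- simulate_ri_genotypes(map, 60, seed = 21)
  qtl <- data.frame(chr = "1", Mb = 100, effect = 1)

  # h2 = 1: trait perfectly separates genotype groups at the QTL marker
  cfg1 <- sim_config(n_strains = 60, qtl = qtl, h2 = 1, sd_within = 0,
                     seed = 22)
  rec1 <- simulate_strain_phenotypes(g, cfg1)
  mk <- attr(rec1, "qtl_markers")
  mu <- attr(rec1, "strain_means")
  expect_equal(unname(mu), unname(g$geno[, mk]))

  # h2 = 0.5: genotype explains about half the strain-mean variance
  cfg2 <- sim_config(n_strains = 60, qtl = qtl, h2 = 0.5, seed = 23)
  rec2 <- simulate_strain_phenotypes(g, cfg2)
  r2 <- summary(lm(attr(rec2, "strain_means") ~ g$geno[, mk]))$r.squared
  expect_gt(r2, 0.25); expect_lt(r2, 0.75)

  # null effects: trait independent of genotype
  cfg0 <- sim_config(n_strains = 60,
                     qtl = data.frame(chr = "1", Mb = 100, effect = 0),
                     h2 = 0.5, seed = 24)
  rec0 <- simulate_strain_phenotypes(g, cfg0)
  expect_length(attr(rec0, "strain_means"), 60)
  expect_equal(nrow(rec0), 60 * 8)         # default 8 replicates/strain
  expect_setequal(unique(rec0$sex), c("M", "F"))

  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(simulate_strain_phenotypes(
    g, sim_config(qtl = data.frame(chr = "9", Mb = 1, effect = 1))),
    "not found")
})

test_that("simulated MR statistics encode the planted slope", {
  # noiseless limit: IVW recovers theta exactly
  s <- simulate_mr_statistics(5, 3, theta = 0.5, seed = 31,
                              se_exp = 0, se_out = 1e-10, flip_fraction = 0)
  h <- harmonize(s$exposure[s$exposure$gene == "G0001", ],
                 s$outcome[s$outcome$variant_id %in%
                             s$exposure$variant_id[s$exposure$gene == "G0001"], ])
  expect_equal(ivw(h)$estimate, 0.5, tolerance = 1e-8)

  # full allele flipping is undone by harmonization (involution)
  a <- simulate_mr_statistics(10, 2, theta = 0.3, seed = 32,
                              flip_fraction = 0)
  b <- simulate_mr_statistics(10, 2, theta = 0.3, seed = 32,
                              flip_fraction = 1)
  expect_identical(a$exposure$beta, b$exposure$beta)
  ha <- harmonize(a$exposure, a$outcome)
  hb <- harmonize(b$exposure, b$outcome)
  expect_equal(ha$beta_out, hb$beta_out, tolerance = 1e-12)

  expect_error(simulate_mr_statistics(2, 0, 0.5), "instrument")
})
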