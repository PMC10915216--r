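test_that("config validation rejects impossible recipes", {
  expect_error(sim_config(allele_freq_bounds = c(0, 0.5)), "inside")
  expect_error(sim_config(var_fracs_trait1 = c(0.5, 0.5, 0.5)), "sum")
  expect_error(sim_config(genetic_corr = 1.2), "correlations")
  expect_error(sim_config(n_causal_additive = 10000, n_snps = 100),
               "causal")
})

test_that("genotypes follow HWE at the drawn frequency and are reproducible", {
  cfg <- sim_config(n_samples = 4000, n_snps = 1, seed = 5,
                    allele_freq_bounds = c(0.5, 0.5),
                    n_causal_additive = 1, n_causal_dominance = 1,
                    n_epistatic_pairs = 1)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$values %in% 0:2))
  # heterozygosity 2pq = 0.5 at p = 0.5
  expect_equal(mean(g$values == 1), 0.5, tolerance = 0.05)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$values, g2$values)
})

test_that("sample allele frequencies track the drawn frequencies", {
  cfg <- sim_config(n_samples = 2000, n_snps = 1000, seed = 3)
  g <- simulate_genotypes(cfg)
  drawn <- attr(g, "drawn_freqs")
  realized <- colMeans(g$values) / 2
  # binomial bound: at n = 2000 the frequency SE is < 0.012, so +/- 0.04
  # holds for >= 95% of SNPs with a wide margin
  expect_gte(mean(abs(realized - drawn) <= 0.04), 0.95)
})

test_that("genetic values hit requested variance fractions exactly", {
  cfg <- sim_config(n_samples = 2000, n_snps = 1000, seed = 2)
  g <- simulate_genotypes(cfg)
  gv <- simulate_effects(cfg, g)
  expect_equal(gv$total, gv$additive + gv$dominance + gv$epistatic)
  tv <- cfg$trait_sds^2
  fr <- rbind(cfg$var_fracs_trait1, cfg$var_fracs_trait2)
  for (tr in 1:2) {
    expect_equal(var(gv$additive[, tr]), fr[tr, 1] * tv[tr],
                 tolerance = 1e-10)
    expect_equal(var(gv$dominance[, tr]), fr[tr, 2] * tv[tr],
                 tolerance = 1e-10)
    expect_equal(var(gv$epistatic[, tr]), fr[tr, 3] * tv[tr],
                 tolerance = 1e-10)
  }
  # component variance over realized phenotypic variance within 0.01 of the
  # requested fraction (phenotype with fixed effects removed)
  ph <- simulate_bivariate_phenotypes(cfg, gv)
  Yg <- cbind(ph$phenotypes$trait1, ph$phenotypes$trait2) - ph$fixed_contrib
  for (tr in 1:2) {
    vp <- var(Yg[, tr])
    expect_equal(var(gv$additive[, tr]) / vp, fr[tr, 1], tolerance = 0.01)
    expect_equal(var(gv$epistatic[, tr]) / vp, fr[tr, 3], tolerance = 0.01)
  }
})

test_that("degenerate effect configurations behave exactly", {
  cfg <- sim_config(n_samples = 200, n_snps = 100, seed = 4,
                    var_fracs_trait1 = c(0, 0, 0),
                    var_fracs_trait2 = c(0, 0, 0))
  g <- simulate_genotypes(cfg)
  gv <- simulate_effects(cfg, g)
  expect_true(all(gv$total == 0))
  # zero fraction requested with zero causal SNPs is fine; nonzero is not
  cfg2 <- sim_config(n_samples = 50, n_snps = 20, seed = 1,
                     n_causal_additive = 0)
  g2 <- simulate_genotypes(cfg2)
  expect_error(simulate_effects(cfg2, g2), "zero causal count")
})

test_that("perfect genetic correlation yields proportional trait values", {
  cfg <- sim_config(n_samples = 500, n_snps = 200, seed = 9,
                    genetic_corr = 1,
                    var_fracs_trait1 = c(0.3, 0, 0),
                    var_fracs_trait2 = c(0.3, 0, 0))
  g <- simulate_genotypes(cfg)
  gv <- simulate_effects(cfg, g)
  expect_equal(cor(gv$additive[, 1], gv$additive[, 2]), 1, tolerance = 1e-10)
})

test_that("phenotype assembly is exact and correlations compose", {
  cfg <- sim_config(n_samples = 2000, n_snps = 500, seed = 6)
  g <- simulate_genotypes(cfg)
  gv <- simulate_effects(cfg, g)
  ph <- simulate_bivariate_phenotypes(cfg, gv)
  Y <- cbind(ph$phenotypes$trait1, ph$phenotypes$trait2)
  recon <- sweep(ph$fixed_contrib + gv$total + ph$residuals, 2,
                 cfg$trait_means, "+")
  expect_equal(Y, recon, tolerance = 1e-12, ignore_attr = TRUE)
  # target phenotypic correlation composed from component correlations
  f1 <- cfg$var_fracs_trait1; f2 <- cfg$var_fracs_trait2
  num <- cfg$genetic_corr * sqrt(f1[1] * f2[1]) +
    cfg$dominance_corr * sqrt(f1[2] * f2[2]) +
    cfg$epistasis_corr * sqrt(f1[3] * f2[3]) +
    cfg$residual_corr * sqrt((1 - sum(f1)) * (1 - sum(f2)))
  Yg <- Y - ph$fixed_contrib
  expect_equal(cor(Yg[, 1], Yg[, 2]), num, tolerance = 0.05)
})

test_that("no residual noise means phenotype equals mean + fixed + genetic", {
  cfg <- sim_config(n_samples = 100, n_snps = 200, seed = 8,
                    var_fracs_trait1 = c(0.5, 0.2, 0.3),
                    var_fracs_trait2 = c(0.4, 0.3, 0.3))
  g <- simulate_genotypes(cfg)
  gv <- simulate_effects(cfg, g)
  ph <- simulate_bivariate_phenotypes(cfg, gv)
  expect_true(all(ph$residuals == 0))
  expect_equal(ph$phenotypes$trait1,
               cfg$trait_means[1] + ph$fixed_contrib[, 1] + gv$total[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("full study pipeline is bit-reproducible from the config", {
  cfg <- sim_config(n_samples = 150, n_snps = 120, seed = 21,
                    missing_rate = 0.02)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genotypes$values, s2$genotypes$values)
  expect_identical(s1$phenotypes$trait1, s2$phenotypes$trait1)
  expect_identical(s1$genetic$total, s2$genetic$total)
  expect_identical(unclass(s1$factors$factors), unclass(s2$factors$factors))
})

test_that("regressing phenotype on true genetic value recovers broad-sense h2", {
  h2b <- numeric(10)
  for (r in 1:10) {
    cfg <- sim_config(n_samples = 2000, n_snps = 500, seed = 100 + r)
    g <- simulate_genotypes(cfg)
    gv <- simulate_effects(cfg, g)
    ph <- simulate_bivariate_phenotypes(cfg, gv)
    yadj <- adjust_phenotypes(ph$phenotypes, ph$factors)
    h2b[r] <- summary(lm(yadj$trait1 ~ gv$total[, 1]))$r.squared
  }
  expect_equal(mean(h2b), sum(sim_config()$var_fracs_trait1),
               tolerance = 0.03)
})
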